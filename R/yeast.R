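# EC50 computation from raw growth-inhibition curves and the yeast
# screen filter pipeline.

#' EC50 from an inhibition curve
#'
#' Log-linear interpolation between the two tested concentrations
#' bracketing 50% inhibition, using the first upward crossing; an exact
#' 50% at a tested concentration returns that concentration. Returns `NA`
#' when the curve never crosses 50% within the tested range (these
#' undefined values drive the screen's "<50% at top" / ">50% at bottom"
#' exclusions).
#'
#' @param concentration Strictly increasing tested concentrations
#'   (molar), length >= 2.
#' @param inhibition Percent growth inhibition at each concentration (may
#'   stray outside 0..100 through assay noise).
#' @return EC50 in molar, or `NA_real_`.
#' @export
ec50_from_curve <- function(concentration, inhibition) {
  stopifnot(length(concentration) >= 2L,
            length(inhibition) == length(concentration),
            all(concentration > 0),
            !is.unsorted(concentration, strictly = TRUE))
  cross <- which(inhibition >= 50)
  if (length(cross) == 0L) return(NA_real_)
  k <- cross[1L]
  if (inhibition[k] == 50) return(concentration[k])
  if (k == 1L) return(NA_real_)  # already above 50% at the lowest dose
  lo <- k - 1L
  f <- (50 - inhibition[lo]) / (inhibition[k] - inhibition[lo])
  10^(log10(concentration[lo]) +
        f * (log10(concentration[k]) - log10(concentration[lo])))
}

# does any component of the structure contain a carbon-metal bond?
.is_organometallic <- function(comps) {
  for (g in comps) {
    b <- g$bond
    if (nrow(b) == 0L) next
    for (r in seq_len(nrow(b))) {
      e1 <- g$elem[b[r, 1L]]; e2 <- g$elem[b[r, 2L]]
      metal1 <- !(e1 %in% .UB_NONMETALS)
      metal2 <- !(e2 %in% .UB_NONMETALS)
      if ((e1 == "C" && metal2) || (e2 == "C" && metal1)) return(TRUE)
    }
  }
  FALSE
}

# are all components except the largest simple halide / alkali counter-ions?
.salt_allowed <- function(comps) {
  sz <- vapply(comps, heavy_atoms, integer(1))
  rest <- comps[-which.max(sz)]
  all(vapply(rest, function(g) {
    heavy_atoms(g) == 1L && g$elem %in% c(.UB_HALOGENS, .UB_ALKALI)
  }, logical(1)))
}

#' Yeast growth-inhibition EC50 pipeline
#'
#' Applies, in order, the screen's exclusion rules and computes per-strain
#' EC50s for the survivors: (1) organometallic compounds (a carbon-metal
#' bond in any component) are excluded; (2) mixtures and salts are
#' excluded unless every counter-ion is a single halide or alkali-metal
#' atom, in which case the largest organic component is scored; (3)
#' compounds whose mean inhibition at the highest tested concentration is
#' below 50%, or at the lowest tested concentration above 50%, are
#' excluded; (4) per-strain EC50s are interpolated with
#' [ec50_from_curve()] and compounds with cross-strain spread
#' `(max - min) / mean > 1` are excluded. Exclusions are outputs, not
#' errors.
#'
#' @param inhibition Long-format data frame: `id`, `strain`,
#'   `concentration` (molar), `inhibition` (percent).
#' @param structures Data frame with `id` and `smiles`.
#' @param spread_max Maximum allowed cross-strain EC50 spread ratio.
#' @return A tibble with one row per compound: `id`, `smiles` (canonical
#'   scored component, `NA` if unparseable), `status`
#'   (`"retained"`/`"excluded"`), `rule` (which rule excluded it),
#'   `n_strains` (strains with a defined EC50), `ec50` (mean across
#'   strains, molar) and `log10_ec50`.
#' @export
yeast_filter <- function(inhibition, structures, spread_max = 1) {
  stopifnot(is.data.frame(inhibition),
            all(c("id", "strain", "concentration", "inhibition") %in%
                  names(inhibition)),
            is.data.frame(structures),
            all(c("id", "smiles") %in% names(structures)))
  ids <- unique(inhibition$id)
  rows <- purrr::map(ids, function(cid) {
    row <- function(status, rule = NA_character_, smiles = NA_character_,
                    n_strains = NA_integer_, ec50 = NA_real_) {
      tibble::tibble(id = cid, smiles = smiles, status = status, rule = rule,
                     n_strains = n_strains, ec50 = ec50,
                     log10_ec50 = log10(ec50))
    }
    smi <- structures$smiles[match(cid, structures$id)]
    if (is.na(smi)) return(row("excluded", "no_structure"))
    comps <- tryCatch(parse_structure(smi, component = "all"),
                      error = function(e) NULL)
    if (is.null(comps)) return(row("excluded", "unparseable"))
    if (inherits(comps, "molgraph")) comps <- list(comps)
    if (.is_organometallic(comps))
      return(row("excluded", "organometallic"))
    if (length(comps) > 1L && !.salt_allowed(comps))
      return(row("excluded", "mixture_or_salt"))
    sz <- vapply(comps, heavy_atoms, integer(1))
    scored <- mol_to_smiles(comps[[which.max(sz)]])

    dat <- inhibition[inhibition$id == cid, ]
    curve <- dat |>
      dplyr::group_by(.data$concentration) |>
      dplyr::summarise(inhibition = mean(.data$inhibition),
                       .groups = "drop") |>
      dplyr::arrange(.data$concentration)
    if (curve$inhibition[nrow(curve)] < 50)
      return(row("excluded", "max_below_50", scored))
    if (curve$inhibition[1L] > 50)
      return(row("excluded", "min_above_50", scored))

    per_strain <- dat |>
      dplyr::arrange(.data$concentration) |>
      dplyr::group_by(.data$strain) |>
      dplyr::summarise(ec50 = ec50_from_curve(.data$concentration,
                                              .data$inhibition),
                       .groups = "drop")
    ec <- per_strain$ec50[is.finite(per_strain$ec50)]
    if (length(ec) == 0L)
      return(row("excluded", "no_ec50", scored))
    if (length(ec) >= 2L && (max(ec) - min(ec)) / mean(ec) > spread_max)
      return(row("excluded", "strain_spread", scored,
                 n_strains = length(ec)))
    row("retained", NA_character_, scored, n_strains = length(ec),
        ec50 = mean(ec))
  })
  dplyr::bind_rows(rows)
}
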