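# Statistical layer: rank correlation of Ub with log half-effect
# concentrations, multiple-testing thresholds, potency bands and hit-rate
# curves. The toxicity convention throughout is log10 of a molar
# half-effect concentration (mol/kg body mass for mammalian whole-organism
# endpoints); a negative correlation means larger Ub at lower
# concentration, i.e. more potent toxicity.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Pearson correlation of average ranks (ties share their mean rank) with
#' a two-sided p-value from the large-sample t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))`. Constant input is flagged as an
#' undefined correlation (`NA`) rather than an error.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`; pairs with missing
#'   values are dropped.
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant input: rank correlation undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

#' Multiple-testing helpers
#'
#' `bonferroni_threshold()` is the family-corrected per-test significance
#' level `alpha / (n_endpoints * n_measures)`; with 35 endpoints and two
#' Ub measures at alpha 0.05 this is the 0.000714 used as the strongest
#' significance tier. `family_wise_prob()` is the chance of at least one
#' false positive among `n_tests` independent tests at per-test level
#' `alpha_star`, `1 - (1 - alpha_star)^n_tests`.
#'
#' @param n_endpoints,n_measures Test family dimensions.
#' @param alpha Family-wise error target.
#' @return A significance level / probability.
#' @export
bonferroni_threshold <- function(n_endpoints, n_measures = 1L, alpha = 0.05) {
  stopifnot(n_endpoints >= 1L, n_measures >= 1L, alpha > 0, alpha < 1)
  alpha / (n_endpoints * n_measures)
}

#' @rdname bonferroni_threshold
#' @param n_tests Number of tests in the family.
#' @param alpha_star Per-test significance level.
#' @export
family_wise_prob <- function(n_tests, alpha_star) {
  stopifnot(n_tests >= 1L, alpha_star >= 0, alpha_star <= 1)
  1 - (1 - alpha_star)^n_tests
}

#' Significance tiers
#'
#' Assigns the conventional star tiers; the default strongest tier is the
#' Bonferroni threshold for 35 endpoints x 2 measures at alpha 0.05.
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Named numeric vector, strongest tier last.
#' @return Character vector of tiers (`""`, `"*"`, `"**"`, `"***"`).
#' @export
significance_tier <- function(p,
    thresholds = c("*" = 0.05, "**" = 0.01,
                   "***" = bonferroni_threshold(35L, 2L, 0.05))) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  out <- rep("", length(p))
  for (k in seq_along(thresholds)) {
    out[!is.na(p) & p < thresholds[k]] <- names(thresholds)[k]
  }
  out
}

.as_tox_tbl <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("id", "log_ec50")
  if (!all(need %in% names(records)))
    stop("toxicity records need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  records
}

#' Correlate a toxicity endpoint with Ub
#'
#' Joins toxicity records to a Ub score table on compound id and computes
#' the Spearman correlation of `ub<n>` with log10 half-effect
#' concentration. A negative `rho` means more unbiological compounds are
#' toxic at lower concentrations.
#'
#' @param records Data frame with `id`, `log_ec50` and optionally
#'   `endpoint` columns.
#' @param ub A table from [ub_table()] (or any data frame with `id` and
#'   `ub<n>` columns).
#' @param n Which Ub variant to use (e.g. 5 for `ub5`).
#' @param thresholds Tier thresholds, see [significance_tier()].
#' @return A `ub_correlation` tibble: `endpoint`, `ub_n`, `n`, `rho`,
#'   `p_value`, `tier`.
#' @export
correlate_endpoint <- function(records, ub, n = 5L,
    thresholds = c("*" = 0.05, "**" = 0.01,
                   "***" = bonferroni_threshold(35L, 2L, 0.05))) {
  records <- .as_tox_tbl(records)
  col <- paste0("ub", n)
  if (!col %in% names(ub))
    stop("ub table has no column '", col, "'", call. = FALSE)
  joined <- dplyr::inner_join(
    dplyr::select(records, dplyr::all_of(c("id", "log_ec50")),
                  dplyr::any_of("endpoint")),
    dplyr::select(ub, dplyr::all_of(c("id", col))), by = "id")
  joined <- joined[is.finite(joined$log_ec50) & is.finite(joined[[col]]), ]
  if (nrow(joined) < 4L)
    stop("endpoint join produced ", nrow(joined), " usable rows (need 4): ",
         nrow(records), " records, ", nrow(ub), " scored compounds, ",
         length(intersect(records$id, ub$id)), " shared ids", call. = FALSE)
  sp <- suppressWarnings(spearman(joined[[col]], joined$log_ec50))
  out <- tibble::tibble(
    endpoint = if ("endpoint" %in% names(joined))
      as.character(joined$endpoint[1L]) else "endpoint",
    ub_n = as.integer(n), n = sp$n, rho = sp$rho, p_value = sp$p_value,
    tier = significance_tier(sp$p_value, thresholds))
  class(out) <- c("ub_correlation", class(out))
  out
}

#' @rdname correlate_endpoint
#' @param ns Ub variants to correlate (one result row each, per endpoint).
#' @export
correlate_endpoints <- function(records, ub, ns = c(5L, 6L),
    thresholds = c("*" = 0.05, "**" = 0.01,
                   "***" = bonferroni_threshold(35L, 2L, 0.05))) {
  records <- .as_tox_tbl(records)
  eps <- if ("endpoint" %in% names(records))
    split(records, records$endpoint) else list(endpoint = records)
  rows <- purrr::map(names(eps), function(ep) {
    purrr::map(ns, function(n) {
      res <- correlate_endpoint(eps[[ep]], ub, n, thresholds)
      res$endpoint <- ep
      res
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ub_correlation", class(out))
  out
}

#' Fisher-z confidence interval for a correlation
#'
#' @param rho Correlation estimate.
#' @param n Sample size (`n >= 4`).
#' @param level Confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
fisher_ci <- function(rho, n, level = 0.95) {
  if (is.na(rho) || n < 4L) return(c(NA_real_, NA_real_))
  z <- atanh(rho)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - hw, z + hw))
}

#' Potency-band correlation analysis
#'
#' Bins records into half-open potency bands `[lo, hi)` of log10
#' half-effect concentration (with open-ended extremes), and computes the
#' Ub rank correlation with a Fisher-z 95% confidence interval within
#' each band. Bands with fewer than 4 records report `NA` statistics.
#'
#' @inheritParams correlate_endpoint
#' @param edges Strictly increasing log10 cut points (default the round
#'   log-unit scheme `-4, -3, -2`).
#' @param level Confidence level for the per-band interval.
#' @return A `ub_bands` tibble: `band`, `lo`, `hi`, `n`, `rho`, `ci_lo`,
#'   `ci_hi`.
#' @export
band_analysis <- function(records, ub, n = 5L, edges = c(-4, -3, -2),
                          level = 0.95) {
  stopifnot(length(edges) >= 1L, !is.unsorted(edges, strictly = TRUE))
  records <- .as_tox_tbl(records)
  col <- paste0("ub", n)
  joined <- dplyr::inner_join(
    dplyr::select(records, dplyr::all_of(c("id", "log_ec50"))),
    dplyr::select(ub, dplyr::all_of(c("id", col))), by = "id")
  joined <- joined[is.finite(joined$log_ec50) & is.finite(joined[[col]]), ]
  lo <- c(-Inf, edges)
  hi <- c(edges, Inf)
  rows <- purrr::map(seq_along(lo), function(k) {
    inb <- joined$log_ec50 >= lo[k] & joined$log_ec50 < hi[k]
    nb <- sum(inb)
    lab <- paste0("[", format(lo[k]), ",", format(hi[k]), ")")
    if (nb < 4L ||
        length(unique(joined[[col]][inb])) == 1L ||
        length(unique(joined$log_ec50[inb])) == 1L) {
      return(tibble::tibble(band = lab, lo = lo[k], hi = hi[k], n = nb,
                            rho = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_))
    }
    sp <- spearman(joined[[col]][inb], joined$log_ec50[inb])
    ci <- fisher_ci(sp$rho, nb, level)
    tibble::tibble(band = lab, lo = lo[k], hi = hi[k], n = nb,
                   rho = sp$rho, ci_lo = ci[1L], ci_hi = ci[2L])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ub_bands", class(out))
  out
}

#' Hit-rate curve over log-concentration bins
#'
#' Fraction of test results that are active within each half-open
#' log10-concentration bin, using only the compounds tested in that bin
#' (a compound tested and inactive counts in the denominator only).
#'
#' @param tests Data frame with columns `concentration` (> 0, molar) and
#'   `active` (logical), one row per compound x tested concentration.
#' @param bin_width Bin width in log10 units (default 0.25).
#' @return A `ub_hit_curve` tibble: `bin_lo`, `bin_hi`, `bin_mid`,
#'   `n_tested`, `n_active`, `hit_rate`.
#' @export
hit_rate_curve <- function(tests, bin_width = 0.25) {
  stopifnot(is.data.frame(tests),
            all(c("concentration", "active") %in% names(tests)),
            all(tests$concentration > 0), bin_width > 0)
  lc <- log10(tests$concentration)
  bin <- floor(lc / bin_width)
  out <- tibble::tibble(bin = bin, active = as.logical(tests$active)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_tested = dplyr::n(),
                     n_active = sum(.data$active), .groups = "drop") |>
    dplyr::mutate(bin_lo = .data$bin * bin_width,
                  bin_hi = (.data$bin + 1) * bin_width,
                  bin_mid = (.data$bin + 0.5) * bin_width,
                  hit_rate = .data$n_active / .data$n_tested) |>
    dplyr::arrange(.data$bin_lo) |>
    dplyr::select("bin_lo", "bin_hi", "bin_mid", "n_tested", "n_active",
                  "hit_rate")
  class(out) <- c("ub_hit_curve", class(out))
  out
}
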