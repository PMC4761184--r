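# Molecule sets are plain tibbles with an `id` and a canonical `smiles`
# column, so they compose with dplyr verbs; a `provenance` attribute
# records where the set came from (enumerated | loaded | synthetic).

#' Build a molecule set
#'
#' Parses, canonicalizes and de-duplicates a collection of structures into
#' a molecule-set tibble (`id`, `smiles`).
#'
#' @param smiles Character vector of SMILES (names become ids) or a data
#'   frame with `smiles` and optionally `id` columns.
#' @param provenance One of `"loaded"`, `"enumerated"`, `"synthetic"`.
#' @param component Passed to [parse_smiles()] for multi-component input.
#' @return A tibble with columns `id`, `smiles` and attribute
#'   `provenance`; duplicates under canonicalization are dropped (first
#'   id wins).
#' @export
mol_set <- function(smiles, provenance = "loaded",
                    component = c("error", "largest")) {
  component <- match.arg(component)
  tb <- .as_mol_tbl(smiles)
  can <- vapply(tb$smiles, function(s)
    mol_to_smiles(parse_smiles(s, component = component)), character(1),
    USE.NAMES = FALSE)
  out <- tibble::tibble(id = tb$id, smiles = can)
  out <- out[!duplicated(out$smiles), ]
  attr(out, "provenance") <- provenance
  out
}

# Coerce to a tibble with id + smiles columns (no parsing).
.as_mol_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("mol%d", seq_along(x))
    return(tibble::tibble(id = ids, smiles = unname(x)))
  }
  if (is.data.frame(x)) {
    if (!"smiles" %in% names(x))
      stop("molecule table needs a 'smiles' column", call. = FALSE)
    id <- if ("id" %in% names(x)) as.character(x$id)
          else sprintf("mol%d", seq_len(nrow(x)))
    return(tibble::tibble(id = id, smiles = as.character(x$smiles)))
  }
  stop("cannot interpret molecule set of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# Coerce to a list of molgraphs.
.as_graph_list <- function(x) {
  if (inherits(x, "molgraph")) return(list(x))
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "molgraph"))) return(x)
  tb <- .as_mol_tbl(x)
  lapply(tb$smiles, parse_structure, component = "largest")
}
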