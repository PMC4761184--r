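# Fragment pools by iterated MCS closure, and fragment-count descriptors.

#' All n-atom fragments of a molecule set
#'
#' Breaks every molecule into its connected `n`-atom subgraphs (atoms plus
#' a chosen bond subset, the same semantics as all matching in unbio) and
#' returns the distinct canonical fragments. This is the fragment set the
#' Ub score is defined against, computed by direct enumeration — it is
#' deliberately not restricted to fragments occurring in two or more
#' molecules.
#'
#' @param molecules Molecule set (data frame with `smiles`, character
#'   vector, or list of molgraphs).
#' @param n Fragment size (heavy atoms), `n >= 1`.
#' @return A tibble with a single `fragment` column of canonical SMILES,
#'   sorted.
#' @export
n_atom_fragments <- function(molecules, n) {
  stopifnot(n >= 1L)
  gs <- .as_graph_list(molecules)
  frags <- unique(unlist(lapply(gs, .n_atom_subgraph_smiles, n = n)))
  tibble::tibble(fragment = sort(frags, method = "radix"))
}

#' Fragment pool by MCS closure
#'
#' For each pair of molecules the maximum common subgraph is computed;
#' the MCS of every pair of resulting fragments, and of every fragment
#' with every molecule, is then added, iterating until no new fragment
#' appears. Fragments of fewer than 3 atoms are ignored, and every pool
#' member necessarily occurs in at least two source molecules.
#'
#' @param molecules Molecule set (>= 2 molecules; a single molecule yields
#'   an empty pool with a warning).
#' @param max_frag_size Largest fragment retained (default 14).
#' @return A `ub_fragment_pool`: a tibble with columns `fragment`
#'   (canonical SMILES), `size` (heavy atoms) and `n_molecules` (number of
#'   source molecules containing the fragment), sorted by size then
#'   fragment.
#' @export
generate_fragment_pool <- function(molecules, max_frag_size = 14L) {
  gs <- .as_graph_list(molecules)
  if (length(gs) < 2L) {
    warning("fragment pools need at least two molecules; returning an ",
            "empty pool")
    out <- tibble::tibble(fragment = character(0), size = integer(0),
                          n_molecules = integer(0))
    class(out) <- c("ub_fragment_pool", class(out))
    return(out)
  }
  pool <- new.env(parent = emptyenv())
  admit <- function(f) {
    sz <- heavy_atoms(f)
    if (sz < 3L || sz > max_frag_size) return(NULL)
    smi <- mol_to_smiles(f)
    if (!is.null(pool[[smi]])) return(NULL)
    pool[[smi]] <- f
    smi
  }
  # seed: pairwise molecule MCS
  newly <- character(0)
  nmol <- length(gs)
  for (i in seq_len(nmol - 1L)) for (j in (i + 1L):nmol) {
    s <- admit(max_common_subgraph(gs[[i]], gs[[j]]))
    if (!is.null(s)) newly <- c(newly, s)
  }
  # closure: fragment x fragment and fragment x molecule MCS, iterated in
  # canonical order until fixed point
  while (length(newly) > 0L) {
    newly <- sort(newly, method = "radix")
    existing <- sort(ls(pool, sorted = FALSE), method = "radix")
    added <- character(0)
    for (fs in newly) {
      f <- pool[[fs]]
      for (os in existing) {
        s <- admit(max_common_subgraph(f, pool[[os]]))
        if (!is.null(s)) added <- c(added, s)
      }
      for (g in gs) {
        s <- admit(max_common_subgraph(f, g))
        if (!is.null(s)) added <- c(added, s)
      }
    }
    newly <- added
  }
  frags <- sort(ls(pool, sorted = FALSE), method = "radix")
  occ <- vapply(frags, function(fs) {
    pl <- .match_plan(pool[[fs]])
    sum(vapply(gs, function(g)
      .match_search(pl, .target_index(g), collect = FALSE), logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    fragment = frags,
    size = vapply(frags, function(fs) heavy_atoms(pool[[fs]]), integer(1),
                  USE.NAMES = FALSE),
    n_molecules = occ
  )
  out <- out[order(out$size, out$fragment, method = "radix"), ]
  class(out) <- c("ub_fragment_pool", class(out))
  out
}

#' Fragment-count descriptors
#'
#' A descriptor is the integral count of occurrences of a pool fragment in
#' a molecule (distinct matched atom/bond subsets, see
#' [count_embeddings()]). Returns the descriptor matrix for a molecule
#' set: one row per molecule, one column per pool fragment in pool order.
#'
#' @param molecules Molecule set.
#' @param pool A fragment pool from [generate_fragment_pool()], or a
#'   tibble/character vector of fragment SMILES.
#' @return A tibble: `id`, `smiles`, then one integer column per fragment
#'   (named by its canonical SMILES).
#' @export
describe_molecules <- function(molecules, pool) {
  frags <- if (is.data.frame(pool)) pool$fragment else as.character(pool)
  if (length(frags) == 0L) stop("fragment pool is empty", call. = FALSE)
  tb <- .as_mol_tbl(molecules)
  gs <- lapply(tb$smiles, parse_structure, component = "largest")
  counts <- lapply(frags, function(fs) {
    vapply(gs, function(g) count_embeddings(fs, g), integer(1))
  })
  names(counts) <- frags
  dplyr::bind_cols(
    tibble::tibble(id = tb$id,
                   smiles = vapply(gs, mol_to_smiles, character(1))),
    tibble::as_tibble(counts, .name_repair = "minimal")
  )
}
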