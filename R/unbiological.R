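# The UnBiological score Ub_N.
#
# Ub_N of a test molecule against a metabolite reference set is the heavy-
# atom count of the largest connected region of the molecule none of whose
# connected N-atom subgraphs occurs in any metabolite. A region is a
# connected subgraph (atoms plus a chosen subset of bonds, the same
# semantics as fragment matching). Regions smaller than N are scored 0:
# a region with no N-atom subgraph satisfies the condition vacuously,
# which would otherwise give every molecule a floor of N-1; with the
# |region| >= N convention metabolites themselves score 0, as intended.

# Decide which n-atom subgraphs of `g` are "biological": a subgraph S is
# in the metabolite n-fragment set iff S embeds in some metabolite.
.biological_masks <- function(g, met_graphs, n) {
  sub <- .n_atom_subgraphs(g, n)
  if (length(sub$masks) == 0L) return(integer(0))
  met_graphs <- met_graphs[vapply(met_graphs, heavy_atoms, integer(1)) >= n]
  if (length(met_graphs) == 0L) return(integer(0))
  tis <- lapply(met_graphs, .target_index)
  cache <- new.env(parent = emptyenv())
  bio <- vapply(seq_along(sub$masks), function(k) {
    smi <- mol_to_smiles(sub$graphs[[k]])
    hit <- cache[[smi]]
    if (is.null(hit)) {
      plan <- .match_plan(sub$graphs[[k]])
      hit <- FALSE
      for (ti in tis) {
        if (.match_search(plan, ti, collect = FALSE)) { hit <- TRUE; break }
      }
      cache[[smi]] <- hit
    }
    hit
  }, logical(1))
  sub$masks[bio]
}

# Branch-and-bound over bond removals: the largest connected bond subset
# containing no biological n-subgraph is found by repeatedly branching on
# the bonds of some violated biological subgraph.
.ub_search <- function(g, bio_masks, n) {
  m <- nrow(g$bond)
  b <- g$bond
  full <- if (m == 0L) 0L else bitwShiftL(1L, m) - 1L
  if (m >= 31L) stop("molecule has too many bonds for Ub scoring (max 30)",
                     call. = FALSE)
  bio_edges <- lapply(bio_masks, function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
  })
  best <- 0L
  seen <- new.env(parent = emptyenv())

  natoms_of <- function(edges) length(unique(c(b[edges, 1L], b[edges, 2L])))

  # connected components of an edge subset, as lists of edge vectors
  comps_of <- function(edges) {
    if (length(edges) == 0L) return(list())
    atoms <- unique(c(b[edges, 1L], b[edges, 2L]))
    parent <- seq_along(atoms)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in edges) {
      i <- find(match(b[e, 1L], atoms)); j <- find(match(b[e, 2L], atoms))
      if (i != j) parent[i] <- j
    }
    root <- vapply(seq_along(atoms), find, integer(1))
    er <- root[match(b[edges, 1L], atoms)]
    split(edges, er)
  }

  solve <- function(edges) {
    for (comp in comps_of(edges)) {
      na <- natoms_of(comp)
      if (na <= best || na < n) next
      mask <- sum(bitwShiftL(1L, comp - 1L))
      key <- as.character(mask)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      viol <- 0L
      for (i in seq_along(bio_masks)) {
        if (bitwAnd(bio_masks[[i]], mask) == bio_masks[[i]]) { viol <- i; break }
      }
      if (viol == 0L) {
        best <<- max(best, na)
      } else {
        for (e in bio_edges[[viol]]) solve(setdiff(comp, e))
      }
    }
    invisible()
  }
  solve(seq_len(m))
  best
}

#' UnBiological score of a molecule
#'
#' Computes `Ub_n`: the heavy-atom count of the largest connected region
#' of `molecule` that contains no connected `n`-atom fragment found in the
#' metabolite reference set. Metabolites themselves score 0; a molecule
#' whose every `n`-atom subgraph is absent from the reference scores its
#' full heavy-atom count. Molecules with fewer than `n` atoms score 0 by
#' convention, as do regions smaller than `n`.
#'
#' `ub_score_oracle()` has the identical contract but computes the value
#' by explicit enumeration of all connected subgraphs of the molecule,
#' checking each against the canonical metabolite fragment set. It exists
#' as an independent ground truth for testing and refuses molecules of
#' more than 14 heavy atoms.
#'
#' @param molecule A [molgraph] or SMILES string (connected; split salts
#'   upstream, e.g. with `parse_structure(component = "largest")`).
#' @param metabolites Metabolite reference set: a character vector of
#'   SMILES, a data frame with a `smiles` column, or a list of molgraphs.
#' @param n Fragment size defining the overlap (the study uses 5 and 6;
#'   small toy reference sets pair naturally with n = 3).
#' @return An integer score.
#' @export
ub_score <- function(molecule, metabolites, n = 5L) {
  stopifnot(n >= 2L)
  g <- .as_molgraph(molecule)
  if (!is_connected_mol(g))
    stop("molecule is disconnected; split salts/mixtures upstream",
         call. = FALSE)
  if (heavy_atoms(g) < n) return(0L)
  met <- .as_graph_list(metabolites)
  if (length(met) == 0L) stop("metabolite set is empty", call. = FALSE)
  bio <- .biological_masks(g, met, n)
  .ub_search(g, bio, n)
}

#' @rdname ub_score
#' @export
ub_score_oracle <- function(molecule, metabolites, n = 5L) {
  stopifnot(n >= 2L)
  g <- .as_molgraph(molecule)
  if (!is_connected_mol(g))
    stop("molecule is disconnected; split salts/mixtures upstream",
         call. = FALSE)
  if (heavy_atoms(g) > 14L)
    stop("oracle limited to molecules of at most 14 heavy atoms",
         call. = FALSE)
  if (heavy_atoms(g) < n) return(0L)
  met <- .as_graph_list(metabolites)
  if (length(met) == 0L) stop("metabolite set is empty", call. = FALSE)
  bio_set <- unlist(lapply(met, .n_atom_subgraph_smiles, n = n))

  sub <- .n_atom_subgraphs(g, n)
  bio_masks <- sub$masks[vapply(sub$graphs, function(s)
    mol_to_smiles(s) %in% bio_set, logical(1))]

  all_subs <- .connected_edge_subsets(g)
  ord <- order(-all_subs$natoms)
  for (k in ord) {
    na <- all_subs$natoms[k]
    if (na < n) break
    mask <- all_subs$masks[k]
    ok <- TRUE
    for (bm in bio_masks) {
      if (bitwAnd(bm, mask) == bm) { ok <- FALSE; break }
    }
    if (ok) return(na)
  }
  0L
}

#' Ub scores for a molecule table
#'
#' Batch driver: computes `Ub_n` for every molecule and every requested
#' fragment size, returning a tibble with one row per molecule and one
#' `ub<n>` column per size (e.g. `ub5`, `ub6`). Molecules that fail to
#' parse or score are reported with `NA` scores and a message in the
#' `note` column rather than aborting the run.
#'
#' @param molecules A data frame with `id` and `smiles` columns, or a
#'   character vector of SMILES.
#' @param metabolites Metabolite reference set (see [ub_score()]).
#' @param ns Integer vector of fragment sizes.
#' @return A tibble with columns `id`, `smiles` (canonical),
#'   `heavy_atoms`, one `ub<n>` column per size, and `note`.
#' @export
ub_table <- function(molecules, metabolites, ns = c(5L, 6L)) {
  stopifnot(length(ns) >= 1L)
  mols <- .as_mol_tbl(molecules)
  met <- .as_graph_list(metabolites)
  rows <- purrr::map(seq_len(nrow(mols)), function(i) {
    out <- list(id = mols$id[i], smiles = NA_character_,
                heavy_atoms = NA_integer_, note = NA_character_)
    for (n in ns) out[[paste0("ub", n)]] <- NA_integer_
    tryCatch({
      g <- parse_structure(mols$smiles[i], component = "largest")
      out$smiles <- mol_to_smiles(g)
      out$heavy_atoms <- heavy_atoms(g)
      for (n in ns) out[[paste0("ub", n)]] <- ub_score(g, met, n)
    }, error = function(e) out$note <<- conditionMessage(e))
    tibble::as_tibble(out)
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate("note", .after = dplyr::last_col())
}
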