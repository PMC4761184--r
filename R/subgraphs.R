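# Exhaustive enumeration of connected subgraphs. A connected subgraph is
# identified with a subset of bonds (plus, for size one, a single atom):
# its atoms are the bond endpoints. Edge subsets, not only node-induced
# subgraphs, are enumerated, because a fragment may omit a ring-closing
# bond that the parent molecule has.

# All connected bond subsets of g (as integer bitmasks over bond rows),
# optionally keeping only those spanning at most `max_atoms` atoms.
# Returns a list with `masks` (integer vector), `edges` (list of integer
# vectors), `natoms` (integer vector).
.connected_edge_subsets <- function(g, max_atoms = Inf, max_subsets = 500000L) {
  m <- nrow(g$bond)
  out_masks <- integer(0)
  out_edges <- list()
  out_natoms <- integer(0)
  if (m == 0L) return(list(masks = out_masks, edges = out_edges,
                           natoms = out_natoms))
  if (m > 30L)
    stop("molecule has ", m, " bonds; connected-subgraph enumeration is ",
         "limited to 30", call. = FALSE)
  b <- g$bond
  # edges adjacent to each edge (sharing an endpoint)
  A <- length(g$elem)
  at_edges <- vector("list", A)
  for (r in seq_len(m)) {
    at_edges[[b[r, 1L]]] <- c(at_edges[[b[r, 1L]]], r)
    at_edges[[b[r, 2L]]] <- c(at_edges[[b[r, 2L]]], r)
  }
  seen <- new.env(parent = emptyenv())
  queue_masks <- integer(0)
  queue_edges <- list()

  push <- function(mask, edges) {
    key <- as.character(mask)
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    atoms <- unique(c(b[edges, 1L], b[edges, 2L]))
    if (length(atoms) > max_atoms) return(invisible())
    out_masks[length(out_masks) + 1L] <<- mask
    out_edges[[length(out_edges) + 1L]] <<- edges
    out_natoms[length(out_natoms) + 1L] <<- length(atoms)
    queue_masks[length(queue_masks) + 1L] <<- mask
    queue_edges[[length(queue_edges) + 1L]] <<- edges
    if (length(out_masks) > max_subsets)
      stop("more than ", max_subsets, " connected subgraphs; refusing",
           call. = FALSE)
    invisible()
  }
  for (r in seq_len(m)) push(bitwShiftL(1L, r - 1L), r)

  head <- 1L
  while (head <= length(queue_masks)) {
    mask <- queue_masks[[head]]
    edges <- queue_edges[[head]]
    head <- head + 1L
    atoms <- unique(c(b[edges, 1L], b[edges, 2L]))
    cand <- setdiff(unique(unlist(at_edges[atoms])), edges)
    for (e in cand) push(bitwOr(mask, bitwShiftL(1L, e - 1L)), sort(c(edges, e)))
  }
  list(masks = out_masks, edges = out_edges, natoms = out_natoms)
}

# All distinct connected n-atom subgraphs of one molgraph, as canonical
# SMILES. For n = 1 these are the element symbols present.
.n_atom_subgraph_smiles <- function(g, n) {
  if (heavy_atoms(g) < n) return(character(0))
  if (n == 1L) {
    return(sort(unique(vapply(unique(g$elem), function(e)
      mol_to_smiles(molgraph(e, validate = FALSE)), character(1)))))
  }
  subs <- .connected_edge_subsets(g, max_atoms = n)
  keep <- which(subs$natoms == n)
  if (length(keep) == 0L) return(character(0))
  sort(unique(vapply(keep, function(k) {
    mol_to_smiles(.subgraph_bonds(g, subs$edges[[k]]))
  }, character(1))))
}

# As above but returning masks and graphs (not deduplicated), for Ub.
.n_atom_subgraphs <- function(g, n) {
  if (heavy_atoms(g) < n || n < 2L) {
    return(list(masks = integer(0), graphs = list()))
  }
  subs <- .connected_edge_subsets(g, max_atoms = n)
  keep <- which(subs$natoms == n)
  list(masks = subs$masks[keep],
       graphs = lapply(subs$edges[keep], function(e) .subgraph_bonds(g, e)))
}
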