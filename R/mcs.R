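#' Maximum common subgraph
#'
#' Finds a largest connected substructure shared by two molecules or
#' fragments, matching on element labels and bond orders. The search
#' enumerates the connected subgraphs of the smaller argument in
#' decreasing atom count and returns the first that embeds in the other;
#' ties at the maximal size are broken deterministically by canonical
#' SMILES order. The result is empty (zero atoms) when the two structures
#' share no element.
#'
#' @param a,b [molgraph] objects or SMILES strings.
#' @return A [molgraph] fragment (possibly with zero atoms).
#' @export
max_common_subgraph <- function(a, b) {
  a <- .as_molgraph(a)
  b <- .as_molgraph(b)
  if (heavy_atoms(a) > heavy_atoms(b)) { tmp <- a; a <- b; b <- tmp }
  if (heavy_atoms(a) == 0L) return(molgraph(character(0), validate = FALSE))
  shared <- intersect(unique(a$elem), unique(b$elem))
  if (length(shared) == 0L) return(molgraph(character(0), validate = FALSE))

  if (heavy_atoms(a) >= 2L && nrow(a$bond) > 0L) {
    subs <- .connected_edge_subsets(a)
    ord <- order(-subs$natoms)
    sizes <- unique(subs$natoms[ord])
    ti <- .target_index(b)
    for (s in sizes) {
      idx <- which(subs$natoms == s)
      frag <- lapply(subs$edges[idx], function(e) .subgraph_bonds(a, e))
      smi <- vapply(frag, mol_to_smiles, character(1))
      keep <- !duplicated(smi)
      frag <- frag[keep]; smi <- smi[keep]
      o <- order(smi)
      for (k in o) {
        if (.match_search(.match_plan(frag[[k]]), ti, collect = FALSE)) {
          return(.canonicalize(frag[[k]]))
        }
      }
    }
  }
  # fall back to single shared atom
  molgraph(sort(shared)[1L], validate = FALSE)
}

#' @rdname max_common_subgraph
#' @export
mcs_size <- function(a, b) heavy_atoms(max_common_subgraph(a, b))
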