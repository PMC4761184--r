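# Substructure matching: backtracking search for monomorphisms (injective
# mappings preserving element labels and bond orders; extra bonds among
# matched target atoms are allowed, as in standard chemical substructure
# semantics). Hydrogens and open valences are never constrained.

# Precompute matching order for the pattern: a DFS order in which every
# atom after the first is bonded to an earlier atom, plus for each atom the
# list of (earlier position, bond order) constraints.
.match_plan <- function(p) {
  A <- length(p$elem)
  adj <- .adjacency(p)
  ord <- integer(0)
  placed <- logical(A)
  # start at the rarest element to cut branching a little
  start <- order(p$elem)[1L]
  stack <- start
  while (length(stack) > 0L) {
    a <- stack[[1L]]; stack <- stack[-1L]
    if (placed[a]) next
    placed[a] <- TRUE
    ord <- c(ord, a)
    nb <- adj[[a]][, 1L]
    stack <- c(nb[!placed[nb]], stack)
  }
  if (length(ord) < A)
    stop("pattern must be connected", call. = FALSE)
  pos <- match(seq_len(A), ord)
  constraints <- lapply(seq_len(A), function(k) {
    a <- ord[k]
    mm <- adj[[a]]
    if (nrow(mm) == 0L) return(matrix(integer(0), 0L, 2L))
    earlier <- mm[pos[mm[, 1L]] < k, , drop = FALSE]
    cbind(pos[earlier[, 1L]], earlier[, 2L])
  })
  deg <- vapply(adj, nrow, integer(1))
  list(ord = ord, constraints = constraints, elem = p$elem[ord],
       deg = deg[ord])
}

# Dense bond-order lookup and adjacency for the target.
.target_index <- function(t) {
  A <- length(t$elem)
  bo <- matrix(0L, A, A)
  eid <- matrix(0L, A, A)
  b <- t$bond
  if (nrow(b) > 0L) {
    for (r in seq_len(nrow(b))) {
      bo[b[r, 1L], b[r, 2L]] <- b[r, 3L]
      bo[b[r, 2L], b[r, 1L]] <- b[r, 3L]
      eid[b[r, 1L], b[r, 2L]] <- r
      eid[b[r, 2L], b[r, 1L]] <- r
    }
  }
  adj <- .adjacency(t)
  deg <- vapply(adj, nrow, integer(1))
  list(bo = bo, eid = eid, adj = adj, deg = deg, elem = t$elem)
}

# Core search. `collect` = FALSE: return TRUE on first embedding.
# `collect` = TRUE: return list of mappings (target atom per pattern
# position in plan order).
.match_search <- function(plan, ti, collect = FALSE) {
  K <- length(plan$ord)
  used <- logical(length(ti$elem))
  map <- integer(K)
  found <- list()
  hit <- FALSE

  place <- function(k) {
    if (hit && !collect) return(invisible())
    if (k > K) {
      if (collect) found[[length(found) + 1L]] <<- map
      hit <<- TRUE
      return(invisible())
    }
    cons <- plan$constraints[[k]]
    cands <- if (k == 1L) {
      which(ti$elem == plan$elem[1L] & ti$deg >= plan$deg[1L])
    } else {
      anchor <- map[cons[1L, 1L]]
      mm <- ti$adj[[anchor]]
      mm[mm[, 2L] == cons[1L, 2L], 1L]
    }
    for (c_ in cands) {
      if (used[c_]) next
      if (ti$elem[c_] != plan$elem[k]) next
      if (ti$deg[c_] < plan$deg[k]) next
      ok <- TRUE
      if (nrow(cons) > 1L) {
        for (r in 2:nrow(cons)) {
          if (ti$bo[map[cons[r, 1L]], c_] != cons[r, 2L]) { ok <- FALSE; break }
        }
      }
      if (!ok) next
      used[c_] <<- TRUE
      map[k] <<- c_
      place(k + 1L)
      used[c_] <<- FALSE
      if (hit && !collect) return(invisible())
    }
    invisible()
  }
  place(1L)
  if (collect) found else hit
}

.as_molgraph <- function(x) {
  if (inherits(x, "molgraph")) x else parse_structure(x)
}

#' Substructure test and embedding counts
#'
#' `is_subgraph()` reports whether `pattern` (a fragment) occurs in
#' `target`: whether an injective mapping of the pattern's atoms onto
#' target atoms exists that preserves element labels and bond orders.
#' `count_embeddings()` counts the distinct matched atom-plus-bond subsets
#' of the target; automorphic re-mappings onto the same atoms and bonds
#' count once, so a symmetric pattern is not multiply counted.
#'
#' @param pattern,target [molgraph] objects or SMILES strings. The pattern
#'   must be connected.
#' @return `is_subgraph()`: a logical flag. `count_embeddings()`: an
#'   integer count.
#' @export
is_subgraph <- function(pattern, target) {
  p <- .as_molgraph(pattern)
  t <- .as_molgraph(target)
  if (heavy_atoms(p) > heavy_atoms(t)) return(FALSE)
  .match_search(.match_plan(p), .target_index(t), collect = FALSE)
}

#' @rdname is_subgraph
#' @export
count_embeddings <- function(pattern, target) {
  p <- .as_molgraph(pattern)
  t <- .as_molgraph(target)
  if (heavy_atoms(p) > heavy_atoms(t)) return(0L)
  plan <- .match_plan(p)
  ti <- .target_index(t)
  maps <- .match_search(plan, ti, collect = TRUE)
  if (length(maps) == 0L) return(0L)
  # distinct atom + bond subsets
  pb <- p$bond
  ppos <- match(seq_len(heavy_atoms(p)), plan$ord)
  keys <- vapply(maps, function(mp) {
    atoms <- sort(mp)
    eids <- if (nrow(pb) > 0L) {
      sort(vapply(seq_len(nrow(pb)), function(r) {
        ti$eid[mp[ppos[pb[r, 1L]]], mp[ppos[pb[r, 2L]]]]
      }, integer(1)))
    } else integer(0)
    paste(paste(atoms, collapse = ","), paste(eids, collapse = ","), sep = "|")
  }, character(1))
  length(unique(keys))
}
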