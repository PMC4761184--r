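#' Molecular graph objects
#'
#' A `molgraph` is the unit of all matching in unbio: a hydrogen-suppressed
#' 2-D molecular graph with element-labelled atoms and bonds of order 1, 2
#' or 3. Hydrogens are always implicit: every valence not used by an
#' explicit bond is assumed to be filled with hydrogen. Fragments (partial
#' structures with open valences) use the same representation; the
#' distinction is purely semantic, since matching ignores hydrogens.
#'
#' @param elem Character vector of element symbols, one per heavy atom.
#' @param bond Integer matrix with one row per bond and columns
#'   `i`, `j`, `order` (1-based atom indices, order in 1..3).
#' @param validate Check valence and connectivity invariants.
#'
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(elem, bond = NULL, validate = TRUE) {
  elem <- as.character(elem)
  if (is.null(bond) || length(bond) == 0L) {
    bond <- matrix(integer(0), nrow = 0L, ncol = 3L)
  }
  bond <- matrix(as.integer(bond), ncol = 3L)
  colnames(bond) <- c("i", "j", "order")
  # store bonds with i < j, sorted
  if (nrow(bond) > 0L) {
    swap <- bond[, 1L] > bond[, 2L]
    bond[swap, 1:2] <- bond[swap, 2:1]
    bond <- bond[order(bond[, 1L], bond[, 2L]), , drop = FALSE]
  }
  g <- structure(list(elem = elem, bond = bond), class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

#' @rdname molgraph
#' @param g A `molgraph`.
#' @export
validate_molgraph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  A <- length(g$elem)
  b <- g$bond
  .elem_code(g$elem)
  if (nrow(b) > 0L) {
    if (any(b[, 1L] < 1L | b[, 2L] < 1L | b[, 1L] > A | b[, 2L] > A))
      stop("bond refers to atom index out of range", call. = FALSE)
    if (any(b[, 1L] == b[, 2L]))
      stop("self-bonds are not allowed", call. = FALSE)
    key <- paste(b[, 1L], b[, 2L])
    if (anyDuplicated(key))
      stop("parallel bonds are not allowed", call. = FALSE)
    if (!all(b[, 3L] %in% 1:3))
      stop("bond orders must be 1, 2 or 3", call. = FALSE)
  }
  bs <- bond_order_sums(g)
  over <- which(vapply(seq_len(A), function(a) {
    bs[a] > .elem_max_valence(g$elem[a])
  }, logical(1)))
  if (length(over) > 0L) {
    stop("valence exceeded at atom index ", over[1L], " (",
         g$elem[over[1L]], ", bond order sum ", bs[over[1L]], ")",
         call. = FALSE)
  }
  invisible(g)
}

#' @rdname molgraph
#' @export
heavy_atoms <- function(g) length(g$elem)

# Per-atom sum of bond orders.
bond_order_sums <- function(g) {
  A <- length(g$elem)
  bs <- integer(A)
  b <- g$bond
  if (nrow(b) > 0L) {
    for (r in seq_len(nrow(b))) {
      bs[b[r, 1L]] <- bs[b[r, 1L]] + b[r, 3L]
      bs[b[r, 2L]] <- bs[b[r, 2L]] + b[r, 3L]
    }
  }
  bs
}

# Remaining valence per atom against the element's maximum allowed state.
free_valences <- function(g) {
  bs <- bond_order_sums(g)
  vapply(seq_along(g$elem), function(a) {
    .elem_max_valence(g$elem[a]) - bs[a]
  }, integer(1))
}

#' @rdname molgraph
#' @export
implicit_hydrogens <- function(g) {
  bs <- bond_order_sums(g)
  vapply(seq_along(g$elem), function(a) {
    h <- .implicit_h(g$elem[a], bs[a])
    if (is.na(h)) 0L else h
  }, integer(1))
}

# Adjacency list: for each atom, integer matrix (nbr, order, bond_row).
.adjacency <- function(g) {
  A <- length(g$elem)
  adj <- vector("list", A)
  for (a in seq_len(A)) adj[[a]] <- matrix(integer(0), 0L, 3L)
  b <- g$bond
  if (nrow(b) > 0L) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1L]; j <- b[r, 2L]; o <- b[r, 3L]
      adj[[i]] <- rbind(adj[[i]], c(j, o, r))
      adj[[j]] <- rbind(adj[[j]], c(i, o, r))
    }
  }
  adj
}

# Connected components as a list of atom-index vectors.
.components <- function(g) {
  A <- length(g$elem)
  if (A == 0L) return(list())
  adj <- .adjacency(g)
  comp <- integer(A)
  k <- 0L
  for (s in seq_len(A)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0L) {
      a <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[a]][, 1L]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  split(seq_len(A), comp)
}

#' @rdname molgraph
#' @export
is_connected_mol <- function(g) length(.components(g)) <= 1L

# Extract the subgraph induced by `atoms` (keeping all bonds among them),
# reindexed to 1..length(atoms).
.subgraph_atoms <- function(g, atoms) {
  atoms <- sort(atoms)
  idx <- match(seq_along(g$elem), atoms)
  b <- g$bond
  keep <- b[, 1L] %in% atoms & b[, 2L] %in% atoms
  nb <- b[keep, , drop = FALSE]
  if (nrow(nb) > 0L) {
    nb[, 1L] <- idx[nb[, 1L]]
    nb[, 2L] <- idx[nb[, 2L]]
  }
  molgraph(g$elem[atoms], nb, validate = FALSE)
}

# Build a molgraph from a subset of bond rows (atoms = endpoints).
.subgraph_bonds <- function(g, bond_rows) {
  b <- g$bond[bond_rows, , drop = FALSE]
  atoms <- sort(unique(c(b[, 1L], b[, 2L])))
  idx <- match(seq_along(g$elem), atoms)
  b[, 1L] <- idx[b[, 1L]]
  b[, 2L] <- idx[b[, 2L]]
  molgraph(g$elem[atoms], b, validate = FALSE)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", heavy_atoms(x), " heavy atoms, ", nrow(x$bond),
      " bonds: ", mol_to_smiles(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.molgraph <- function(x, ...) mol_to_smiles(x)
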