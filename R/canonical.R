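# Canonicalization and SMILES output.
#
# A unique atom ordering is obtained from a BLISS canonical labeling
# (igraph) of a vertex-coloured encoding of the molecular graph: atoms are
# coloured by element, and every bond is subdivided through an auxiliary
# vertex coloured by bond order, which lets the vertex-colour-only
# canonical form see edge labels. Two molgraphs are equal iff their
# canonical SMILES strings are equal.

.canonical_order <- function(g) {
  A <- length(g$elem)
  if (A == 1L) return(1L)
  m <- nrow(g$bond)
  codes <- .elem_code(g$elem)
  if (m == 0L) stop("disconnected multi-atom graph cannot be canonicalized",
                    call. = FALSE)
  ed <- integer(4L * m)
  for (r in seq_len(m)) {
    k <- 4L * (r - 1L)
    ed[k + 1L] <- g$bond[r, 1L]; ed[k + 2L] <- A + r
    ed[k + 3L] <- g$bond[r, 2L]; ed[k + 4L] <- A + r
  }
  ig <- igraph::make_graph(ed, n = A + m, directed = FALSE)
  colors <- c(codes, 1000L + g$bond[, 3L])
  lab <- igraph::canonical_permutation(ig, colors = colors)$labeling
  order(lab[seq_len(A)])
}

# Return g with atoms permuted into canonical order.
.canonicalize <- function(g) {
  ord <- .canonical_order(g)
  rank <- match(seq_along(ord), ord)
  b <- g$bond
  if (nrow(b) > 0L) {
    b[, 1L] <- rank[b[, 1L]]
    b[, 2L] <- rank[b[, 2L]]
  }
  molgraph(g$elem[ord], b, validate = FALSE)
}

.atom_token <- function(sym, h) {
  if (sym %in% .UB_ORGANIC_SUBSET) return(sym)
  hs <- if (h <= 0L) "" else if (h == 1L) "H" else paste0("H", h)
  paste0("[", sym, hs, "]")
}

.bond_sym <- c("", "=", "#")

# Deterministic SMILES writer: DFS from atom 1, neighbours in index order.
# Assumes atoms are already in the desired (e.g. canonical) order.
.write_smiles <- function(g) {
  A <- length(g$elem)
  if (A == 0L) return("")
  hh <- implicit_hydrogens(g)
  if (A == 1L) return(.atom_token(g$elem[1L], hh[1L]))
  adj <- .adjacency(g)
  adj <- lapply(adj, function(mm) mm[order(mm[, 1L]), , drop = FALSE])

  visited <- logical(A)
  used <- logical(nrow(g$bond))
  children <- vector("list", A)   # rows (child, order)
  ringmarks <- vector("list", A)  # rows (digit, order, open)
  visit_order <- integer(0)

  # pass 1: DFS tree + ring-closure digit assignment. Each ring bond gets
  # a distinct digit (no reuse: molecules in scope have few rings).
  next_digit <- 0L
  visited[1L] <- TRUE
  dfs <- function(u) {
    visit_order <<- c(visit_order, u)
    mm <- adj[[u]]
    for (r in seq_len(nrow(mm))) {
      v <- mm[r, 1L]; o <- mm[r, 2L]; e <- mm[r, 3L]
      if (used[e]) next
      if (!visited[v]) {
        used[e] <<- TRUE
        visited[v] <<- TRUE
        children[[u]] <<- rbind(children[[u]], c(v, o))
        dfs(v)
      } else {
        used[e] <<- TRUE
        next_digit <<- next_digit + 1L
        if (next_digit > 99L) stop("too many ring bonds", call. = FALSE)
        ringmarks[[v]] <<- rbind(ringmarks[[v]], c(next_digit, o, 1L))
        ringmarks[[u]] <<- rbind(ringmarks[[u]], c(next_digit, o, 0L))
      }
    }
  }
  dfs(1L)

  ringtok <- function(u) {
    rm_ <- ringmarks[[u]]
    if (is.null(rm_)) return("")
    rm_ <- rm_[order(rm_[, 1L]), , drop = FALSE]
    paste(vapply(seq_len(nrow(rm_)), function(k) {
      d <- rm_[k, 1L]
      paste0(.bond_sym[rm_[k, 2L]], if (d < 10L) d else paste0("%", d))
    }, character(1)), collapse = "")
  }

  emit <- function(u) {
    out <- paste0(.atom_token(g$elem[u], hh[u]), ringtok(u))
    ch <- children[[u]]
    if (!is.null(ch) && nrow(ch) > 0L) {
      k <- nrow(ch)
      if (k > 1L) {
        for (r in seq_len(k - 1L)) {
          out <- paste0(out, "(", .bond_sym[ch[r, 2L]], emit(ch[r, 1L]), ")")
        }
      }
      out <- paste0(out, .bond_sym[ch[k, 2L]], emit(ch[k, 1L]))
    }
    out
  }
  emit(1L)
}

#' Canonical SMILES output
#'
#' Writes a `molgraph` as a deterministic canonical SMILES string (always
#' kekulized; hydrogens implicit). Two molgraphs represent the same
#' 2-D structure iff their canonical SMILES are identical.
#'
#' @param g A [molgraph].
#' @param canonical If `FALSE`, write in the stored atom order instead of
#'   the canonical one.
#' @return A SMILES string.
#' @export
mol_to_smiles <- function(g, canonical = TRUE) {
  if (heavy_atoms(g) == 0L) return("")
  if (canonical) g <- .canonicalize(g)
  .write_smiles(g)
}

#' @rdname mol_to_smiles
#' @param text A SMILES string.
#' @param component Passed to [parse_smiles()].
#' @export
canonical_smiles <- function(text, component = c("error", "largest", "all")) {
  component <- match.arg(component)
  cache <- .ub_cache$canon
  if (component == "error" && !is.null(out <- cache[[text]])) return(out)
  g <- parse_smiles(text, component = component)
  out <- if (is.list(g) && !inherits(g, "molgraph")) {
    vapply(g, mol_to_smiles, character(1))
  } else {
    mol_to_smiles(g)
  }
  if (component == "error") cache[[text]] <- out
  out
}

#' @rdname mol_to_smiles
#' @param a,b molgraphs to compare.
#' @export
mol_identical <- function(a, b) {
  identical(mol_to_smiles(a), mol_to_smiles(b))
}

# package-level caches
.ub_cache <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .ub_cache$canon <- new.env(parent = emptyenv())
  .ub_cache$space <- new.env(parent = emptyenv())
}
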