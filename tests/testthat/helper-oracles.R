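# Independent oracles and fixture generators used across the suite.
# These deliberately avoid the package's own matcher/enumerator code
# paths: matching goes through igraph's VF2, tree counting through
# Pruefer sequences, subgraph enumeration through atom-subset brute force.

# --- independent substructure matcher (igraph VF2 monomorphism) --------

.to_igraph <- function(g) {
  A <- unbio::heavy_atoms(g)
  ig <- igraph::make_graph(if (nrow(g$bond)) as.integer(t(g$bond[, 1:2]))
                           else integer(0), n = A, directed = FALSE)
  igraph::V(ig)$color <- match(g$elem, c("C", "N", "O", "P", "S", "Si", "F",
                                         "Cl", "Br", "I", "Na", "K", "Hg"))
  igraph::E(ig)$color <- if (nrow(g$bond)) as.integer(g$bond[, 3]) else integer(0)
  ig
}

oracle_is_subgraph <- function(pattern, target) {
  p <- if (inherits(pattern, "molgraph")) pattern else parse_smiles(pattern)
  t <- if (inherits(target, "molgraph")) target else parse_smiles(target)
  if (unbio::heavy_atoms(p) > unbio::heavy_atoms(t)) return(FALSE)
  ip <- .to_igraph(p); it <- .to_igraph(t)
  igraph::subgraph_isomorphic(ip, it, method = "vf2",
                              vertex.color1 = igraph::V(it)$color,
                              vertex.color2 = igraph::V(ip)$color,
                              edge.color1 = igraph::E(it)$color,
                              edge.color2 = igraph::E(ip)$color)
}

oracle_count_embeddings <- function(pattern, target) {
  p <- if (inherits(pattern, "molgraph")) pattern else parse_smiles(pattern)
  t <- if (inherits(target, "molgraph")) target else parse_smiles(target)
  if (unbio::heavy_atoms(p) > unbio::heavy_atoms(t)) return(0L)
  ip <- .to_igraph(p); it <- .to_igraph(t)
  maps <- igraph::subgraph_isomorphisms(ip, it, method = "vf2",
                                        vertex.color1 = igraph::V(it)$color,
                                        vertex.color2 = igraph::V(ip)$color,
                                        edge.color1 = igraph::E(it)$color,
                                        edge.color2 = igraph::E(ip)$color)
  if (length(maps) == 0L) return(0L)
  keys <- vapply(maps, function(mp) {
    mp <- as.integer(mp)
    atoms <- sort(mp)
    eids <- if (nrow(p$bond)) {
      sort(vapply(seq_len(nrow(p$bond)), function(r) {
        a <- mp[p$bond[r, 1]]; b <- mp[p$bond[r, 2]]
        paste(sort(c(a, b)), collapse = "-")
      }, character(1)))
    } else character(0)
    paste(paste(atoms, collapse = ","), paste(eids, collapse = ","),
          sep = "|")
  }, character(1))
  length(unique(keys))
}

# --- independent MCS by atom-subset brute force ------------------------

# all connected subgraphs of g as (atom set, bond subset) pairs, found by
# combn over atom subsets and subsets of the induced bonds
oracle_all_connected_subgraphs <- function(g) {
  A <- unbio::heavy_atoms(g)
  out <- list()
  for (k in seq_len(A)) {
    for (atoms in utils::combn(A, k, simplify = FALSE)) {
      rows <- which(g$bond[, 1] %in% atoms & g$bond[, 2] %in% atoms)
      if (k == 1L) { out[[length(out) + 1L]] <- list(atoms = atoms,
                                                     rows = integer(0)); next }
      if (length(rows) < k - 1L) next
      for (j in (k - 1L):length(rows)) {
        for (sub in utils::combn(rows, j, simplify = FALSE)) {
          cover <- sort(unique(c(g$bond[sub, 1], g$bond[sub, 2])))
          if (!identical(cover, sort(atoms))) next
          ig <- igraph::make_graph(as.integer(t(matrix(
            match(g$bond[sub, 1:2], atoms), ncol = 2))), n = k,
            directed = FALSE)
          if (igraph::is_connected(ig))
            out[[length(out) + 1L]] <- list(atoms = atoms, rows = sub)
        }
      }
    }
  }
  out
}

oracle_mcs_size <- function(a, b) {
  a <- if (inherits(a, "molgraph")) a else parse_smiles(a)
  b <- if (inherits(b, "molgraph")) b else parse_smiles(b)
  if (unbio::heavy_atoms(a) > unbio::heavy_atoms(b)) { tmp <- a; a <- b; b <- tmp }
  best <- 0L
  for (sub in oracle_all_connected_subgraphs(a)) {
    k <- length(sub$atoms)
    if (k <= best) next
    frag <- if (k == 1L) unbio::molgraph(a$elem[sub$atoms]) else {
      bm <- a$bond[sub$rows, , drop = FALSE]
      bm[, 1] <- match(bm[, 1], sub$atoms); bm[, 2] <- match(bm[, 2], sub$atoms)
      unbio::molgraph(a$elem[sub$atoms], bm, validate = FALSE)
    }
    if (oracle_is_subgraph(frag, b)) best <- k
  }
  best
}

# --- independent count of unlabeled trees with max degree 4 ------------

# via Pruefer sequences and igraph isomorphism classes
oracle_alkane_count <- function(n) {
  if (n <= 2L) return(1L)
  reps <- list()
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- tabulate(pr, n) + 1L
    if (max(deg) > 4L) next
    tree <- igraph::make_from_prufer(as.integer(pr))
    new <- TRUE
    for (g0 in reps) {
      if (igraph::isomorphic(g0, tree)) { new <- FALSE; break }
    }
    if (new) reps[[length(reps) + 1L]] <- tree
  }
  length(reps)
}

# --- random molecule fixtures ------------------------------------------

# random connected molecule over `elements` (tree growth + optional ring)
random_test_molecule <- function(size, elements = c("C", "C", "C", "N", "O"),
                                 p_ring = 0.3, orders = c(1L, 1L, 2L)) {
  maxv <- c(C = 4L, N = 3L, O = 2L, S = 6L, Cl = 1L, F = 1L)
  repeat {
    g <- unbio::molgraph(sample(elements, 1L))
    ok <- TRUE
    while (unbio::heavy_atoms(g) < size) {
      bs <- integer(unbio::heavy_atoms(g))
      if (nrow(g$bond)) for (r in seq_len(nrow(g$bond))) {
        bs[g$bond[r, 1]] <- bs[g$bond[r, 1]] + g$bond[r, 3]
        bs[g$bond[r, 2]] <- bs[g$bond[r, 2]] + g$bond[r, 3]
      }
      fv <- maxv[g$elem] - bs
      open <- which(fv > 0L)
      if (!length(open)) { ok <- FALSE; break }
      a <- open[sample.int(length(open), 1L)]
      el <- sample(elements, 1L)
      oo <- orders[orders <= min(fv[a], maxv[[el]])]
      if (!length(oo)) next
      g <- unbio::molgraph(c(g$elem, el),
                           rbind(g$bond, c(a, unbio::heavy_atoms(g) + 1L,
                                           oo[sample.int(length(oo), 1L)])),
                           validate = FALSE)
    }
    if (!ok) next
    if (stats::runif(1) < p_ring && unbio::heavy_atoms(g) >= 3L) {
      bs <- integer(unbio::heavy_atoms(g))
      if (nrow(g$bond)) for (r in seq_len(nrow(g$bond))) {
        bs[g$bond[r, 1]] <- bs[g$bond[r, 1]] + g$bond[r, 3]
        bs[g$bond[r, 2]] <- bs[g$bond[r, 2]] + g$bond[r, 3]
      }
      fv <- maxv[g$elem] - bs
      open <- which(fv > 0L)
      if (length(open) >= 2L) {
        ij <- sort(sample(open, 2L))
        has <- nrow(g$bond) && any(g$bond[, 1] == ij[1] & g$bond[, 2] == ij[2])
        if (!has) g <- unbio::molgraph(g$elem, rbind(g$bond, c(ij, 1L)),
                                       validate = FALSE)
      }
    }
    return(g)
  }
}

# random permutation of atom indices (same molecule, relabeled)
permute_molgraph <- function(g) {
  A <- unbio::heavy_atoms(g)
  perm <- sample.int(A)
  b <- g$bond
  if (nrow(b)) { b[, 1] <- perm[b[, 1]]; b[, 2] <- perm[b[, 2]] }
  unbio::molgraph(g$elem[order(perm)], b, validate = FALSE)
}
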