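# Exhaustive enumeration of valence-legal chemical space.
#
# Molecules are grown atom-by-atom: every (k-1)-atom graph is extended by
# one new atom bonded to an existing one, then closed under single-edge
# additions (ring formation) within the same size, with canonical-SMILES
# de-duplication at every step. Because every connected valence-legal
# graph has a spanning tree obtainable by leaf removal, and its remaining
# bonds can be added one at a time without violating valence, this BFS is
# exhaustive for the configured rule set. Stability filters, ring policy
# and element-state rules are applied to the final list only, so they
# cannot prune intermediates that larger legal molecules grow through.

#' Chemical-space specification
#'
#' Describes a space of valence-legal molecules: the element alphabet,
#' maximum heavy-atom count, allowed bond orders, ring policy, allowed
#' sulfur/phosphorus oxidation states and banned (unstable) substructures.
#'
#' @param elements Subset of C, N, O, P, S, Si.
#' @param max_size Maximum heavy-atom count (full enumeration is capped at
#'   `enumeration_cap`).
#' @param bond_orders Subset of 1:3.
#' @param rings Allow rings (`TRUE`) or acyclic space only.
#' @param max_ring_systems Maximum number of fused-ring systems
#'   (connected components of ring bonds).
#' @param min_ring_size Smallest allowed ring.
#' @param sulfur_states Allowed sulfur valences; S(VI) is only admitted in
#'   a sulfone/sulfate-like context (at least two double-bonded oxygens).
#' @param phosphorus_states Allowed phosphorus valences (P(V) by default).
#' @param banned Character vector of banned substructure SMILES;
#'   `default_banned_patterns()` ships O-O-O chains and nitrogen-halogen
#'   bonds and is an extension point, not a complete stability theory.
#' @param enumeration_cap Refuse full enumeration above this size.
#' @return An object of class `chem_space_spec`.
#' @export
chem_space_spec <- function(elements = c("C", "N", "O"),
                            max_size = 5L,
                            bond_orders = c(1L, 2L, 3L),
                            rings = TRUE,
                            max_ring_systems = 2L,
                            min_ring_size = 3L,
                            sulfur_states = c(2L, 6L),
                            phosphorus_states = 5L,
                            banned = default_banned_patterns(),
                            enumeration_cap = 8L) {
  elements <- match.arg(elements, c("C", "N", "O", "P", "S", "Si"),
                        several.ok = TRUE)
  stopifnot(length(elements) >= 1L, max_size >= 1L,
            all(bond_orders %in% 1:3),
            all(sulfur_states %in% c(2L, 4L, 6L)),
            all(phosphorus_states %in% c(3L, 5L)))
  for (p in banned) parse_smiles(p)  # must all be parseable
  structure(list(
    elements = elements, max_size = as.integer(max_size),
    bond_orders = sort(as.integer(bond_orders)), rings = isTRUE(rings),
    max_ring_systems = as.integer(max_ring_systems),
    min_ring_size = as.integer(min_ring_size),
    sulfur_states = sort(as.integer(sulfur_states)),
    phosphorus_states = sort(as.integer(phosphorus_states)),
    banned = banned, enumeration_cap = as.integer(enumeration_cap)
  ), class = "chem_space_spec")
}

#' @rdname chem_space_spec
#' @export
default_banned_patterns <- function() {
  path <- system.file("extdata", "banned_patterns.smi", package = "unbio")
  if (!nzchar(path)) return(c("OOO", "NF", "NCl", "NBr", "NI"))
  tb <- read_smiles_file(path)
  tb$smiles
}

# max valence per element under a spec (states restrict S and P)
.spec_max_valence <- function(spec) {
  v <- vapply(spec$elements, .elem_max_valence, integer(1))
  names(v) <- spec$elements
  if ("S" %in% spec$elements) v[["S"]] <- max(spec$sulfur_states)
  if ("P" %in% spec$elements) v[["P"]] <- max(spec$phosphorus_states)
  v
}

# ring bonds = bonds on some cycle (non-bridges)
.ring_bond_rows <- function(g) {
  m <- nrow(g$bond)
  if (m == 0L) return(integer(0))
  ig <- igraph::make_graph(as.integer(t(g$bond[, 1:2, drop = FALSE])),
                           n = length(g$elem), directed = FALSE)
  setdiff(seq_len(m), igraph::bridges(ig))
}

.ring_system_count <- function(g, ring_rows) {
  if (length(ring_rows) == 0L) return(0L)
  sub <- .subgraph_bonds(g, ring_rows)
  length(.components(sub))
}

.girth_of <- function(g) {
  if (nrow(g$bond) == 0L) return(Inf)
  ig <- igraph::make_graph(as.integer(t(g$bond[, 1:2, drop = FALSE])),
                           n = length(g$elem), directed = FALSE)
  gr <- suppressWarnings(igraph::girth(ig)$girth)
  if (is.null(gr) || is.na(gr) || gr == 0) Inf else gr
}

# Element-state rules: sulfur above S(II) must be sulfone/sulfate-like;
# each atom's bond sum must be fillable to an allowed state.
.state_legal <- function(g, spec) {
  bs <- bond_order_sums(g)
  for (a in seq_along(g$elem)) {
    el <- g$elem[a]
    if (el == "S") {
      states <- spec$sulfur_states
      if (bs[a] > min(states)) {
        fill <- states[states >= bs[a]]
        if (length(fill) == 0L) return(FALSE)
        if (min(fill) == 6L) {
          # the hexavalent state is sulfone/sulfate-like only: fully
          # substituted (no hydrogen fill) with >= 2 double-bonded oxygens
          if (bs[a] != 6L) return(FALSE)
          b <- g$bond
          dbo <- sum((b[, 1L] == a & b[, 3L] == 2L & g$elem[b[, 2L]] == "O") |
                     (b[, 2L] == a & b[, 3L] == 2L & g$elem[b[, 1L]] == "O"))
          if (dbo < 2L) return(FALSE)
        }
      }
    } else if (el == "P") {
      states <- spec$phosphorus_states
      if (!any(states >= bs[a])) return(FALSE)
      if (length(states) == 1L && states == 5L) {
        # P(V) only: require a pentavalent-looking centre (>= one double
        # bond or bond sum > 3), i.e. exclude phosphine-like P(III)
        b <- g$bond
        hasdb <- any((b[, 1L] == a | b[, 2L] == a) & b[, 3L] >= 2L)
        if (bs[a] <= 3L && !hasdb) return(FALSE)
      }
    }
  }
  TRUE
}

.space_key <- function(spec, max_size = spec$max_size) {
  paste(paste(spec$elements, collapse = ""), max_size,
        paste(spec$bond_orders, collapse = ""), spec$rings,
        spec$max_ring_systems, spec$min_ring_size,
        paste(spec$sulfur_states, collapse = ""),
        paste(spec$phosphorus_states, collapse = ""),
        paste(spec$banned, collapse = "|"), sep = ";")
}

#' Enumerate a chemical space
#'
#' Generates every connected, valence-legal molecule of up to
#' `spec$max_size` heavy atoms over the spec's element alphabet,
#' de-duplicated under canonicalization, with ring-policy, element-state
#' and banned-pattern filters applied. Results are cached per spec within
#' a session.
#'
#' @param spec A [chem_space_spec()].
#' @return A molecule-set tibble (`id`, `smiles`, `heavy_atoms`) with
#'   provenance `"enumerated"`, sorted by size then canonical SMILES.
#' @export
enumerate_space <- function(spec) {
  stopifnot(inherits(spec, "chem_space_spec"))
  if (spec$max_size > spec$enumeration_cap) {
    est <- sum(length(spec$elements)^(seq_len(spec$max_size)))
    stop("max_size ", spec$max_size, " exceeds the enumeration cap of ",
         spec$enumeration_cap, " (well over ", format(est, big.mark = ","),
         " candidate structures); use sample_space() instead", call. = FALSE)
  }
  key <- .space_key(spec)
  hit <- .ub_cache$space[[key]]
  if (!is.null(hit)) return(hit)

  maxval <- .spec_max_valence(spec)
  orders <- spec$bond_orders

  # level 1: single atoms
  level <- lapply(spec$elements, function(e) molgraph(e, validate = FALSE))
  names(level) <- vapply(level, mol_to_smiles, character(1))
  level <- level[order(names(level), method = "radix")]
  all_levels <- list(level)

  extend_atom <- function(g) {
    out <- list()
    fv <- maxval[g$elem] - bond_order_sums(g)
    for (el in spec$elements) {
      for (a in which(fv > 0L)) {
        for (o in orders[orders <= min(fv[a], maxval[[el]])]) {
          out[[length(out) + 1L]] <-
            molgraph(c(g$elem, el),
                     rbind(g$bond, c(a, length(g$elem) + 1L, o)),
                     validate = FALSE)
        }
      }
    }
    out
  }

  close_rings <- function(env) {
    # close under adding one bond between existing atoms
    frontier <- as.list(env)
    while (length(frontier) > 0L) {
      new <- list()
      for (g in frontier) {
        fv <- maxval[g$elem] - bond_order_sums(g)
        A <- length(g$elem)
        bonded <- matrix(FALSE, A, A)
        if (nrow(g$bond) > 0L)
          bonded[g$bond[, 1:2, drop = FALSE]] <- TRUE
        for (i in seq_len(A - 1L)) for (j in (i + 1L):A) {
          if (bonded[i, j]) next
          for (o in orders[orders <= min(fv[i], fv[j])]) {
            cand <- molgraph(g$elem, rbind(g$bond, c(i, j, o)),
                             validate = FALSE)
            smi <- mol_to_smiles(cand)
            if (is.null(env[[smi]])) {
              env[[smi]] <- cand
              new[[length(new) + 1L]] <- cand
            }
          }
        }
      }
      frontier <- new
    }
    env
  }

  for (k in seq_len(spec$max_size - 1L)) {
    cand <- new.env(parent = emptyenv())
    for (g in all_levels[[k]]) {
      for (x in extend_atom(g)) {
        smi <- mol_to_smiles(x)
        if (is.null(cand[[smi]])) cand[[smi]] <- x
      }
    }
    if (spec$rings) cand <- close_rings(cand)
    nm <- sort(ls(cand, sorted = FALSE), method = "radix")
    all_levels[[k + 1L]] <- stats::setNames(mget(nm, envir = cand), nm)
  }

  mols <- unlist(all_levels, recursive = FALSE)
  smis <- names(mols)

  keep <- vapply(seq_along(mols), function(i) {
    g <- mols[[i]]
    rr <- .ring_bond_rows(g)
    if (!spec$rings && length(rr) > 0L) return(FALSE)
    if (length(rr) > 0L) {
      if (.ring_system_count(g, rr) > spec$max_ring_systems) return(FALSE)
      if (.girth_of(g) < spec$min_ring_size) return(FALSE)
    }
    .state_legal(g, spec)
  }, logical(1))
  mols <- mols[keep]; smis <- smis[keep]

  out <- tibble::tibble(
    id = sprintf("enum%05d", seq_along(smis)),
    smiles = smis,
    heavy_atoms = vapply(mols, heavy_atoms, integer(1))
  )
  out <- out[order(out$heavy_atoms, out$smiles, method = "radix"), ]
  out$id <- sprintf("enum%05d", seq_len(nrow(out)))
  out <- apply_stability_filters(out, spec$banned)
  attr(out, "provenance") <- "enumerated"
  .ub_cache$space[[key]] <- out
  out
}

#' Remove molecules containing banned substructures
#'
#' @param molecules A molecule-set data frame (`id`, `smiles`).
#' @param banned Character vector of substructure SMILES; molecules
#'   containing any of them are dropped, order preserved.
#' @return The filtered tibble.
#' @export
apply_stability_filters <- function(molecules, banned) {
  tb <- if (is.data.frame(molecules)) molecules else .as_mol_tbl(molecules)
  if (length(banned) == 0L || nrow(tb) == 0L) return(tibble::as_tibble(tb))
  pats <- lapply(banned, function(p) .match_plan(.as_molgraph(p)))
  keep <- vapply(tb$smiles, function(s) {
    ti <- .target_index(parse_structure(s, component = "largest"))
    for (pl in pats) {
      if (.match_search(pl, ti, collect = FALSE)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
  out <- tibble::as_tibble(tb[keep, , drop = FALSE])
  attr(out, "provenance") <- attr(molecules, "provenance")
  out
}

#' Sample molecules from a chemical space
#'
#' Draws `n` molecules with replacement. For enumerable specs
#' (`max_size <= enumeration_cap`) the draw is uniform over
#' [enumerate_space()]; larger spaces use a random-growth rejection
#' sampler (documented as approximately, not exactly, uniform).
#'
#' @param spec A [chem_space_spec()].
#' @param n Number of draws.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A molecule-set tibble (`id`, `smiles`, `heavy_atoms`),
#'   provenance `"enumerated"`, possibly with repeated structures.
#' @export
sample_space <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "chem_space_spec"), n >= 1L)
  if (spec$max_size <= spec$enumeration_cap) {
    space <- enumerate_space(spec)
    idx <- withr::with_seed(seed,
      sample.int(nrow(space), n, replace = TRUE))
    out <- tibble::tibble(id = sprintf("samp%05d", seq_len(n)),
                          smiles = space$smiles[idx],
                          heavy_atoms = space$heavy_atoms[idx])
  } else {
    out <- withr::with_seed(seed, {
      draws <- purrr::map(seq_len(n), function(i) .random_molecule(spec))
      tibble::tibble(id = sprintf("samp%05d", seq_len(n)),
                     smiles = vapply(draws, mol_to_smiles, character(1)),
                     heavy_atoms = vapply(draws, heavy_atoms, integer(1)))
    })
  }
  attr(out, "provenance") <- "enumerated"
  out
}

# Rejection sampler: random tree growth plus random ring closures, redrawn
# until all spec filters pass.
.random_molecule <- function(spec, max_tries = 10000L) {
  maxval <- .spec_max_valence(spec)
  pats <- lapply(spec$banned, function(p) .match_plan(.as_molgraph(p)))
  for (try in seq_len(max_tries)) {
    size <- sample.int(spec$max_size, 1L)
    g <- molgraph(sample(spec$elements, 1L), validate = FALSE)
    ok <- TRUE
    while (heavy_atoms(g) < size) {
      fv <- maxval[g$elem] - bond_order_sums(g)
      open <- which(fv > 0L)
      if (length(open) == 0L) { ok <- FALSE; break }
      a <- open[sample.int(length(open), 1L)]
      el <- sample(spec$elements, 1L)
      oo <- spec$bond_orders[spec$bond_orders <= min(fv[a], maxval[[el]])]
      if (length(oo) == 0L) next
      o <- oo[sample.int(length(oo), 1L)]
      g <- molgraph(c(g$elem, el),
                    rbind(g$bond, c(a, heavy_atoms(g) + 1L, o)),
                    validate = FALSE)
    }
    if (!ok) next
    if (spec$rings && heavy_atoms(g) >= spec$min_ring_size &&
        stats::runif(1) < 0.3) {
      fv <- maxval[g$elem] - bond_order_sums(g)
      open <- which(fv > 0L)
      if (length(open) >= 2L) {
        ij <- sort(open[sample.int(length(open), 2L)])
        oo <- spec$bond_orders[spec$bond_orders <= min(fv[ij])]
        b <- g$bond
        already <- nrow(b) > 0L && any(b[, 1L] == ij[1L] & b[, 2L] == ij[2L])
        if (length(oo) > 0L && !already) {
          g <- molgraph(g$elem, rbind(b, c(ij[1L], ij[2L],
                                           oo[sample.int(length(oo), 1L)])),
                        validate = FALSE)
        }
      }
    }
    rr <- .ring_bond_rows(g)
    if (!spec$rings && length(rr) > 0L) next
    if (length(rr) > 0L &&
        (.ring_system_count(g, rr) > spec$max_ring_systems ||
         .girth_of(g) < spec$min_ring_size)) next
    if (!.state_legal(g, spec)) next
    ti <- .target_index(g)
    banned_hit <- FALSE
    for (pl in pats) {
      if (.match_search(pl, ti, collect = FALSE)) { banned_hit <- TRUE; break }
    }
    if (banned_hit) next
    return(g)
  }
  stop("rejection sampler failed after ", max_tries, " tries; the spec may ",
       "admit no molecules", call. = FALSE)
}
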