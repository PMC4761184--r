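# Chemical-space coverage: how much of fragment space a molecule
# collection occupies, against the expectation for a randomly assembled
# collection of the same size.

#' Fraction of fragments not found in a molecule set
#'
#' @param fragments Character vector (or tibble with `fragment` column) of
#'   fragment SMILES.
#' @param molecules Molecule set; an empty set leaves every fragment
#'   unfound (fraction 1).
#' @return Fraction in `[0, 1]` of fragments that occur in no molecule of
#'   the set.
#' @export
observed_unfound_fraction <- function(fragments, molecules) {
  frags <- if (is.data.frame(fragments)) fragments$fragment
           else as.character(fragments)
  stopifnot(length(frags) >= 1L)
  gs <- .as_graph_list(molecules)
  if (length(gs) == 0L) return(1)
  tis <- lapply(gs, .target_index)
  unfound <- vapply(frags, function(fs) {
    pl <- .match_plan(.as_molgraph(fs))
    for (ti in tis) {
      if (.match_search(pl, ti, collect = FALSE)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
  mean(unfound)
}

#' Probability that a fragment matches a random molecule
#'
#' Monte-Carlo estimate of the frequency with which each fragment occurs
#' in a molecule drawn at random from a chemical space, with a binomial
#' standard error. With `exact = TRUE` (enumerable specs only) the exact
#' fraction over the enumerated space is returned instead.
#'
#' @param fragments Fragment SMILES (vector or tibble with `fragment`).
#' @param spec A [chem_space_spec()].
#' @param n_samples Monte-Carlo sample size.
#' @param seed Integer seed (draws are deterministic given the seed).
#' @param exact Use the full enumerated space instead of sampling.
#' @return A tibble: `fragment`, `p_match`, `se`.
#' @export
fragment_match_probability <- function(fragments, spec, n_samples = 2000L,
                                       seed = 1L, exact = FALSE) {
  frags <- if (is.data.frame(fragments)) fragments$fragment
           else as.character(fragments)
  stopifnot(length(frags) >= 1L, n_samples >= 1L)
  if (exact) {
    space <- enumerate_space(spec)
    draw <- space$smiles
    nn <- length(draw)
    se0 <- function(p) sqrt(p * (1 - p) / nn)
  } else {
    draw <- sample_space(spec, n_samples, seed = seed)$smiles
    nn <- n_samples
    se0 <- function(p) sqrt(p * (1 - p) / nn)
  }
  # matching is per distinct structure, weighted by multiplicity
  uniq <- unique(draw)
  wt <- as.numeric(table(factor(draw, levels = uniq)))
  tis <- lapply(uniq, function(s)
    .target_index(parse_structure(s, component = "largest")))
  p <- vapply(frags, function(fs) {
    pl <- .match_plan(.as_molgraph(fs))
    hit <- vapply(tis, function(ti)
      .match_search(pl, ti, collect = FALSE), logical(1))
    sum(wt[hit]) / nn
  }, numeric(1), USE.NAMES = FALSE)
  tibble::tibble(fragment = frags, p_match = p,
                 se = vapply(p, se0, numeric(1)))
}

#' Expected unfound fraction in a random collection
#'
#' If a fragment matches a random molecule with probability `p`, the
#' chance that none of `M` independently drawn molecules contains it is
#' `(1 - p)^M`; the expected unfound fraction is the mean over fragments.
#'
#' @param match_probs Numeric vector of per-fragment match probabilities
#'   (or the tibble from [fragment_match_probability()]).
#' @param M Collection size.
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_unfound_fraction <- function(match_probs, M) {
  p <- if (is.data.frame(match_probs)) match_probs$p_match
       else as.numeric(match_probs)
  stopifnot(all(p >= 0 & p <= 1), M >= 0)
  mean((1 - p)^M)
}

#' Observed vs expected chemical-space coverage curve
#'
#' For each fragment size `n`, takes all `n`-atom fragments of the
#' enumerated space, measures the fraction not found in the molecule
#' collection, and compares it with the fraction expected if the
#' collection had been assembled by drawing molecules at random from the
#' same space (Monte-Carlo match probabilities, delta-method standard
#' error).
#'
#' @param spec A [chem_space_spec()] describing the reference space.
#' @param molecules The molecule collection (e.g. a metabolite set).
#' @param sizes Fragment sizes to profile.
#' @param n_mc Monte-Carlo sample size per fragment size.
#' @param seed Integer seed.
#' @return A `ub_coverage` tibble: `n`, `n_fragments`, `observed_unfound`,
#'   `expected_unfound`, `se_expected`.
#' @export
coverage_curve <- function(spec, molecules, sizes = 3:7, n_mc = 2000L,
                           seed = 1L) {
  tb <- .as_mol_tbl(molecules)
  M <- nrow(tb)
  space <- enumerate_space(spec)
  rows <- purrr::map(seq_along(sizes), function(k) {
    n <- sizes[k]
    frags <- n_atom_fragments(space, n)$fragment
    if (length(frags) == 0L) {
      return(tibble::tibble(n = n, n_fragments = 0L,
                            observed_unfound = NA_real_,
                            expected_unfound = NA_real_,
                            se_expected = NA_real_))
    }
    obs <- observed_unfound_fraction(frags, tb)
    mp <- fragment_match_probability(frags, spec, n_samples = n_mc,
                                     seed = seed + k)
    expd <- expected_unfound_fraction(mp, M)
    # delta method: d/dp (1-p)^M = -M (1-p)^(M-1)
    se <- sqrt(sum((M * (1 - mp$p_match)^(M - 1) * mp$se)^2)) / length(frags)
    tibble::tibble(n = n, n_fragments = length(frags),
                   observed_unfound = obs, expected_unfound = expd,
                   se_expected = se)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ub_coverage", class(out))
  out
}
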