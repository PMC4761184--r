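# Coverage statistics: observed vs expected occupancy of fragment space.

test_that("observed unfound fraction counts fragments missing from a set", {
  expect_equal(observed_unfound_fraction(c("CCC", "CCO"), "CCCO"), 0)
  expect_equal(observed_unfound_fraction("NCC", "CCCO"), 1)
  expect_equal(observed_unfound_fraction(c("CC", "NN"), c("CCO", "CCC")), 0.5)
  # empty molecule set: everything unfound
  expect_equal(observed_unfound_fraction("CC", character(0)), 1)
})

test_that("expected unfound fraction follows the (1-p)^M closed form", {
  expect_equal(expected_unfound_fraction(0.5, 2L), 0.25)
  expect_equal(expected_unfound_fraction(c(0, 1), 10L), 0.5)
  expect_equal(expected_unfound_fraction(0.01, 100L), 0.99^100)
  expect_equal(round(expected_unfound_fraction(0.01, 100L), 4), 0.3660)
  expect_equal(expected_unfound_fraction(c(0.3, 0.7), 0L), 1)
  # monotone non-increasing in M
  p <- c(0.05, 0.2, 0.6)
  vals <- vapply(0:20, function(M) expected_unfound_fraction(p, M), numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("match probabilities are exact on tiny spaces and seeded", {
  # all C-only acyclic saturated molecules of exactly 4 atoms contain CCC
  spec <- chem_space_spec(elements = "C", max_size = 4L, bond_orders = 1L,
                          rings = FALSE, banned = character(0))
  space4 <- enumerate_space(spec)
  frag_in_4 <- vapply(space4$smiles[space4$heavy_atoms == 4L],
                      function(m) is_subgraph("CCC", m), logical(1))
  expect_true(all(frag_in_4))  # butane and isobutane both contain CCC

  mp <- fragment_match_probability(c("CCC", "N"), spec, n_samples = 500L,
                                   seed = 5L)
  expect_equal(mp$p_match[2], 0)  # no nitrogen in a C-only space
  expect_identical(mp, fragment_match_probability(c("CCC", "N"), spec,
                                                  n_samples = 500L, seed = 5L))
  # MC converges to the exact enumerated fraction within 3 binomial sigma
  exact <- fragment_match_probability("CCC", spec, exact = TRUE)$p_match
  expect_true(abs(mp$p_match[1] - exact) <=
                3 * sqrt(exact * (1 - exact) / 500) + 1e-9)
})

test_that("a random metabolome matches its null; a structured one exceeds it", {
  spec <- chem_space_spec(elements = c("C", "O"), max_size = 4L,
                          bond_orders = c(1L, 2L), rings = FALSE,
                          banned = character(0))
  space <- enumerate_space(spec)
  frags <- n_atom_fragments(space, 3L)$fragment
  M <- 12L

  # null: metabolome = M uniform draws from the space itself
  draws <- sample_space(spec, M, seed = 29L)
  obs <- observed_unfound_fraction(frags, draws)
  mp <- fragment_match_probability(frags, spec, n_samples = 2000L, seed = 31L)
  expd <- expected_unfound_fraction(mp, M)
  # binomial-ish spread of the observed fraction around its expectation
  sd0 <- sqrt(sum(mp$p_match * (1 - mp$p_match)^(2 * M - 1))) / length(frags) +
    sqrt(expd * (1 - expd) / length(frags))
  expect_lt(abs(obs - expd), 3 * max(sd0, 0.05))

  # structured subset (saturated molecules only): observed > expected
  sat <- space[!grepl("=", space$smiles), ]
  sat <- sat[order(-sat$heavy_atoms), ][seq_len(M), ]
  obs_s <- observed_unfound_fraction(frags, sat)
  expect_gt(obs_s, expd)
})

test_that("coverage_curve assembles per-size observed and expected rows", {
  spec <- chem_space_spec(elements = c("C", "O"), max_size = 4L,
                          bond_orders = c(1L, 2L), rings = FALSE,
                          banned = character(0))
  mets <- sample_space(spec, 10L, seed = 37L)
  cv <- coverage_curve(spec, mets, sizes = 2:4, n_mc = 300L, seed = 41L)
  expect_named(cv, c("n", "n_fragments", "observed_unfound",
                     "expected_unfound", "se_expected"))
  expect_equal(cv$n, 2:4)
  expect_true(all(cv$observed_unfound >= 0 & cv$observed_unfound <= 1))
  expect_true(all(cv$expected_unfound >= 0 & cv$expected_unfound <= 1))
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})
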