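# Statistical layer: rank correlations, multiple testing, bands, hit
# rates, EC50s and the yeast filter pipeline.

test_that("spearman handles monotone, antitone and tied data", {
  expect_equal(spearman(c(1, 2, 3, 4), c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(c(1, 2, 3, 4), c(40, 30, 20, 10))$rho, -1)
  tied <- spearman(c(1, 2, 2, 3), c(1, 1, 2, 3))
  expect_equal(round(tied$rho, 4), 0.8333)
  expect_equal(tied$rho,
               suppressWarnings(stats::cor.test(c(1, 2, 2, 3), c(1, 1, 2, 3),
                                                method = "spearman"))$estimate,
               ignore_attr = TRUE)
  expect_warning(flat <- spearman(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_true(is.na(flat$rho))
  expect_error(spearman(1:3, 1:3), "at least 4")
  # invariance under strictly monotone transforms
  set.seed(83)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$rho, base$rho)
  expect_equal(spearman(x, y^3 + 5 * y)$rho, base$rho)
})

test_that("multiple-testing numbers reproduce the 35x2 family", {
  expect_equal(signif(bonferroni_threshold(35L, 2L, 0.05), 3), 0.000714)
  expect_equal(bonferroni_threshold(1L, 1L, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10L, 2L, 0.01), 0.0005)

  expect_equal(round(family_wise_prob(70L, 0.05 / 70), 2), 0.05)
  expect_equal(family_wise_prob(1L, 0.37), 0.37)
  expect_equal(family_wise_prob(2L, 0.5), 0.75)
  # number of repeat studies expected for one family-level false positive
  expect_equal(round(1 / family_wise_prob(70L, 0.05 / 70)), 20)

  # family-wise probability at the Bonferroni level never exceeds alpha
  for (e in c(5L, 35L)) for (m in 1:2) {
    a <- bonferroni_threshold(e, m, 0.05)
    expect_lte(family_wise_prob(e * m, a), 0.05)
  }
  expect_identical(significance_tier(c(0.2, 0.04, 0.005, 1e-5)),
                   c("", "*", "**", "***"))
})

test_that("correlate_endpoint joins, flags and is order-invariant", {
  set.seed(89)
  ub <- tibble::tibble(id = sprintf("c%02d", 1:30),
                       ub5 = sample(0:8, 30, replace = TRUE))
  rec <- tibble::tibble(id = ub$id, endpoint = "toy",
                        log_ec50 = -0.3 * ub$ub5 + rnorm(30, sd = 0.5))
  res <- correlate_endpoint(rec, ub, n = 5L)
  expect_lt(res$rho, 0)
  shuffled <- rec[sample.int(nrow(rec)), ]
  expect_equal(correlate_endpoint(shuffled, ub, n = 5L)$rho, res$rho)

  const <- dplyr::mutate(ub, ub5 = 2L)
  expect_true(is.na(correlate_endpoint(rec, const, n = 5L)$rho))

  expect_error(correlate_endpoint(rec[1:3, ], ub, n = 5L), "4")
  expect_error(correlate_endpoint(rec, dplyr::rename(ub, ub6 = ub5), n = 5L),
               "ub5")
})

test_that("fisher CI matches the closed form and bands partition records", {
  expect_equal(round(fisher_ci(0.5, 30L), 3), c(0.170, 0.729))
  expect_equal(fisher_ci(NA_real_, 30L), c(NA_real_, NA_real_))

  set.seed(97)
  ub <- tibble::tibble(id = sprintf("c%03d", 1:120),
                       ub5 = sample(0:9, 120, replace = TRUE))
  rec <- tibble::tibble(id = ub$id,
                        log_ec50 = runif(120, -6, 0))
  bands <- band_analysis(rec, ub, n = 5L, edges = c(-4, -3, -2))
  expect_equal(sum(bands$n), 120L)
  expect_equal(bands$lo, c(-Inf, -4, -3, -2))
  expect_equal(bands$hi, c(-4, -3, -2, Inf))
  # all records in one band: others report n and no CI
  rec1 <- dplyr::mutate(rec, log_ec50 = runif(120, -2.9, -2.1))
  b1 <- band_analysis(rec1, ub, n = 5L)
  expect_equal(b1$n[b1$lo == -3], 120L)
  expect_true(all(is.na(b1$rho[b1$n == 0])))
  expect_s3_class(ggplot2::autoplot(bands), "ggplot")
})

test_that("hit-rate curve counts actives over tested per log bin", {
  tests <- tibble::tibble(
    id = c("a", "b", "c", "d", "e"),
    concentration = c(1e-6, 1e-6, 1e-6, 1e-5, 1e-5),
    active = c(TRUE, FALSE, FALSE, TRUE, TRUE))
  hc <- hit_rate_curve(tests, bin_width = 0.25)
  expect_equal(nrow(hc), 2L)
  expect_equal(hc$hit_rate, c(1 / 3, 1))
  expect_equal(hc$n_tested, c(3L, 2L))
  # all active: every populated bin at 1
  hc2 <- hit_rate_curve(dplyr::mutate(tests, active = TRUE))
  expect_true(all(hc2$hit_rate == 1))
  expect_s3_class(ggplot2::autoplot(hc), "ggplot")
})

test_that("EC50 interpolation is log-linear with first-crossing rules", {
  expect_equal(ec50_from_curve(c(10e-6, 100e-6), c(30, 70)),
               10^((log10(10e-6) + log10(100e-6)) / 2))
  expect_equal(round(ec50_from_curve(c(10e-6, 100e-6), c(30, 70)) * 1e6, 1),
               31.6)
  expect_equal(ec50_from_curve(c(1e-6, 1e-5, 1e-4), c(10, 50, 90)), 1e-5)
  expect_true(is.na(ec50_from_curve(c(1e-6, 1e-5), c(10, 40))))
  expect_true(is.na(ec50_from_curve(c(1e-6, 1e-5), c(60, 90))))
  expect_error(ec50_from_curve(c(1e-5, 1e-6), c(10, 60)), "unsorted|incr",
               ignore.case = TRUE)
})

test_that("yeast filter applies the exclusion rules in order", {
  conc <- c(1.3e-6, 1e-5, 1e-4)
  mk <- function(id, inh) {
    tidyr::expand_grid(id = id, strain = c("s1", "s2"),
                       concentration = conc) |>
      dplyr::arrange(strain, concentration) |>
      dplyr::mutate(inhibition = rep(inh, 2))
  }
  inhib <- dplyr::bind_rows(
    mk("ok",       c(10, 55, 90)),
    mk("weak",     c(5, 20, 40)),      # <50% at top concentration
    mk("toostrong", c(70, 80, 95)),    # >50% at bottom concentration
    mk("metal",    c(10, 60, 90)),
    mk("mixture",  c(10, 60, 90)),
    mk("salt",     c(10, 60, 90)))
  # one compound with wildly spread strain EC50s
  spread <- tibble::tibble(
    id = "spread", strain = rep(c("s1", "s2"), each = 3),
    concentration = rep(conc, 2),
    inhibition = c(10, 90, 95, 10, 20, 55))
  inhib <- dplyr::bind_rows(inhib, spread)
  structures <- tibble::tibble(
    id = c("ok", "weak", "toostrong", "metal", "mixture", "salt", "spread"),
    smiles = c("CCO", "CCO", "CCO", "CC[Hg]CC", "CCO.CCN",
               "CC(=O)[O-].[Na+]", "CCO"))
  res <- yeast_filter(inhib, structures)
  get <- function(i) res[res$id == i, ]
  expect_equal(get("ok")$status, "retained")
  expect_true(is.finite(get("ok")$ec50))
  expect_equal(get("weak")$rule, "max_below_50")
  expect_equal(get("toostrong")$rule, "min_above_50")
  expect_equal(get("metal")$rule, "organometallic")
  expect_equal(get("mixture")$rule, "mixture_or_salt")
  # alkali-metal salt retained, scored on the organic component
  expect_equal(get("salt")$status, "retained")
  expect_equal(get("salt")$smiles, canonical_smiles("CC(=O)O"))
  expect_equal(get("spread")$rule, "strain_spread")
  # retained EC50s sit within the tested range
  expect_true(get("ok")$ec50 >= min(conc) && get("ok")$ec50 <= max(conc))
})

test_that("tidiers summarise correlation families", {
  set.seed(101)
  ub <- tibble::tibble(id = sprintf("c%02d", 1:40),
                       ub5 = sample(0:8, 40, TRUE),
                       ub6 = sample(0:8, 40, TRUE))
  rec <- dplyr::bind_rows(
    tibble::tibble(id = ub$id, endpoint = "ep1",
                   log_ec50 = -0.4 * ub$ub5 + rnorm(40, sd = .4)),
    tibble::tibble(id = ub$id, endpoint = "ep2",
                   log_ec50 = rnorm(40)))
  res <- correlate_endpoints(rec, ub, ns = c(5L, 6L))
  expect_equal(nrow(res), 4L)
  td <- tidy(res)
  expect_named(td, c("term", "estimate", "p.value", "n", "tier"))
  gl <- glance(res)
  expect_equal(gl$n_tests, 4L)
  expect_equal(gl$alpha_star, 0.05 / 4)
  expect_lte(gl$family_wise_p, 0.05)
})
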