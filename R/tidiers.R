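# broom-style tidiers for correlation results.

#' Tidy correlation results
#'
#' `tidy()` returns the per-endpoint correlation rows in broom column
#' conventions (`term`, `estimate`, `p.value`); `glance()` summarises the
#' whole family: number of tests, the Bonferroni-corrected per-test
#' level, how many tests clear it, and the family-wise false-positive
#' probability at that level.
#'
#' @param x A `ub_correlation` object from [correlate_endpoints()].
#' @param alpha Family-wise error target used by `glance()`.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy ub_correlation
#' @export
tidy.ub_correlation <- function(x, ...) {
  tibble::tibble(
    term = paste0(x$endpoint, ":ub", x$ub_n),
    estimate = x$rho,
    p.value = x$p_value,
    n = x$n,
    tier = x$tier
  )
}

#' @rdname tidy.ub_correlation
#' @method glance ub_correlation
#' @export
glance.ub_correlation <- function(x, alpha = 0.05, ...) {
  n_tests <- nrow(x)
  n_endpoints <- length(unique(x$endpoint))
  n_measures <- length(unique(x$ub_n))
  astar <- bonferroni_threshold(n_endpoints, n_measures, alpha)
  tibble::tibble(
    n_endpoints = n_endpoints,
    n_measures = n_measures,
    n_tests = n_tests,
    alpha_star = astar,
    n_below_alpha_star = sum(x$p_value < astar, na.rm = TRUE),
    family_wise_p = family_wise_prob(n_tests, astar)
  )
}
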