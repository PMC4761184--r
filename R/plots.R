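# ggplot2 autoplot methods for result types.

#' Plot methods
#'
#' `autoplot()` methods for the tibble result classes: potency-band
#' correlations (point + 95% CI per band), hit-rate curves (fraction
#' active per log-concentration bin) and coverage curves (observed vs
#' expected unfound fraction by fragment size).
#'
#' @param object A `ub_bands`, `ub_hit_curve` or `ub_coverage` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name unbio-autoplot
NULL

#' @rdname unbio-autoplot
#' @method autoplot ub_bands
#' @export
autoplot.ub_bands <- function(object, ...) {
  ggplot2::ggplot(object,
      ggplot2::aes(x = .data$band, y = .data$rho)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::labs(x = "log10 EC50 band (molar)",
                  y = "Spearman rho (Ub vs log EC50)") +
    ggplot2::theme_minimal()
}

#' @rdname unbio-autoplot
#' @method autoplot ub_hit_curve
#' @export
autoplot.ub_hit_curve <- function(object, ...) {
  ggplot2::ggplot(object,
      ggplot2::aes(x = .data$bin_mid, y = .data$hit_rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "log10 concentration (molar)",
                  y = "fraction of tested compounds active") +
    ggplot2::theme_minimal()
}

#' @rdname unbio-autoplot
#' @method autoplot ub_coverage
#' @export
autoplot.ub_coverage <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("n", "observed_unfound",
                                  "expected_unfound")],
    cols = c("observed_unfound", "expected_unfound"),
    names_to = "which", values_to = "fraction")
  ggplot2::ggplot(long,
      ggplot2::aes(x = .data$n, y = .data$fraction,
                   colour = .data$which, shape = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "fragment size (heavy atoms)",
                  y = "fraction of fragments not found") +
    ggplot2::theme_minimal()
}

#' @rdname unbio-autoplot
#' @param x Object to plot.
#' @param y Ignored.
#' @export
plot.ub_bands <- function(x, y, ...) print(autoplot.ub_bands(x, ...))

#' @rdname unbio-autoplot
#' @export
plot.ub_hit_curve <- function(x, y, ...) print(autoplot.ub_hit_curve(x, ...))

#' @rdname unbio-autoplot
#' @export
plot.ub_coverage <- function(x, y, ...) print(autoplot.ub_coverage(x, ...))
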