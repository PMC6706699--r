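#' Plot a proportion-versus-intensity curve
#'
#' Proportion of master detections with significant slave signal per
#' equal-count master-intensity bin.
#'
#' @param object A `ccp_proportion_curve` from [proportion_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccp_proportion_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$bin_center, y = .data$proportion_positive)) +
    geom_line(colour = "grey40") +
    geom_point(size = 2) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "master intensity (bin mean)",
         y = "proportion slave-significant") +
    theme_minimal()
}

#' Plot cohort-averaged intensity traces
#'
#' Mean trace with a mean +/- SE ribbon per lifetime cohort and channel.
#'
#' @param object A `ccp_cohorts` tibble from [cohort_traces()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ccp_cohorts <- function(object, ...) {
  ggplot(object, aes(x = .data$rel_time, y = .data$mean,
                     colour = .data$channel, fill = .data$channel)) +
    geom_ribbon(aes(ymin = .data$mean - .data$se,
                    ymax = .data$mean + .data$se),
                alpha = 0.25, colour = NA) +
    geom_line() +
    facet_wrap(~.data$cohort) +
    labs(x = "fraction of lifetime", y = "intensity (mean ± SE)") +
    theme_minimal()
}

#' Plot a binding fit with its data
#'
#' Observed points and the fitted model curve.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- object$data
  df <- tibble(x = d[[1]], y = d[[2]])
  p <- ggplot(df, aes(x = .data$x, y = .data$y)) + geom_point() +
    labs(x = names(d)[1], y = names(d)[2], title = object$model) +
    theme_minimal()
  if (!is.null(object$fitted))
    p <- p + geom_line(data = tibble(x = df$x, y = object$fitted),
                       colour = "firebrick")
  p
}

#' Lifetime distribution histogram
#'
#' @param lifetimes_s Lifetimes in seconds (bona fide tracks).
#' @param binwidth Histogram bin width, seconds.
#' @return A ggplot.
#' @export
plot_lifetimes <- function(lifetimes_s, binwidth = 10) {
  ggplot(tibble(lifetime_s = lifetimes_s), aes(x = .data$lifetime_s)) +
    geom_histogram(binwidth = binwidth, boundary = 0,
                   fill = "grey60", colour = "grey30") +
    labs(x = "lifetime (s)", y = "tracks") +
    theme_minimal()
}
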