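#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_histogram geom_point
#'   geom_vline geom_abline geom_ribbon labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Test information curve of a calibration
#'
#' @param object A `neatlink_fit`.
#' @param ... Unused.
#' @return A ggplot: information against ability.
#' @export
autoplot.neatlink_fit <- function(object, ...) {
  info <- test_information(object$bank, object$grid)
  ggplot(info, aes(x = .data$theta, y = .data$information)) +
    geom_line(linewidth = 0.8) +
    labs(x = "Ability (theta)", y = "Test information",
         title = paste0("Test information: ", object$bank$form_id[1])) +
    theme_minimal()
}

#' Histogram of standardized bivariate residuals
#'
#' Mirrors the usual local-independence figure: residual z values with the
#' Bonferroni cutoffs marked.
#'
#' @param object A `neatlink_li`.
#' @param binwidth Histogram bin width (default 0.25).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neatlink_li <- function(object, binwidth = 0.25, ...) {
  cut <- object$summary$cutoff
  ggplot(dplyr::filter(object$cells, .data$usable), aes(x = .data$z)) +
    geom_histogram(binwidth = binwidth, fill = "grey40") +
    geom_vline(xintercept = c(-cut, cut), linetype = "dashed") +
    labs(x = "Standardized residual (z)", y = "Cell count",
         title = "Bivariate standardized Pearson residuals") +
    theme_minimal()
}

#' Equating table plot
#'
#' Equated score against raw score, with the identity line for reference.
#'
#' @param object A `neatlink_equating`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neatlink_equating <- function(object, ...) {
  ggplot(object, aes(x = .data$score, y = .data$equivalent)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "Raw score (from-form)", y = "Equated score (to-form)",
         title = paste0(object$method[1], " equating")) +
    theme_minimal()
}

#' Percentile fan of an age-reference model
#'
#' @param object A `neatlink_refmodel`.
#' @param levels Percentile levels to draw.
#' @param data Optional tibble `age`, `score` of the fitted observations,
#'   drawn as points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neatlink_refmodel <- function(object, levels = c(2.5, 10, 25, 50, 75, 90),
                                       data = NULL, ...) {
  ages <- seq(object$age_range[1], object$age_range[2], length.out = 100)
  fan <- purrr::map_dfr(levels, function(lv) {
    tibble(age = ages, level = factor(lv),
           value = object$mean_fn(ages) + qnorm(lv / 100) * object$sd_fn(ages))
  })
  p <- ggplot(fan, aes(x = .data$age, y = .data$value, colour = .data$level))
  if (!is.null(data)) {
    p <- p + geom_point(data = data, aes(x = .data$age, y = .data$score),
                        inherit.aes = FALSE, alpha = 0.3, size = 0.7)
  }
  p + geom_line() +
    labs(x = "Age (years)", y = "Score", colour = "Percentile",
         title = paste0("Age-specific reference intervals (", object$model_id, ")")) +
    theme_minimal()
}
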