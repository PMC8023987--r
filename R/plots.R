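#' Spaghetti plot of individual trajectories
#'
#' One line per patient on the original outcome scale, with the pointwise
#' median overlaid. Requires ggplot2 (suggested); plotting is cosmetic and
#' never gates the pipeline.
#'
#' @param x a [cohort()].
#' @param outcome `"pga"` or `"das"`.
#' @return A ggplot object.
#' @export
plot_spaghetti <- function(x, outcome = "pga") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_spaghetti needs the ggplot2 package")
  v <- x$visits[!is.na(x$visits[[outcome]]), ]
  v$bin <- round(v$t * 2) / 2
  med <- stats::aggregate(v[[outcome]], list(t = v$bin), median)
  ggplot2::ggplot(v, ggplot2::aes(.data$t, .data[[outcome]])) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       alpha = 0.15, colour = "steelblue") +
    ggplot2::geom_line(data = med, ggplot2::aes(.data$t, .data$x),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "Years since diagnosis", y = toupper(outcome))
}

#' Predicted class trajectories with confidence bands
#'
#' Plots [predict_trajectory()] curves for every class of a fit.
#'
#' @param fit a [fit_gmm()] result.
#' @param time_grid evaluation times.
#' @param ... passed to [predict_trajectory()].
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fit, time_grid = seq(0, 10, by = 0.25), ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectories needs the ggplot2 package")
  curves <- do.call(rbind, lapply(seq_len(fit$spec$n_classes), function(g) {
    cv <- predict_trajectory(fit, g, time_grid, ...)
    cv$class <- factor(g)
    cv
  }))
  ggplot2::ggplot(curves, ggplot2::aes(.data$t, .data$median,
                                       colour = .data$class)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = 2) +
    ggplot2::labs(x = "Years since diagnosis",
                  y = paste("Predicted median", toupper(fit$spec$outcome)))
}
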