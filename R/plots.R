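#' Plot a log-log scaling fit
#'
#' Scatter of the fitted data on the log10-log10 scale with the fitted
#' line. Only available for fits that retain their model frame.
#'
#' @param object A `scaling_fit` from [fit_loglog()].
#' @param xlab,ylab Axis labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_fit <- function(object, xlab = "log10 x", ylab = "log10 y",
                                 ...) {
  if (is.null(object$lm)) {
    stop("this fit carries no data to plot (published-coefficient fit)",
         call. = FALSE)
  }
  mf <- stats::model.frame(object$lm)
  d <- tibble::tibble(x = mf[[2]], y = mf[[1]])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#4477aa") +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("slope %.3f, intercept %.3f, r² %.3f",
                                  object$slope, object$intercept,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Density plot of logged signed PPE
#'
#' Compares the distribution of sign-preserving logged percent prediction
#' errors per clade against the total sample, per method. Mass left of the
#' dashed zero line marks underestimation.
#'
#' @param per_specimen The `per_specimen` tibble from [accuracy_report()].
#' @return A ggplot object.
#' @export
plot_ppe_density <- function(per_specimen) {
  total <- dplyr::mutate(per_specimen, clade = "total")
  d <- dplyr::bind_rows(per_specimen, total)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logged_ppe, colour = .data$clade)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::facet_wrap(~method, ncol = 1) +
    ggplot2::labs(x = "signed PPE, sign-preserving log10 scale",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Mean PPE with 95% confidence intervals by method and group
#'
#' @param summary The `summary` tibble from [accuracy_report()].
#' @return A ggplot object.
#' @export
plot_ppe_means <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$mean_ppe,
                               colour = .data$method)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_ppe - .data$ci95_halfwidth,
                   ymax = .data$mean_ppe + .data$ci95_halfwidth),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "mean PPE (%, 95% CI)") +
    ggplot2::theme_minimal()
}

#' Center-of-mass metric against skull:tail ratio
#'
#' Scatter of one positional metric against log10 skull:tail volume ratio,
#' coloured by clade and faceted by variant. Regression lines are drawn
#' only for group/variant fits whose slope is significant at p < 0.05.
#'
#' @param study Output of [com_study()].
#' @param metric `"pct_AG"` or `"dca_fl"`.
#' @return A ggplot object.
#' @export
plot_com_study <- function(study, metric = c("pct_AG", "dca_fl")) {
  metric <- match.arg(metric)
  d <- study$metrics
  d$value <- d[[metric]]
  lines <- dplyr::filter(study$regressions, .data$metric == !!metric,
                         .data$significant)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log10_skull_tail,
                                       y = .data$value,
                                       colour = .data$clade)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "log10 skull:tail volume ratio", y = metric) +
    ggplot2::theme_minimal()
  if (nrow(lines)) {
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group))
  }
  p
}
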