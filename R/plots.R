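#' Plot module stress-response profiles
#'
#' Faceted time-course of the mean delta-RMA per module and stress with a
#' standard-error ribbon, mirroring the usual module-profile panel layout.
#'
#' @param object A [module_profiles()] result.
#' @param ncol Facet columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.module_profiles <- function(object, ncol = 4, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$timepoint_h,
                                       y = .data$mean_delta_rma,
                                       colour = .data$stress,
                                       fill = .data$stress)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_delta_rma - .data$se,
                                      ymax = .data$mean_delta_rma + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(-1, 1), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~module, ncol = ncol) +
    ggplot2::labs(x = "hours after stress onset",
                  y = expression(Delta ~ "RMA (stress - control)"))
}

#' Plot the correlation-space scatter of a plasticity comparison
#'
#' 2-D binned density of TF-target pairs positioned by their Pearson
#' correlation in each condition; dashed lines mark the selected delta-r
#' cutoff band outside which pairs are called plastic.
#'
#' @param object A [plasticity_comparison()] result.
#' @param bins Number of bins per axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.plasticity_cmp <- function(object, bins = 60, ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$r_a, y = .data$r_b)) +
    ggplot2::geom_bin2d(bins = bins) +
    ggplot2::coord_fixed(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = sprintf("r (%s)", object$cond_a),
                  y = sprintf("r (%s)", object$cond_b))
  if (!object$cutoff$no_signal) {
    c0 <- object$cutoff$cutoff
    p <- p +
      ggplot2::geom_abline(intercept = c(-c0, c0), slope = 1,
                           linetype = "dashed")
  }
  p
}

#' Plot per-test differential-expression call counts
#'
#' Bar chart of up- and down-regulated gene counts per stress and timepoint.
#'
#' @param object A `de_calls` object from [sam_call_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_calls <- function(object, ...) {
  tab <- object$diagnostics |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "count") |>
    dplyr::mutate(direction = sub("^n_", "", .data$direction))
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$timepoint_h),
                                    y = .data$count,
                                    fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stress) +
    ggplot2::labs(x = "hours after stress onset", y = "genes called")
}
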