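# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname nss_result_tidiers
#' @title Tidiers for NSS results
#' @description `tidy()` returns the per-stimulus score table; `glance()` a
#'   one-row summary with the aggregate mean NSS.
#' @param x an `nss_result` from [mean_nss_over_stimuli()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.nss_result <- function(x, ...) x$scores

#' @rdname nss_result_tidiers
#' @export
glance.nss_result <- function(x, ...) {
  tibble(mean_nss = x$mean_nss, n_used = x$n_used, n_excluded = x$n_excluded)
}

#' @rdname recovery_result_tidiers
#' @title Tidiers for recovery results
#' @description `tidy()` returns the NSS-vs-`w_i` curve; `glance()` a one-row
#'   summary with the estimate (and the true generating value if known).
#' @param x a `recovery_result` from [estimate_parameter()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.recovery_result <- function(x, ...) x$curve

#' @rdname recovery_result_tidiers
#' @export
glance.recovery_result <- function(x, ...) {
  tibble(estimate = x$estimate, true_value = x$true_value,
         peak_nss = max(x$curve$mean_nss))
}

#' @export
tidy.recovery_experiment <- function(x, ...) x$estimates

#' @export
glance.recovery_experiment <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$estimates, gen_w_i = .data$gen_w_i),
                   hits = sum(.data$hit), n_replicates = dplyr::n(),
                   .groups = "drop")
}

#' Plot a saliency map
#'
#' Raster heat map of the saliency map in image orientation (row 0 at the
#' top).
#'
#' @param object a `saliency_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(nrow(object)) - 1L,
                           col = seq_len(ncol(object)) - 1L)
  df$saliency <- as.vector(t(unclass(object)[,]))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (cells)", y = "y (cells)",
                  title = sprintf("Saliency map at t = %s ms", attr(object, "t")))
}

#' Plot an NSS-vs-parameter recovery curve
#'
#' @param object a `recovery_result` or `recovery_experiment`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$w_i, .data$mean_nss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2) +
    ggplot2::labs(x = "candidate w_i", y = "mean NSS")
}

#' @rdname autoplot.recovery_result
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(.data$w_i, .data$mean_nss,
                               group = interaction(.data$gen_w_i, .data$seed),
                               colour = factor(.data$gen_w_i))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "candidate w_i", y = "mean NSS",
                  colour = "generating w_i")
}

#' Plot region-mean activity trajectories
#'
#' Line plot of [region_mean_activity()] output: one curve per region over
#' simulation time.
#'
#' @param traj tibble with `t`, `region`, `mean_activity`.
#' @return A ggplot object.
#' @export
plot_region_activity <- function(traj) {
  ggplot2::ggplot(traj, ggplot2::aes(.data$t, .data$mean_activity,
                                     colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t (ms)", y = "mean activity")
}
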