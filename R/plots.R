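#' Plot a simulated trajectory
#'
#' Administrator share and per-capita energy over time, the standard view of
#' a single run: energy first rises as coordination pays off, then declines
#' as the administration grows, while the share ratchets (or, with
#' exploration, fluctuates) upward.
#'
#' @param object A `"collapse_sim"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collapse_sim <- function(object, ...) {
  df <- object$records |>
    dplyr::transmute(
      .data$t,
      `administrator share` = .data$N_A / object$params$N,
      `energy per capita` = .data$E_per_capita
    ) |>
    tidyr::pivot_longer(-"t", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble survival histogram
#'
#' @param object A `"collapse_ensemble"` object.
#' @param binwidth,censor_from Passed to [survival_histogram()].
#' @param ... Unused.
#' @return A ggplot object; the right-censored bar is drawn in its own
#'   colour.
#' @export
autoplot.collapse_ensemble <- function(object, binwidth = 250,
                                       censor_from = 5000, ...) {
  h <- survival_histogram(object, binwidth, censor_from) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::mutate(
      x = ifelse(is.finite(.data$bin_end),
                 (.data$bin_start + .data$bin_end) / 2,
                 .data$bin_start + binwidth / 2)
    )
  ggplot2::ggplot(h, ggplot2::aes(.data$x, .data$count,
                                  fill = .data$is_censored_bin)) +
    ggplot2::geom_col(width = binwidth * 0.9) +
    ggplot2::labs(x = "survival time", y = "runs",
                  fill = "right-censored") +
    ggplot2::theme_minimal()
}

#' Plot a mean-field trajectory
#'
#' @param object A `"macro_traj"` object.
#' @param ... Unused.
#' @return A ggplot object (administrator share and per-capita energy
#'   against time).
#' @export
autoplot.macro_traj <- function(object, ...) {
  df <- object$path |>
    dplyr::select("t", `administrator share` = "share",
                  `energy per capita` = "E_per_capita") |>
    tidyr::pivot_longer(-"t", names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::labs(x = "time", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a survival-time map
#'
#' Heat map of macro-approximation survival times over the `(rho, c)` plane,
#' one facet per exploration probability; capped (censored) cells are the
#' long-survival plateau.
#'
#' @param object A `"sweep_result"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(
    object$grid,
    ggplot2::aes(.data$rho, .data$c, fill = .data$survival_time)
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$p_e),
      labeller = ggplot2::label_both
    ) +
    ggplot2::scale_fill_viridis_c(name = "survival time") +
    ggplot2::labs(x = "link density rho", y = "productivity c") +
    ggplot2::theme_minimal()
}
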