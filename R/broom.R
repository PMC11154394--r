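#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a simulation into its per-step record table
#'
#' @param x A `"collapse_sim"` object.
#' @param ... Unused.
#' @return The per-step tibble
#'   (`t, R, N_L, N_C, N_A, E, E_per_capita, roc, n_flips, recruited`).
#' @export
tidy.collapse_sim <- function(x, ...) x$records

#' One-row summary of a simulation
#'
#' @param x A `"collapse_sim"` object.
#' @param ... Unused.
#' @return Tibble with `survival_time`, `censored`, `terminal_cause`,
#'   `final_share` (administrator share at termination), `max_E_per_capita`
#'   and `n_recruited`.
#' @export
glance.collapse_sim <- function(x, ...) {
  tibble::tibble(
    survival_time = x$survival_time,
    censored = x$censored,
    terminal_cause = x$terminal_cause,
    final_share = sum(x$final_state$admin) / x$params$N,
    max_E_per_capita = max(x$records$E_per_capita),
    n_recruited = sum(x$records$recruited)
  )
}

#' @rdname tidy.collapse_sim
#' @param x A `"collapse_ensemble"` object.
#' @export
tidy.collapse_ensemble <- function(x, ...) x$runs

#' @rdname glance.collapse_sim
#' @export
glance.collapse_ensemble <- function(x, ...) {
  ms <- median_survival(x)
  tibble::tibble(
    n_runs = x$n_runs,
    median_survival = ms$median,
    at_cap = ms$at_cap,
    prop_censored = mean(x$runs$censored)
  )
}

#' @rdname tidy.collapse_sim
#' @export
tidy.macro_traj <- function(x, ...) x$path

#' @rdname glance.collapse_sim
#' @export
glance.macro_traj <- function(x, ...) {
  tibble::tibble(
    survival_time = x$survival_time,
    censored = x$censored,
    final_share = x$path$share[nrow(x$path)]
  )
}

#' @rdname tidy.collapse_sim
#' @export
tidy.sweep_result <- function(x, ...) x$grid

#' @rdname glance.collapse_sim
#' @export
glance.sweep_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$grid),
    prop_at_cap = mean(x$grid$censored)
  )
}
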