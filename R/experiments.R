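#' Run an ensemble of independent simulations
#'
#' Executes `n_runs` independent [run_simulation()] calls with derived seeds
#' `base_seed, base_seed + 1, ...`; the ensemble is fully determined by
#' `(params, n_runs, base_seed)` and results are order-stable.
#'
#' @param params A [model_params()] object (its own `seed` is ignored in
#'   favour of the derived seeds).
#' @param n_runs Number of runs.
#' @param base_seed First seed of the derived sequence (defaults to
#'   `params$seed`).
#' @param keep_paths Keep per-step administrator-share and energy paths for
#'   every run (needed for micro/macro comparisons; off by default to save
#'   memory).
#' @return Object of class `"collapse_ensemble"`: list with `params`,
#'   `n_runs`, `runs` (tibble `run, seed, survival_time, censored,
#'   terminal_cause`) and, when `keep_paths = TRUE`, `paths` (long tibble
#'   `run, t, share, E_per_capita`).
#' @examples
#' ens <- run_ensemble(model_params(N = 100, t_max = 300), n_runs = 5)
#' median_survival(ens)
#' @export
run_ensemble <- function(params, n_runs, base_seed = params$seed,
                         keep_paths = FALSE) {
  stopifnot(inherits(params, "model_params"), n_runs >= 1)
  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  sims <- purrr::map(seeds, function(s) {
    p <- params
    p$seed <- s
    run_simulation(p)
  })
  runs <- tibble::tibble(
    run = seq_len(n_runs),
    seed = seeds,
    survival_time = purrr::map_int(sims, "survival_time"),
    censored = purrr::map_lgl(sims, "censored"),
    terminal_cause = purrr::map_chr(sims, "terminal_cause")
  )
  paths <- NULL
  if (keep_paths) {
    paths <- purrr::imap(sims, function(s, i) {
      tibble::tibble(
        run = i, t = s$records$t,
        share = s$records$N_A / params$N,
        E_per_capita = s$records$E_per_capita
      )
    })
    paths <- dplyr::bind_rows(paths)
  }
  structure(
    list(params = params, n_runs = n_runs, runs = runs, paths = paths),
    class = "collapse_ensemble"
  )
}

#' @export
print.collapse_ensemble <- function(x, ...) {
  ms <- median_survival(x)
  cat(sprintf(
    "<collapse_ensemble> %d runs | median survival = %s, %d censored\n",
    x$n_runs,
    if (ms$at_cap) paste0(">= ", format(ms$median)) else format(ms$median),
    sum(x$runs$censored)
  ))
  invisible(x)
}

#' Ensemble-mean administrator share path
#'
#' Mean of `N_A / N` at each time step over all runs of an ensemble built
#' with `keep_paths = TRUE`. Collapsed runs stay in the average after their
#' termination at share 1 and per-capita energy 0 (the collapse state is
#' absorbing), so the mean is always over all `n_runs` runs.
#'
#' @param ensemble A `"collapse_ensemble"` with stored paths.
#' @param t_end Horizon (defaults to the ensemble's `t_max`).
#' @return Tibble `t, share, E_per_capita` for `t = 1..t_end`.
#' @export
ensemble_mean_share <- function(ensemble, t_end = ensemble$params$t_max) {
  stopifnot(inherits(ensemble, "collapse_ensemble"))
  if (is.null(ensemble$paths)) {
    stop("ensemble was built without keep_paths = TRUE")
  }
  ensemble$paths |>
    dplyr::filter(.data$t <= t_end) |>
    tidyr::complete(
      run = seq_len(ensemble$n_runs), t = seq_len(t_end),
      fill = list(share = 1, E_per_capita = 0)
    ) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      share = mean(.data$share),
      E_per_capita = mean(.data$E_per_capita),
      .groups = "drop"
    )
}

#' Median survival time with right-censoring
#'
#' Sample median of the survival times, with censored runs entering at their
#' censoring value `t_max` (a lower bound on their true survival). For an
#' even number of runs the midpoint of the two central order statistics is
#' used, censored or not. When the median itself sits at the cap it is
#' reported as "at the cap": the true median is `>= t_max`, potentially
#' infinite, and cannot be distinguished further.
#'
#' @param result A `"collapse_ensemble"` object.
#' @return One-row tibble with `median` and `at_cap`.
#' @export
median_survival <- function(result) {
  stopifnot(inherits(result, "collapse_ensemble"))
  if (result$n_runs < 1) stop("empty ensemble")
  med <- stats::median(result$runs$survival_time)
  tibble::tibble(median = med, at_cap = med >= result$params$t_max)
}

#' Histogram of survival times with a right-censored bar
#'
#' Bins the survival times of collapsed runs into fixed-width bins and
#' accumulates all censored runs into a single terminal bar, flagged with
#' `is_censored_bin` (drawn at `t >= censor_from`, mirroring how censored
#' cases are displayed apart from genuine collapses).
#'
#' @param result A `"collapse_ensemble"` object.
#' @param binwidth Bin width in time steps.
#' @param censor_from Left edge of the terminal censored bar.
#' @return Tibble `bin_start, bin_end, count, is_censored_bin`; empty bins
#'   are kept so the histogram is directly plottable.
#' @export
survival_histogram <- function(result, binwidth = 250,
                               censor_from = 5000) {
  stopifnot(inherits(result, "collapse_ensemble"))
  if (result$n_runs < 1) stop("empty ensemble")
  t_max <- result$params$t_max
  edges <- seq(0, ceiling(t_max / binwidth) * binwidth, by = binwidth)
  obs <- result$runs$survival_time[!result$runs$censored]
  counts <- if (length(obs)) {
    tabulate(findInterval(obs, edges, left.open = TRUE),
             nbins = length(edges) - 1)
  } else {
    integer(length(edges) - 1)
  }
  dplyr::bind_rows(
    tibble::tibble(
      bin_start = edges[-length(edges)], bin_end = edges[-1],
      count = counts, is_censored_bin = FALSE
    ),
    tibble::tibble(
      bin_start = censor_from, bin_end = Inf,
      count = sum(result$runs$censored), is_censored_bin = TRUE
    )
  )
}

#' Survival-time map over link density, productivity and exploration
#'
#' Sweeps the deterministic macroscopic approximation over a
#' `(rho, c, p_e)` grid: each cell integrates the mean-field dynamics from
#' `N_A = 0` (unit-step Euler, as in [integrate_macro()]) and records the
#' survival time, capped at `t_max`. The sweep is a pure function of the
#' grid — no randomness is involved — which is what makes a dense map
#' affordable; stochastic ensembles are reserved for spot checks.
#'
#' All cells are integrated simultaneously as one vectorized state, so the
#' default 21-point axes finish in seconds.
#'
#' @param base_params A [model_params()] object giving all non-swept
#'   parameters.
#' @param rho_values,c_values,pe_values Grid axes (defaults: 21 points over
#'   the studied ranges `rho` in `[0, 0.1]`, `c` in `[1, 3]`, and `p_e` in
#'   `{0, 1/2N, 1/N, 2/N}`).
#' @return Object of class `"sweep_result"`: list with `params`, the axes,
#'   `grid` (tibble `rho, c, p_e, survival_time, censored`) and `medians`
#'   (per `(p_e, c)`: median over the `rho` axis of the survival time, with
#'   `at_cap` flag).
#' @examples
#' sw <- parameter_sweep(model_params(N = 100, t_max = 1000),
#'                       rho_values = c(0, 0.02, 0.05),
#'                       c_values = c(1, 2), pe_values = c(0, 0.02))
#' sw$medians
#' @export
parameter_sweep <- function(base_params,
                            rho_values = seq(0, 0.1, length.out = 21),
                            c_values = seq(1, 3, length.out = 21),
                            pe_values = c(0, 0.5, 1, 2) / base_params$N) {
  stopifnot(inherits(base_params, "model_params"))
  stopifnot(length(rho_values) > 0, length(c_values) > 0, length(pe_values) > 0)
  if (any(rho_values < 0 | rho_values > 1)) stop("rho grid must lie in [0, 1]")
  if (any(pe_values < 0 | pe_values > 1)) stop("p_e grid must lie in [0, 1]")
  if (any(c_values < 1)) stop("c grid must be >= 1")
  grid <- tidyr::expand_grid(
    rho = rho_values, c = c_values, p_e = pe_values
  )
  pp <- param_list(base_params)
  N <- pp$N
  t_max <- pp$t_max
  x <- numeric(nrow(grid))
  surv <- rep(NA_integer_, nrow(grid))
  Na_eps <- N^pp$a * pp$epsilon
  for (t in seq_len(t_max)) {
    q <- (1 - grid$rho)^x
    e <- ((N - x) * q)^pp$a + grid$c * ((N - x) * (1 - q))^pp$b
    xa <- ifelse(e > 0, Na_eps / e, Inf)
    rhs <- grid$p_e * (N - 2 * x) +
      (grid$rho > 0) *
        stats::pbeta(pmin(xa, 1), shape1 = pp$beta, shape2 = pp$alpha)
    x <- pmin(pmax(x + rhs, 0), N)
    hit <- is.na(surv) & x >= N - 0.5
    surv[hit] <- t
    if (!anyNA(surv)) break
  }
  grid$censored <- is.na(surv)
  grid$survival_time <- ifelse(is.na(surv), t_max, surv)
  medians <- grid |>
    dplyr::group_by(.data$p_e, .data$c) |>
    dplyr::summarise(
      median_survival = stats::median(.data$survival_time),
      at_cap = stats::median(.data$survival_time) >= t_max,
      .groups = "drop"
    )
  structure(
    list(
      params = base_params,
      rho_values = rho_values, c_values = c_values, pe_values = pe_values,
      grid = grid, medians = medians
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "<sweep_result> %d x %d x %d grid (rho x c x p_e) | %d of %d cells at the cap\n",
    length(x$rho_values), length(x$c_values), length(x$pe_values),
    sum(x$grid$censored), nrow(x$grid)
  ))
  invisible(x)
}

#' Time spent near the half-administrator metastable state
#'
#' For exploration just below the critical value `1/N` and a large
#' productivity `c`, trajectories linger near `N_A = N/2` for a long time
#' before a shock sequence finally tips them into collapse. This probe runs
#' a stochastic ensemble and measures, per run, the sojourn time inside the
#' band `N_A/N` in `[0.5 - delta, 0.5 + delta]` together with the survival
#' time.
#'
#' @param params A [model_params()] object (intended: `p_e < 1/N`, large
#'   `c`).
#' @param n_runs Number of runs.
#' @param delta Half-width of the share band (default 0.1; `delta = 0`
#'   counts only exact hits).
#' @param base_seed First derived seed.
#' @return Tibble `run, seed, sojourn_time, survival_time, censored`.
#' @export
metastability_probe <- function(params, n_runs, delta = 0.1,
                                base_seed = params$seed) {
  stopifnot(inherits(params, "model_params"), n_runs >= 1, delta >= 0)
  ens <- run_ensemble(params, n_runs, base_seed, keep_paths = TRUE)
  sojourn <- ens$paths |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(
      sojourn_time = sum(abs(.data$share - 0.5) <= delta),
      .groups = "drop"
    )
  dplyr::left_join(ens$runs, sojourn, by = "run") |>
    dplyr::select(
      "run", "seed", "sojourn_time", "survival_time", "censored"
    )
}
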