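#' Draw shock-reduced per-node resources
#'
#' The per-node resource available at a time step is
#' `R = R_max * (1 - B)` with `B ~ Beta(alpha, beta)`: `B` is the shock
#' magnitude, so `R` is usually close to `R_max` with a rare chance of a
#' severe reduction.
#'
#' @param params A [model_params()] object (must have `alpha, beta > 0`).
#' @param n Number of draws.
#' @return Numeric vector of length `n`, each value in `[0, R_max]`.
#' @export
draw_shock <- function(params, n = 1) {
  stopifnot(inherits(params, "model_params"))
  if (params$alpha <= 0 || params$beta <= 0) {
    stop(validation_error("alpha, beta: Beta shape parameters must be > 0"))
  }
  params$R_max * (1 - stats::rbeta(n, params$alpha, params$beta))
}

#' Total energy produced by the labor force
#'
#' Cobb-Douglas-style production with decreasing returns to scale:
#' `E = R * (N_L^a + c * N_C^b)`. Administrators produce nothing; an empty
#' labor force (`N_L = N_C = 0`) produces `E = 0`.
#'
#' @param N_L,N_C Counts of uncoordinated and coordinated laborers.
#' @param R Realized per-node resource (from [draw_shock()]).
#' @param params A [model_params()] object supplying `a`, `b`, `c`.
#' @return Total energy `E` (vectorized over the count/resource arguments).
#' @export
compute_energy <- function(N_L, N_C, R, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(N_L < 0) || any(N_C < 0)) stop("laborer counts must be non-negative")
  if (any(R < 0)) stop("resource R must be non-negative")
  R * (N_L^params$a + params$c * N_C^params$b)
}

#' Pick the next administrator
#'
#' Recruitment rule: if no administrators exist, the laborer with the most
#' network connections becomes the sole administrator (requires degree >= 1);
#' otherwise the coordinated laborer with the most connections becomes an
#' additional administrator. Ties in degree are broken uniformly at random
#' with the run RNG. Returns `NA` when no eligible candidate exists (e.g. an
#' edgeless graph, or no coordinated laborers left in a fragmented network),
#' in which case recruitment is skipped for that step.
#'
#' @param state A `"society"` object.
#' @return Integer node id, or `NA_integer_` when the pool is empty.
#' @export
select_recruit <- function(state) {
  stopifnot(inherits(state, "society"))
  cnt <- admin_neighbor_counts(state)
  recruit_from(state$admin, cnt, state$degree)
}

# shared candidate logic; `cnt` = administrator-neighbor counts
recruit_from <- function(admin, cnt, degree) {
  cand <- if (!any(admin)) {
    which(!admin & degree > 0L)
  } else {
    which(!admin & cnt > 0L)
  }
  if (!length(cand)) return(NA_integer_)
  d <- degree[cand]
  ties <- cand[d == max(d)]
  if (length(ties) > 1L) ties[sample.int(length(ties), 1L)] else ties
}

#' One round of random social mobility
#'
#' Every node independently switches its status with probability `p_e`:
#' administrators step down, non-administrators (whether coordinated or not)
#' step up. All flips are committed simultaneously, and laborer/coordinated
#' labels are re-derived from the final administrator set — only the
#' admin-vs-non-admin direction is stochastic.
#'
#' @param state A `"society"` object.
#' @param params A [model_params()] object supplying `p_e`.
#' @return List with `state` (updated society) and `n_flips` (number of
#'   nodes that switched).
#' @export
exploration_step <- function(state, params) {
  stopifnot(inherits(state, "society"), inherits(params, "model_params"))
  n_flips <- 0L
  if (params$p_e > 0) {
    flip <- stats::runif(state$n) < params$p_e
    n_flips <- sum(flip)
    state$admin[flip] <- !state$admin[flip]
  }
  list(state = state, n_flips = n_flips)
}

# ---------------------------------------------------------------------------
# internal mutable simulation state: environment with admin flags plus an
# incrementally maintained count of administrator neighbors per node (the
# network is static, so role classification reduces to these counts)

sim_env <- function(soc) {
  st <- new.env(parent = emptyenv())
  st$n <- soc$n
  st$nbrs <- soc$nbrs
  st$degree <- soc$degree
  st$admin <- soc$admin
  st$adm_nbr <- admin_neighbor_counts(soc)
  st$n_admin <- sum(soc$admin)
  st
}

flip_node <- function(st, v) {
  up <- !st$admin[v]
  st$admin[v] <- up
  st$n_admin <- st$n_admin + if (up) 1L else -1L
  nb <- st$nbrs[[v]]
  if (length(nb)) st$adm_nbr[nb] <- st$adm_nbr[nb] + if (up) 1L else -1L
  invisible(up)
}

# One model time step on the internal state. Fixed draw order per step:
# (1) one uniform per node for exploration (skipped entirely when p_e = 0);
# (2) one Beta shock draw; (3) a single tie-break draw, only if a
# recruitment happens and the maximum degree is tied.
step_env <- function(st, prev_E, pp) {
  n_flips <- 0L
  if (pp$p_e > 0) {
    flips <- which(stats::runif(st$n) < pp$p_e)
    n_flips <- length(flips)
    for (v in flips) flip_node(st, v)
  }
  B <- stats::rbeta(1, pp$alpha, pp$beta)
  R <- pp$R_max * (1 - B)
  N_A <- st$n_admin
  N_C <- sum(!st$admin & st$adm_nbr > 0L)
  N_L <- st$n - N_A - N_C
  E <- R * (N_L^pp$a + pp$c * N_C^pp$b)
  recruited <- FALSE
  if (E / st$n < pp$epsilon) {
    v <- recruit_from(st$admin, st$adm_nbr, st$degree)
    if (!is.na(v)) {
      flip_node(st, v) # promotion takes effect from the next step's energy
      recruited <- TRUE
    }
  }
  list(
    R = R, N_L = N_L, N_C = N_C, N_A = N_A, E = E,
    roc = if (is.null(prev_E)) NA_real_ else E - prev_E,
    n_flips = n_flips, recruited = recruited
  )
}

#' Execute one full model time step
#'
#' Composition of the model rules, in order: (1) exploration flips;
#' (2) shock draw; (3) role classification and energy production `E(t)`
#' from the post-exploration, pre-recruitment roles; (4) return on
#' complexity `roc = E(t) - E(t-1)`; (5) threshold check `E(t)/N < epsilon`
#' and, if it fires, promotion of [select_recruit()]'s candidate — the
#' promotion affects energy only from the next step onward.
#'
#' This is the single-step surface of the same engine that powers
#' [run_simulation()]; it consumes the current R RNG state.
#'
#' @param state A `"society"` object.
#' @param params A [model_params()] object.
#' @param prev_E Previous step's energy, or `NULL` on the first step.
#' @param t Time index recorded in the output row.
#' @return List with `state` (updated society) and `record`, a one-row
#'   tibble with columns
#'   `t, R, N_L, N_C, N_A, E, E_per_capita, roc, n_flips, recruited`.
#' @export
simulate_step <- function(state, params, prev_E = NULL, t = 1L) {
  stopifnot(inherits(state, "society"), inherits(params, "model_params"))
  st <- sim_env(state)
  rec <- step_env(st, prev_E, param_list(params))
  state$admin <- st$admin
  list(
    state = state,
    record = tibble::tibble(
      t = as.integer(t), R = rec$R, N_L = rec$N_L, N_C = rec$N_C,
      N_A = rec$N_A, E = rec$E, E_per_capita = rec$E / state$n,
      roc = rec$roc, n_flips = rec$n_flips, recruited = rec$recruited
    )
  )
}

#' Simulate a society until collapse or censoring
#'
#' Builds a fresh Erdos-Renyi network and iterates the model rules until
#' either every node is an administrator (collapse: no laborers remain, so
#' `E = 0` forever) or `t_max` steps have elapsed (the run is
#' right-censored). All randomness — network construction, shocks,
#' exploration and tie-breaks — flows from `params$seed` in a fixed draw
#' order, so a run is fully reproducible.
#'
#' @param params A [model_params()] object.
#' @return Object of class `"collapse_sim"`: list with
#'   \describe{
#'     \item{params}{the input parameters}
#'     \item{records}{tibble of per-step observables, one row per step
#'       (`t, R, N_L, N_C, N_A, E, E_per_capita, roc, n_flips, recruited`);
#'       role counts and `E` are post-exploration, pre-recruitment}
#'     \item{survival_time}{termination step}
#'     \item{censored}{`TRUE` iff the run reached `t_max` without collapse}
#'     \item{terminal_cause}{`"all-administrators"` or `"reached-t_max"`}
#'     \item{final_state}{the `"society"` at termination}
#'   }
#' @examples
#' sim <- run_simulation(model_params(N = 100, t_max = 200, seed = 1))
#' glance(sim)
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  pp <- param_list(params)
  withr::with_seed(pp$seed, {
    soc <- build_network(params)
    st <- sim_env(soc)
    tm <- pp$t_max
    R <- numeric(tm); N_L <- integer(tm); N_C <- integer(tm)
    N_A <- integer(tm); E <- numeric(tm); roc <- numeric(tm)
    n_flips <- integer(tm); recruited <- logical(tm)
    prev_E <- NULL
    t_end <- tm
    cause <- "reached-t_max"
    for (t in seq_len(tm)) {
      rec <- step_env(st, prev_E, pp)
      R[t] <- rec$R; N_L[t] <- rec$N_L; N_C[t] <- rec$N_C
      N_A[t] <- rec$N_A; E[t] <- rec$E; roc[t] <- rec$roc
      n_flips[t] <- rec$n_flips; recruited[t] <- rec$recruited
      prev_E <- rec$E
      if (st$n_admin == st$n) {
        t_end <- t
        cause <- "all-administrators"
        break
      }
    }
    idx <- seq_len(t_end)
    soc$admin <- st$admin
    structure(
      list(
        params = params,
        records = tibble::tibble(
          t = idx, R = R[idx], N_L = N_L[idx], N_C = N_C[idx],
          N_A = N_A[idx], E = E[idx], E_per_capita = E[idx] / pp$N,
          roc = roc[idx], n_flips = n_flips[idx], recruited = recruited[idx]
        ),
        survival_time = t_end,
        censored = cause == "reached-t_max",
        terminal_cause = cause,
        final_state = soc
      ),
      class = "collapse_sim"
    )
  })
}

#' @export
print.collapse_sim <- function(x, ...) {
  cat(sprintf(
    "<collapse_sim> N = %d, seed = %d | survival = %d (%s)%s\n",
    x$params$N, x$params$seed, x$survival_time, x$terminal_cause,
    if (x$censored) " [censored]" else ""
  ))
  invisible(x)
}

#' Energy output as a function of administration size
#'
#' Smooths the energy trajectory with a centred moving average and keys it by
#' the administration size `N_A`, reproducing the "diminishing marginal
#' returns" arc: energy first rises with complexity, peaks, then declines.
#'
#' @param result A `"collapse_sim"` object, or a data frame with columns
#'   `E` and `N_A` (and optionally `t`).
#' @param window Moving-average window length in steps (`1` leaves `E`
#'   untouched).
#' @return Tibble with columns `t`, `N_A`, `E`, `E_smooth` (NA-padded at the
#'   ends where the window does not fit).
#' @export
roc_curve <- function(result, window = 50) {
  rec <- if (inherits(result, "collapse_sim")) result$records else tibble::as_tibble(result)
  if (!nrow(rec)) stop("empty trajectory")
  stopifnot(window >= 1)
  sm <- if (window == 1) {
    rec$E
  } else {
    as.numeric(stats::filter(rec$E, rep(1 / window, window), sides = 2))
  }
  tibble::tibble(
    t = if ("t" %in% names(rec)) rec$t else seq_len(nrow(rec)),
    N_A = rec$N_A, E = rec$E, E_smooth = sm
  )
}
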