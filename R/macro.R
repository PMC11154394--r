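#' Mean-field laborer counts at a given administration size
#'
#' Under the homogeneous-density approximation, a non-administrator escapes
#' coordination only if it is linked to none of the `N_A` administrators,
#' which happens with probability `(1 - rho)^N_A`. Hence
#' `N_L = (N - N_A) (1 - rho)^N_A` and
#' `N_C = (N - N_A) (1 - (1 - rho)^N_A)`; the two always sum to `N - N_A`
#' exactly.
#'
#' @param N_A Continuous administrator count, in `[0, N]` (vectorized).
#' @param params A [model_params()] object.
#' @return Tibble with columns `N_A`, `N_L`, `N_C`.
#' @export
macro_counts <- function(N_A, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(N_A < 0 | N_A > params$N)) stop("N_A must lie in [0, N]")
  q <- (1 - params$rho)^N_A
  tibble::tibble(
    N_A = N_A,
    N_L = (params$N - N_A) * q,
    N_C = (params$N - N_A) * (1 - q)
  )
}

# deterministic energy factor e = N_L^a + c N_C^b at mean-field counts;
# lean versions (plain lists, no tibbles) are used inside integration loops
macro_energy_factor <- function(N_A, pp) {
  q <- (1 - pp$rho)^N_A
  NL <- (pp$N - N_A) * q
  NC <- (pp$N - N_A) * (1 - q)
  NL^pp$a + pp$c * NC^pp$b
}

macro_rhs_fast <- function(N_A, pp) {
  e <- macro_energy_factor(N_A, pp)
  x <- ifelse(e > 0, pp$N^pp$a * pp$epsilon / e, Inf)
  pp$p_e * (pp$N - 2 * N_A) +
    (pp$rho > 0) * stats::pbeta(pmin(x, 1), shape1 = pp$beta, shape2 = pp$alpha)
}

#' Probability that a shock triggers a recruitment
#'
#' An administrator is recruited iff `E/N < epsilon`, i.e. iff the retained
#' resource fraction `1 - B` falls below `N^a * epsilon / e` where
#' `e = N_L^a + c N_C^b` is the deterministic energy factor. Since
#' `1 - B ~ Beta(beta, alpha)` (note the swapped shapes), the probability is
#' the Beta CDF evaluated at that ratio, clamped to `[0, 1]`: when even the
#' unshocked economy cannot meet demand (`x > 1`, including the `e = 0`
#' boundary at `N_A = N`), recruitment is certain.
#'
#' @param N_A Continuous administrator count, in `[0, N]` (vectorized).
#' @param params A [model_params()] object.
#' @return Probability in `[0, 1]`.
#' @export
recruitment_probability <- function(N_A, params) {
  stopifnot(inherits(params, "model_params"))
  e <- macro_energy_factor(N_A, params)
  x <- ifelse(e > 0, params$N^params$a * params$epsilon / e, Inf)
  stats::pbeta(pmin(x, 1), shape1 = params$beta, shape2 = params$alpha)
}

#' Right-hand side of the macroscopic administrator dynamics
#'
#' `dN_A/dt = p_e (N - 2 N_A) + P(N_A)`: the exploration term balances
#' random hirings against random demotions, and `P` is the per-step
#' [recruitment_probability()] of a threshold-triggered appointment.
#'
#' In the degenerate edgeless case `rho = 0` the recruitment term is
#' dropped: without links no node can ever be coordinated, so the micro
#' model has no eligible recruit and stays in its initial state, and the
#' mean-field dynamics mirror that (only exploration, if any, moves
#' `N_A`).
#'
#' @param N_A Continuous administrator count, in `[0, N]` (vectorized).
#' @param params A [model_params()] object.
#' @return Rate of change of `N_A` per unit time.
#' @export
macro_rhs <- function(N_A, params) {
  stopifnot(inherits(params, "model_params"))
  macro_rhs_fast(N_A, params)
}

#' Integrate the macroscopic approximation forward in time
#'
#' The micro-model is a discrete-time map that recruits at most about one
#' administrator per step, so the reference integrator is explicit Euler
#' with unit time step, clipped to `[0, N]`. A continuous-time Runge-Kutta
#' alternative (`method = "ode45"`, via \pkg{deSolve}) is available for
#' comparison but is not the reference. The deterministic per-capita energy
#' path uses the expected retained resource
#' `E[R] = R_max * beta / (alpha + beta)`.
#'
#' @param params A [model_params()] object.
#' @param N_A0 Initial administrator count (default 0, the all-laborer
#'   society).
#' @param t_end Integration horizon (defaults to `t_max`).
#' @param method `"euler"` (reference) or `"ode45"`.
#' @return Object of class `"macro_traj"`: list with `params`, `path`
#'   (tibble `t, N_A, share, E_per_capita` on `t = 0..t_end`),
#'   `survival_time` (first `t` with `N_A >= N - 0.5`, the half-count
#'   reading of the discrete collapse state, or `t_end` if never reached)
#'   and `censored`.
#' @examples
#' tr <- integrate_macro(model_params(N = 100), t_end = 500)
#' glance(tr)
#' @export
integrate_macro <- function(params, N_A0 = 0, t_end = params$t_max,
                            method = c("euler", "ode45")) {
  stopifnot(inherits(params, "model_params"))
  method <- match.arg(method)
  if (N_A0 < 0 || N_A0 > params$N) stop("N_A0 must lie in [0, N]")
  N <- params$N
  pp <- param_list(params)
  if (method == "euler") {
    x <- numeric(t_end + 1)
    x[1] <- N_A0
    for (t in seq_len(t_end)) {
      x[t + 1] <- min(max(x[t] + macro_rhs_fast(x[t], pp), 0), N)
    }
  } else {
    if (!requireNamespace("deSolve", quietly = TRUE)) {
      stop("method = 'ode45' requires the deSolve package")
    }
    f <- function(t, y, parms) {
      list(macro_rhs(min(max(y, 0), N), params))
    }
    out <- deSolve::ode(
      y = N_A0, times = 0:t_end, func = f, parms = NULL, method = "ode45"
    )
    x <- pmin(pmax(out[, 2], 0), N)
  }
  e <- macro_energy_factor(x, pp)
  ER <- params$R_max * params$beta / (params$alpha + params$beta)
  hit <- which(x >= N - 0.5)
  surv <- if (length(hit)) hit[1] - 1L else t_end
  structure(
    list(
      params = params,
      path = tibble::tibble(
        t = 0:t_end, N_A = x, share = x / N, E_per_capita = ER * e / N
      ),
      survival_time = as.integer(surv),
      censored = !length(hit)
    ),
    class = "macro_traj"
  )
}

#' @export
print.macro_traj <- function(x, ...) {
  cat(sprintf(
    "<macro_traj> N = %d | survival = %d%s, final share = %.3f\n",
    x$params$N, x$survival_time, if (x$censored) " [censored]" else "",
    x$path$share[nrow(x$path)]
  ))
  invisible(x)
}

#' Fixed points of the macroscopic dynamics and their stability
#'
#' Locates all interior roots of [macro_rhs()] on `(0, N)` by sign-change
#' bracketing on a fine grid followed by `uniroot()` polishing, and labels
#' each stable/unstable by the sign of a central-difference derivative. The
#' boundaries of the clipped dynamics are reported too: `N_A = N` (the
#' collapse state) is attracting iff the rhs is still positive just below
#' it, which happens exactly for `p_e < 1/N`. Plateaus where the rhs is
#' numerically indistinguishable from zero without crossing it (large `c`,
#' tiny exploration) are reported as `"metastable"` quasi-fixed points at
#' the point of smallest |rhs|.
#'
#' @param params A [model_params()] object.
#' @param grid_n Number of grid points used for bracketing.
#' @param quasi_tol |rhs| threshold below which a non-crossing plateau is
#'   flagged as metastable.
#' @return Tibble with columns `N_A`, `kind` (`"interior"`, `"boundary"`,
#'   `"metastable"`), `stability` (`"stable"`, `"unstable"`, `"marginal"`)
#'   and `rhs` (residual rate at the reported point).
#' @export
find_fixed_points <- function(params, grid_n = 4001, quasi_tol = 1e-9) {
  stopifnot(inherits(params, "model_params"))
  N <- params$N
  xs <- seq(0, N, length.out = grid_n)
  fx <- macro_rhs(xs, params)
  h <- max(N * 1e-7, 1e-9)
  out <- list()

  add_interior <- function(lower, upper) {
    r <- stats::uniroot(
      function(x) macro_rhs(x, params),
      lower = lower, upper = upper, tol = 1e-12
    )$root
    d <- (macro_rhs(r + h, params) - macro_rhs(r - h, params)) / (2 * h)
    out[[length(out) + 1L]] <<- tibble::tibble(
      N_A = r, kind = "interior",
      stability = if (d < 0) "stable" else "unstable",
      rhs = macro_rhs(r, params)
    )
  }

  # the grid splits into "zeroish" segments (|rhs| below tolerance) and
  # signed stretches; a root is a sign change between signed stretches, a
  # zeroish segment with opposite signs on both flanks is a root that the
  # grid happens to straddle, and a zeroish segment without a flank sign
  # change is a metastable plateau (e.g. large c with tiny exploration)
  zeroish <- abs(fx) < quasi_tol
  cross <- which(!zeroish[-grid_n] & !zeroish[-1] & fx[-grid_n] * fx[-1] < 0)
  for (i in cross) add_interior(xs[i], xs[i + 1])

  if (any(zeroish)) {
    runs <- rle(zeroish)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      lo <- starts[k]; hi <- ends[k]
      left <- if (lo > 1L) fx[lo - 1L] else NA_real_
      right <- if (hi < grid_n) fx[hi + 1L] else NA_real_
      if (!is.na(left) && !is.na(right) && left * right < 0) {
        add_interior(xs[lo - 1L], xs[hi + 1L])
      } else {
        seg <- (lo:hi)[xs[lo:hi] > 0 & xs[lo:hi] < N]
        if (length(seg)) {
          j <- seg[which.min(abs(fx[seg]))]
          out[[length(out) + 1L]] <- tibble::tibble(
            N_A = xs[j], kind = "metastable", stability = "marginal",
            rhs = fx[j]
          )
        }
      }
    }
  }

  # clipped boundaries: stability from the one-sided flow
  delta <- N * 1e-9
  f_lo <- macro_rhs(delta, params)
  f_hi <- macro_rhs(N - delta, params)
  out[[length(out) + 1L]] <- tibble::tibble(
    N_A = 0, kind = "boundary",
    stability = if (f_lo < -quasi_tol) "stable"
                else if (f_lo > quasi_tol) "unstable" else "marginal",
    rhs = f_lo
  )
  out[[length(out) + 1L]] <- tibble::tibble(
    N_A = N, kind = "boundary",
    stability = if (f_hi > quasi_tol) "stable"
                else if (f_hi < -quasi_tol) "unstable" else "marginal",
    rhs = f_hi
  )
  dplyr::arrange(dplyr::bind_rows(out), .data$N_A)
}

#' Critical exploration probability for escaping collapse
#'
#' The collapse fixed point `N_A = N` of the macroscopic dynamics is
#' attracting as long as the rhs stays positive at the boundary. In the
#' limit `N_A -> N` the recruitment term tends to 1, so the boundary rate is
#' `p_e (N - 2N) + 1 = 1 - p_e N`, which changes sign exactly at
#' `p_e = 1/N`: at or above one status switch per time step, collapse is no
#' longer attracting.
#'
#' @param params A [model_params()] object (only `N` matters for the closed
#'   form; the numerical search uses the full rhs).
#' @param method `"closed_form"` (returns `1/N`) or `"numerical"`
#'   (bisection on the sign of the rhs just below the boundary; agrees with
#'   the closed form to the requested tolerance).
#' @param tol Bisection interval tolerance for the numerical method.
#' @return The critical exploration probability.
#' @export
critical_exploration <- function(params, method = c("closed_form", "numerical"),
                                 tol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  method <- match.arg(method)
  N <- params$N
  if (method == "closed_form") return(1 / N)
  delta <- N * 1e-12
  g <- function(pe) {
    p2 <- params
    p2$p_e <- pe
    macro_rhs(N - delta, p2)
  }
  lo <- 0; hi <- 1
  if (g(lo) <= 0) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Size-independent rescaling of the link density
#'
#' Replacing `rho` by `rho_N = 1 - sigma^(1/N)` makes the escape probability
#' `(1 - rho_N)^N = sigma` independent of the system size, so per-capita
#' quantities of the approximation become comparable across `N`.
#'
#' @param sigma Target escape probability, strictly inside `(0, 1)`.
#' @param N System size, `>= 1`.
#' @return The rescaled link probability `1 - sigma^(1/N)`.
#' @export
rescale_density <- function(sigma, N) {
  if (any(sigma <= 0 | sigma >= 1)) stop("sigma must lie strictly in (0, 1)")
  stopifnot(N >= 1)
  1 - sigma^(1 / N)
}
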