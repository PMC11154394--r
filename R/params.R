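#' Parameter set for the societal collapse model
#'
#' Constructs and validates the full set of scalar parameters that drive a
#' single model run: the network, the shock process, the energy production
#' function and the social-mobility ("exploration") mechanism. The defaults
#' are the study conditions used throughout the package's experiments.
#'
#' The maximum per-node resource is derived, never user-set:
#' `R_max = N / N^a = N^(1 - a)`, which normalizes the unperturbed per-capita
#' energy production of the all-laborer society to exactly 1.
#'
#' @param N Number of nodes (agents) in the network; fixed over a run.
#' @param t_max Maximum number of time steps before a run is right-censored.
#' @param alpha,beta Shape parameters of the Beta-distributed shocks
#'   `B ~ Beta(alpha, beta)`; the default `(1, 15)` makes most shocks small
#'   (`E[B] = 1/16`) with a thin tail of severe ones.
#' @param epsilon Per-capita energy threshold below which one additional
#'   administrator is recruited ("the society's vital needs").
#' @param a Output elasticity to scale of uncoordinated laborers, `0 < a <= 1`.
#' @param b Output elasticity to scale of coordinated laborers, `0 < b <= 1`
#'   (economically `a <= b < 1` is the usual regime).
#' @param c Productivity factor of coordinated laborers, `c >= 1`.
#' @param rho Link probability of the Erdos-Renyi network, in `[0, 1]`.
#' @param p_e Exploration probability: per-node, per-step probability of
#'   switching between administrator and non-administrator status.
#' @param seed Integer RNG seed; all randomness in a run flows from it.
#'
#' @return A one-row tibble of class `"model_params"` with one column per
#'   parameter plus the derived `R_max`.
#'
#' @examples
#' model_params()
#' model_params(N = 100, p_e = 0.02, seed = 42)
#' @export
model_params <- function(N = 400, t_max = 10000, alpha = 1, beta = 15,
                         epsilon = 1, a = 0.75, b = 0.75, c = 1.05,
                         rho = 0.02, p_e = 0, seed = 1L) {
  p <- tibble::tibble(
    N = as.integer(N), t_max = as.integer(t_max),
    alpha = as.numeric(alpha), beta = as.numeric(beta),
    epsilon = as.numeric(epsilon),
    a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
    rho = as.numeric(rho), p_e = as.numeric(p_e),
    seed = as.integer(seed)
  )
  problems <- validate_params(p)
  if (length(problems)) {
    stop(validation_error(problems))
  }
  p$R_max <- p$N^(1 - p$a)
  class(p) <- c("model_params", class(p))
  p
}

#' Validate a parameter table
#'
#' Checks every parameter against its admissible range and returns all
#' violations at once (so a config file with several bad values is reported
#' in full, not one error at a time).
#'
#' @param p A one-row data frame with the columns of [model_params()].
#' @return Character vector of violation messages; empty when valid.
#' @keywords internal
validate_params <- function(p) {
  msg <- character()
  chk <- function(ok, text) if (!isTRUE(ok)) msg <<- c(msg, text)
  chk(nrow(p) == 1L, "parameter table must have exactly one row")
  if (nrow(p) != 1L) return(msg)
  chk(is.finite(p$N) && p$N >= 1, "N: node count must be an integer >= 1")
  chk(is.finite(p$t_max) && p$t_max >= 1, "t_max: must be an integer >= 1")
  chk(is.finite(p$alpha) && p$alpha > 0, "alpha: Beta shape must be > 0")
  chk(is.finite(p$beta) && p$beta > 0, "beta: Beta shape must be > 0")
  chk(is.finite(p$epsilon) && p$epsilon >= 0, "epsilon: threshold must be >= 0")
  chk(is.finite(p$a) && p$a > 0 && p$a <= 1, "a: elasticity must be in (0, 1]")
  chk(is.finite(p$b) && p$b > 0 && p$b <= 1, "b: elasticity must be in (0, 1]")
  chk(is.finite(p$c) && p$c >= 1, "c: productivity factor must be >= 1")
  chk(is.finite(p$rho) && p$rho >= 0 && p$rho <= 1,
      "rho: link probability must be in [0, 1]")
  chk(is.finite(p$p_e) && p$p_e >= 0 && p$p_e <= 1,
      "p_e: exploration probability must be in [0, 1]")
  chk(is.finite(p$seed), "seed: must be a finite integer")
  msg
}

validation_error <- function(problems) {
  structure(
    class = c("collapsenet_validation_error", "error", "condition"),
    list(message = paste0(
      "invalid model parameters:\n",
      paste0("  - ", problems, collapse = "\n")
    ), call = NULL)
  )
}

# plain-list view used in hot loops (avoids tibble column access per step)
param_list <- function(params) {
  stopifnot(inherits(params, "model_params"))
  as.list(params)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  NextMethod()
  invisible(x)
}
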