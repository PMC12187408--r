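#' Integrate the deterministic delay-differential system
#'
#' Fixed-step Heun integration of the noise-free rate equations
#' `dM/dt = alpha_M f(P(t - tau)) - mu_M M`, `dP/dt = alpha_P M - mu_P P`,
#' with the delayed protein value read from a ring buffer at lag
#' `round(tau/dt)`. This is the joint limit of infinite system size and
#' infinitely fast bursting, and the zero-noise reference for all
#' stochastic tiers. The delay `tau` is snapped to the nearest multiple of
#' `dt` (a warning is issued if the adjustment exceeds 1e-9 min).
#'
#' @param params a [feedback_params()] object.
#' @param T total integration time, min.
#' @param dt step size, min; must satisfy `dt <= tau`.
#' @param history constant pre-`t = 0` state, a numeric vector
#'   `c(M, P)` (default `c(0, 0)`); the trajectory starts from the same
#'   values at `t = 0`.
#' @return A [new_trajectory()] with channels `M` and `P`.
#' @examples
#' traj <- integrate_dde(feedback_params(), T = 2000, dt = 0.5)
#' tail(traj$P, 1)  # approaches the stable fixed point
#' @export
integrate_dde <- function(params, T, dt, history = c(0, 0)) {
  stopifnot(inherits(params, "feedback_params"), T > 0, dt > 0,
            is.numeric(history), length(history) == 2L, all(history >= 0))
  if (params$tau > 0 && dt > params$tau)
    stop("`dt` must not exceed the delay tau (", params$tau, " min)", call. = FALSE)
  L <- round(params$tau / dt)
  if (abs(L * dt - params$tau) > 1e-9)
    warning(sprintf("tau snapped from %g to %g min to align with the dt grid",
                    params$tau, L * dt))
  res <- dde_kernel(params$alpha_M, params$alpha_P, params$mu_M, params$mu_P,
                    params$h, params$P0, params$tau, T, dt,
                    history[1], history[2], history[1], history[2])
  new_trajectory(res$time, list(M = res$M, P = res$P),
                 meta = list(tier = "dde", params = params, dt = dt,
                             history = history))
}
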