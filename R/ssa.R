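#' Exact delayed stochastic simulation of the full bursting model
#'
#' Statistically exact simulation of the discrete reaction system: a
#' telegraph promoter switched OFF at rate `lam * (P/P0)^h` and ON at rate
#' `lam`, transcription at rate `alpha_M * Omega` while ON with the product
#' delivered after a fixed delay `tau` (the transcript is committed at
#' initiation and arrives regardless of later promoter switching), plus
#' first-order translation and degradation. Delayed arrivals are handled as
#' scheduled events: whenever the earliest pending arrival precedes the
#' next tentative reaction, time advances to the arrival, the mRNA count is
#' incremented and the exponential clock is redrawn (valid by
#' memorylessness, and required because propensities change at arrivals).
#'
#' With `noise$lam = Inf` the promoter is eliminated and transcription
#' fires at the averaged rate `alpha_M * Omega * f(P)` (the
#' "copy-number-noise-only" tier).
#'
#' @param params a [feedback_params()] object.
#' @param noise a [noise_scales()] object; `omega` must be finite.
#' @param T total simulated time, min.
#' @param sample_dt output grid spacing, min; the piecewise-constant state
#'   is sampled by zero-order hold. If `T` is not a multiple the final
#'   partial interval is dropped with a warning.
#' @param seed integer seed.
#' @param init either `"fixed-point"` (counts `round(Omega * M*)`,
#'   `round(Omega * P*)`) or a numeric vector `c(n_M, n_P)` of molecule
#'   counts.
#' @param sigma0 initial promoter state, or `NULL` (default) to draw it
#'   Bernoulli(`f(P_init)`) from the seeded stream — the stationary
#'   conditional law of the promoter at the initial protein level.
#' @return A [new_trajectory()] with channels `M`, `P` (cu) and `sigma`;
#'   metadata records the delay bookkeeping (`n_initiated`, `n_arrived`,
#'   `queue_residue`).
#' @examples
#' traj <- simulate_full(feedback_params(), noise_scales(omega = 1, lam = 0.1),
#'                       T = 500, sample_dt = 1, seed = 1)
#' @export
simulate_full <- function(params, noise, T, sample_dt = 1, seed = 1L,
                          init = "fixed-point", sigma0 = NULL) {
  stopifnot(inherits(params, "feedback_params"), inherits(noise, "noise_scales"),
            T > 0, sample_dt > 0)
  if (!is.finite(noise$omega))
    stop("the full discrete model requires a finite system size omega", call. = FALSE)
  if (abs(T / sample_dt - round(T / sample_dt)) > 1e-9)
    warning("T is not a multiple of sample_dt; the final partial interval is dropped")
  st <- resolve_init_counts(init, params, noise$omega)
  set.seed(as.integer(seed))
  bursting <- is.finite(noise$lam)
  if (is.null(sigma0)) {
    sigma0 <- if (bursting)
      as.integer(stats::runif(1) < hill_repression(st[2] / noise$omega, params$P0, params$h))
    else 1L
  }
  res <- ssa_full_kernel(params$alpha_M, params$alpha_P, params$mu_M,
                         params$mu_P, params$h, params$P0, params$tau,
                         noise$omega, noise$lam, T, sample_dt,
                         st[1], st[2], as.integer(sigma0))
  new_trajectory(res$time, list(M = res$M, P = res$P, sigma = res$sigma),
                 meta = list(tier = if (bursting) "full" else "copy-number-only",
                             params = params, noise = noise, seed = seed,
                             sample_dt = sample_dt,
                             n_initiated = res$n_initiated,
                             n_arrived = res$n_arrived,
                             queue_residue = res$queue_residue))
}

#' Gillespie simulation of the bursting toggle switch
#'
#' Standard (non-delayed) SSA over the eight reactions of the two-gene
#' mutual-repression motif with telegraph promoters: production of each
#' protein at rate `alpha * Omega` while its promoter is ON, first-order
#' degradation, and promoter switching where each gene's OFF rate is
#' `lam * (other/P0)^h` and its ON rate is `lam`.
#'
#' @param params a [toggle_params()] object; its `noise` must have finite
#'   `omega` and `lam`.
#' @param T total simulated time, min.
#' @param sample_dt output grid spacing, min.
#' @param seed integer seed.
#' @param init numeric `c(A, B)` initial concentrations in cu (converted to
#'   counts via `Omega`), default `c(1, 1)`.
#' @param sigma0 integer `c(sigma_A, sigma_B)` or `NULL` to draw each
#'   Bernoulli from the stationary conditional law given the opposing
#'   protein.
#' @return A [new_trajectory()] with channels `A`, `B`, `sigma_A`,
#'   `sigma_B`.
#' @examples
#' tp <- toggle_params()
#' traj <- simulate_toggle_ssa(tp, T = 2000, sample_dt = 1, seed = 1)
#' @export
simulate_toggle_ssa <- function(params, T, sample_dt = 1, seed = 1L,
                                init = c(1, 1), sigma0 = NULL) {
  stopifnot(inherits(params, "toggle_params"), T > 0, sample_dt > 0,
            is.numeric(init), length(init) == 2L, all(init >= 0))
  noise <- params$noise
  if (!is.finite(noise$omega) || !is.finite(noise$lam))
    stop("the discrete toggle model requires finite omega and lam", call. = FALSE)
  nA <- round(noise$omega * init[1]); nB <- round(noise$omega * init[2])
  set.seed(as.integer(seed))
  if (is.null(sigma0)) {
    sigma0 <- c(
      as.integer(stats::runif(1) < hill_repression(nB / noise$omega, params$P0, params$h)),
      as.integer(stats::runif(1) < hill_repression(nA / noise$omega, params$P0, params$h)))
  }
  res <- ssa_toggle_kernel(params$alpha, params$mu, params$h, params$P0,
                           noise$omega, noise$lam, T, sample_dt,
                           nA, nB, as.integer(sigma0[1]), as.integer(sigma0[2]))
  new_trajectory(res$time,
                 list(A = res$A, B = res$B,
                      sigma_A = res$sigma_A, sigma_B = res$sigma_B),
                 meta = list(tier = "toggle-ssa", params = params, seed = seed,
                             sample_dt = sample_dt))
}

# init -> molecule counts c(n_M, n_P)
resolve_init_counts <- function(init, params, omega) {
  if (identical(init, "fixed-point")) {
    fp <- solve_fixed_point(params)
    c(round(omega * fp$M_star), round(omega * fp$P_star))
  } else {
    stopifnot(is.numeric(init), length(init) == 2L, all(init >= 0))
    round(init)
  }
}
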