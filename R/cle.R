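#' Instantaneous mRNA noise variance of the extended CLE
#'
#' The white-noise variance (per unit time) driving the mRNA equation of
#' the extended chemical Langevin equation. Two contributions: a bursting
#' term `(alpha_M^2/lam) * 2 (Pd/P0)^h / (1 + (Pd/P0)^h)^3` from the
#' telegraph promoter, and the classical copy-number term
#' `(1/Omega) * (alpha_M f(Pd) + mu_M M)`. A contribution vanishes exactly
#' when its scale parameter is `Inf`.
#'
#' @param P_delayed delayed protein concentration `P(t - tau)`, cu (>= 0).
#' @param params a [feedback_params()] object.
#' @param noise a [noise_scales()] object.
#' @param M current mRNA concentration, cu (>= 0).
#' @return Variance in cu^2/min, always >= 0.
#' @examples
#' fp <- feedback_params()
#' noise_variance_M(fp$P0, fp, noise_scales(omega = Inf, lam = 10), M = 1)
#' # = alpha_M^2 / (4 * lam)
#' @export
noise_variance_M <- function(P_delayed, params, noise, M) {
  stopifnot(inherits(params, "feedback_params"), inherits(noise, "noise_scales"))
  if (any(P_delayed < 0) || any(M < 0))
    stop("`P_delayed` and `M` must be nonnegative (clamp first)", call. = FALSE)
  x <- (P_delayed / params$P0)^params$h
  burst <- if (is.finite(noise$lam))
    (params$alpha_M^2 / noise$lam) * 2 * x / (1 + x)^3 else 0
  copy <- if (is.finite(noise$omega))
    (params$alpha_M / (1 + x) + params$mu_M * M) / noise$omega else 0
  burst + copy
}

#' Simulate the extended chemical Langevin equation
#'
#' Euler-Maruyama integration of the coupled SDEs for mRNA and protein
#' concentration with independent Gaussian increments: the mRNA noise
#' variance is [noise_variance_M()] (copy-number plus bursting
#' contributions) and the protein noise variance is the classical
#' `(1/Omega)(alpha_P M + mu_P P)`. The delayed protein value is read from
#' a ring buffer at lag `round(tau/dt)`. The state is clamped at zero after
#' each step.
#'
#' By default the mRNA drift is `alpha_M f(P(t - tau)) - mu_M M`, the form
#' consistent with the deterministic rate equations and with the
#' `alpha_M^2` scale of the bursting noise; `drift_alpha_m = FALSE` drops
#' the prefactor `alpha_M` in front of `f`.
#'
#' @param params a [feedback_params()] object.
#' @param noise a [noise_scales()] object (`Inf` entries switch the
#'   corresponding noise source off; with both infinite the scheme reduces
#'   to an Euler integration of the deterministic system).
#' @param T total simulated time, min.
#' @param dt integration step, min (default 0.01); must satisfy
#'   `dt <= tau`.
#' @param seed integer seed.
#' @param init either `"fixed-point"` or numeric `c(M, P)` in cu.
#' @param history_fill pre-`t = 0` value of the delayed protein channel;
#'   default the initial `P`.
#' @param sample_dt spacing of the stored grid, min (default `dt`); must
#'   be a multiple of `dt`. Integration always proceeds at `dt`.
#' @param drift_alpha_m logical, see Details.
#' @return A [new_trajectory()] with channels `M` and `P`.
#' @examples
#' traj <- simulate_cle(feedback_params(), noise_scales(omega = 100, lam = 10),
#'                      T = 500, dt = 0.01, seed = 1, sample_dt = 1)
#' @export
simulate_cle <- function(params, noise, T, dt = 0.01, seed = 1L,
                         init = "fixed-point", history_fill = NULL,
                         sample_dt = dt, drift_alpha_m = TRUE) {
  stopifnot(inherits(params, "feedback_params"), inherits(noise, "noise_scales"),
            T > 0, dt > 0)
  if (params$tau > 0 && dt > params$tau)
    stop("`dt` must not exceed the delay tau", call. = FALSE)
  thin <- round(sample_dt / dt)
  if (abs(thin * dt - sample_dt) > 1e-9 * sample_dt || thin < 1)
    stop("`sample_dt` must be a positive multiple of `dt`", call. = FALSE)
  if (identical(init, "fixed-point")) {
    fp <- solve_fixed_point(params)
    init <- c(fp$M_star, fp$P_star)
  }
  stopifnot(is.numeric(init), length(init) == 2L, all(init >= 0))
  if (is.null(history_fill)) history_fill <- init[2]
  set.seed(as.integer(seed))
  res <- cle_kernel(params$alpha_M, params$alpha_P, params$mu_M, params$mu_P,
                    params$h, params$P0, params$tau, noise$omega, noise$lam,
                    isTRUE(drift_alpha_m), T, dt, as.integer(thin),
                    init[1], init[2], history_fill)
  new_trajectory(res$time, list(M = res$M, P = res$P),
                 meta = list(tier = "cle", params = params, noise = noise,
                             seed = seed, dt = dt, sample_dt = sample_dt,
                             drift_alpha_m = drift_alpha_m))
}

#' Simulate the linear-noise approximation
#'
#' Euler-Maruyama integration of the linearised fluctuation dynamics about
#' the deterministic fixed point: `dm = (alpha_M f'(P*) p(t - tau) -
#' mu_M m) dt + sigma_M dW_M`, `dp = (alpha_P m - mu_P p) dt +
#' sigma_P dW_P`, with constant noise amplitudes from
#' [noise_amplitudes()]. Fluctuations may be negative; no clamping is
#' applied. The returned channels `m` and `p` are deviations from
#' `(M*, P*)` in cu.
#'
#' @inheritParams simulate_cle
#' @param init numeric `c(m, p)` initial fluctuation, default `c(0, 0)`.
#' @return A [new_trajectory()] with channels `m` and `p`.
#' @examples
#' traj <- simulate_lna(feedback_params(), noise_scales(omega = 100, lam = 10),
#'                      T = 500, dt = 0.01, seed = 1, sample_dt = 1)
#' @export
simulate_lna <- function(params, noise, T, dt = 0.01, seed = 1L,
                         init = c(0, 0), sample_dt = dt) {
  stopifnot(inherits(params, "feedback_params"), inherits(noise, "noise_scales"),
            T > 0, dt > 0, is.numeric(init), length(init) == 2L)
  if (params$tau > 0 && dt > params$tau)
    stop("`dt` must not exceed the delay tau", call. = FALSE)
  thin <- round(sample_dt / dt)
  if (abs(thin * dt - sample_dt) > 1e-9 * sample_dt || thin < 1)
    stop("`sample_dt` must be a positive multiple of `dt`", call. = FALSE)
  fp <- solve_fixed_point(params)
  amp <- noise_amplitudes(params, noise)
  gain <- params$alpha_M * hill_derivative(fp$P_star, params$P0, params$h)
  set.seed(as.integer(seed))
  res <- lna_kernel(gain, params$alpha_P, params$mu_M, params$mu_P,
                    params$tau, amp$sigma2_M, amp$sigma2_P,
                    T, dt, as.integer(thin), init[1], init[2])
  new_trajectory(res$time, list(m = res$m, p = res$p),
                 meta = list(tier = "lna", params = params, noise = noise,
                             seed = seed, dt = dt, sample_dt = sample_dt,
                             fixed_point = fp, amplitudes = amp))
}

#' Simulate the toggle-switch chemical Langevin equation
#'
#' Two-channel Euler-Maruyama scheme with drifts `alpha f(B) - mu A` and
#' `alpha f(A) - mu B` and independent noise variances combining the
#' bursting term `(alpha^2/lam) * 2 (x/P0)^h / (1 + (x/P0)^h)^3` (with `x`
#' the opposing protein) and the copy-number term
#' `(1/Omega)(alpha f(x) + mu self)`. States are clamped at zero.
#'
#' @param params a [toggle_params()] object.
#' @param T total simulated time, min.
#' @param dt integration step, min (default 0.01).
#' @param seed integer seed.
#' @param init numeric `c(A, B)` in cu, default `c(1, 1)`.
#' @param sample_dt stored grid spacing, a multiple of `dt`.
#' @param drift_alpha logical; `FALSE` drops the `alpha` prefactor in the
#'   drifts (literal reduced-rate reading; identical when `alpha = 1`).
#' @return A [new_trajectory()] with channels `A` and `B`.
#' @examples
#' traj <- simulate_toggle_cle(toggle_params(), T = 2000, dt = 0.01,
#'                             seed = 1, sample_dt = 1)
#' @export
simulate_toggle_cle <- function(params, T, dt = 0.01, seed = 1L,
                                init = c(1, 1), sample_dt = dt,
                                drift_alpha = TRUE) {
  stopifnot(inherits(params, "toggle_params"), T > 0, dt > 0,
            is.numeric(init), length(init) == 2L, all(init >= 0))
  thin <- round(sample_dt / dt)
  if (abs(thin * dt - sample_dt) > 1e-9 * sample_dt || thin < 1)
    stop("`sample_dt` must be a positive multiple of `dt`", call. = FALSE)
  noise <- params$noise
  set.seed(as.integer(seed))
  res <- cle_toggle_kernel(params$alpha, params$mu, params$h, params$P0,
                           noise$omega, noise$lam, isTRUE(drift_alpha),
                           T, dt, as.integer(thin), init[1], init[2])
  new_trajectory(res$time, list(A = res$A, B = res$B),
                 meta = list(tier = "toggle-cle", params = params, seed = seed,
                             dt = dt, sample_dt = sample_dt))
}
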