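# Reference parameter set of the neural-progenitor feedback oscillator
# (concentrations in cu, time in min); the package defaults equal these.
ref_params <- function() feedback_params()

# Small linear-friendly parameter set for fast oracle checks
small_params <- function(P0 = 1e30, h = 2, tau = 5)
  feedback_params(alpha_M = 5, alpha_P = 2, mu_M = 0.3, mu_P = 0.1,
                  h = h, P0 = P0, tau = tau)

# Closed-form solution of the constant-input linear cascade
#   dM/dt = u - mu_M M,  dP/dt = alpha_P M - mu_P P
# starting from (M0, P0c) -- the matrix-exponential oracle for a 2x2
# triangular system, valid for mu_M != mu_P.
cascade_closed_form <- function(t, u, alpha_P, mu_M, mu_P, M0, P0c) {
  Minf <- u / mu_M
  M <- Minf + (M0 - Minf) * exp(-mu_M * t)
  Pinf <- alpha_P * Minf / mu_P
  c1 <- alpha_P * (M0 - Minf) / (mu_P - mu_M)
  c2 <- P0c - Pinf - c1
  P <- Pinf + c1 * exp(-mu_M * t) + c2 * exp(-mu_P * t)
  list(M = M, P = P)
}

# Stationary covariance of the linear cascade driven by white noise
# (Lyapunov solution):
#   dm = -mu_M m dt + sigma_M dW1,  dp = (alpha_P m - mu_P p) dt + sigma_P dW2
lyapunov_var_p <- function(alpha_P, mu_M, mu_P, s2M, s2P) {
  v_m <- s2M / (2 * mu_M)
  c_mp <- alpha_P * v_m / (mu_M + mu_P)
  (alpha_P * c_mp + s2P / 2) / mu_P
}

# build a plain trajectory from a vector for analysis tests
vec_traj <- function(x, dt = 1, channel = "P") {
  chan <- stats::setNames(list(x), channel)
  new_trajectory(seq(0, by = dt, length.out = length(x)), chan,
                 meta = list(tier = "synthetic"))
}
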