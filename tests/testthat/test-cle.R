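test_that("mRNA noise variance reproduces its closed-form special cases", {
  p <- ref_params()
  # at the repression threshold with copy-number noise off: alpha_M^2/(4 lam)
  expect_equal(noise_variance_M(p$P0, p, noise_scales(omega = Inf, lam = 10),
                                M = 3),
               p$alpha_M^2 / (4 * 10))
  # bursting off: the classical CLE variance
  ns <- noise_scales(omega = 50, lam = Inf)
  expect_equal(noise_variance_M(1000, p, ns, M = 2),
               (p$alpha_M * hill_repression(1000, p$P0, p$h) + p$mu_M * 2) / 50)
  # both off: zero
  expect_equal(noise_variance_M(1000, p, noise_scales(Inf, Inf), M = 2), 0)
  expect_error(noise_variance_M(-1, p, ns, M = 1), "nonnegative")
  # nonnegative over a sweep of states
  set.seed(1)
  v <- noise_variance_M(runif(100, 0, 1e5), p, noise_scales(3, 0.2),
                        M = runif(100, 0, 100))
  expect_true(all(v >= 0))
})

test_that("CLE noise variance at the fixed point equals the LNA amplitude", {
  p <- ref_params()
  ns <- noise_scales(omega = 100, lam = 10)
  amp <- noise_amplitudes(p, ns)
  fp <- solve_fixed_point(p)
  expect_equal(noise_variance_M(fp$P_star, p, ns, fp$M_star), amp$sigma2_M,
               tolerance = 1e-12)
})

test_that("zero-noise CLE tracks the deterministic delay equation", {
  p <- ref_params()
  ns <- noise_scales(omega = Inf, lam = Inf)
  tr <- simulate_cle(p, ns, T = 500, dt = 0.01, seed = 1, init = c(0, 0),
                     history_fill = 0, sample_dt = 1)
  dde <- integrate_dde(p, T = 500, dt = 0.01, history = c(0, 0))
  idx <- match(tr$time, dde$time)
  fp <- solve_fixed_point(p)
  expect_lt(max(abs(tr$P - dde$P[idx])) / fp$P_star, 0.01)
})

test_that("clamped silent system stays exactly at zero", {
  p <- feedback_params(alpha_M = 0, alpha_P = 2, mu_M = 0.3, mu_P = 0.1,
                       h = 2, P0 = 10, tau = 2)
  tr <- simulate_cle(p, noise_scales(omega = 10, lam = 5), T = 100,
                     dt = 0.01, seed = 9, init = c(0, 0), sample_dt = 1)
  expect_true(all(tr$M == 0))
  expect_true(all(tr$P == 0))
})

test_that("CLE and LNA are seed-deterministic", {
  p <- ref_params()
  ns <- noise_scales(omega = 100, lam = 10)
  a <- simulate_cle(p, ns, T = 100, dt = 0.01, seed = 5, sample_dt = 1)
  b <- simulate_cle(p, ns, T = 100, dt = 0.01, seed = 5, sample_dt = 1)
  expect_identical(a$P, b$P)
  la <- simulate_lna(p, ns, T = 100, dt = 0.01, seed = 5, sample_dt = 1)
  lb <- simulate_lna(p, ns, T = 100, dt = 0.01, seed = 5, sample_dt = 1)
  expect_identical(la$p, lb$p)
})

test_that("LNA fluctuations are centred and decay without driving noise", {
  p <- ref_params()
  # the linearised oscillator is underdamped, so allow several damping times
  tr <- simulate_lna(p, noise_scales(omega = Inf, lam = Inf), T = 3e4,
                     dt = 0.05, seed = 2, init = c(5, 5), sample_dt = 10)
  expect_lt(abs(tr$m[nrow(tr)]), 1e-4)
  expect_lt(abs(tr$p[nrow(tr)]), 1e-3)
  tr2 <- simulate_lna(p, noise_scales(omega = 100, lam = 10), T = 2e4,
                      dt = 0.02, seed = 3, sample_dt = 1)
  st <- stationary_std(tr2, "p", 500)
  expect_lt(abs(st$mean), 3 * st$Sigma / sqrt(st$n_effective / 250))
})

test_that("stationary LNA variance scales exactly as 1/lam and 1/Omega", {
  p <- ref_params()
  # bursting only: quadrupling lam quarters the variance
  s1 <- sigma_from_spectrum(p, noise_scales(omega = Inf, lam = 0.5))
  s2 <- sigma_from_spectrum(p, noise_scales(omega = Inf, lam = 2))
  expect_equal(s1^2 / s2^2, 4, tolerance = 1e-8)
  # copy-number only: same in Omega
  s3 <- sigma_from_spectrum(p, noise_scales(omega = 25, lam = Inf))
  s4 <- sigma_from_spectrum(p, noise_scales(omega = 100, lam = Inf))
  expect_equal(s3^2 / s4^2, 4, tolerance = 1e-8)
})

test_that("noise-free toggle CLE lands on a deterministic fixed point", {
  tp <- toggle_params(noise = noise_scales(omega = Inf, lam = Inf))
  tr <- simulate_toggle_cle(tp, T = 2000, dt = 0.01, seed = 1,
                            init = c(1, 1), sample_dt = 1)
  fps <- toggle_fixed_points(tp)
  endA <- tr$A[nrow(tr)]; endB <- tr$B[nrow(tr)]
  d <- min(sqrt((fps$A - endA)^2 + (fps$B - endB)^2))
  expect_lt(d, 1e-3)
})

test_that("bursting toggle CLE reproduces the high/low state occupancy", {
  tr <- simulate_toggle_cle(toggle_params(), T = 5000, dt = 0.01, seed = 6,
                            init = c(1, 1), sample_dt = 1)
  mA <- mean(tr$A[tr$time >= 1000]); mB <- mean(tr$B[tr$time >= 1000])
  expect_lt(abs(max(mA, mB) - 9) / 9, 0.15)
  expect_lt(abs(min(mA, mB) - 1), 0.6)
})

test_that("toggle CLE with bursting off reduces to the classical two-species CLE", {
  # variance terms must equal (1/Omega)(alpha f + mu x) only; compare the
  # stationary spread against an independent classical run at large lam
  tp_inf <- toggle_params(noise = noise_scales(omega = 100, lam = Inf))
  tp_fast <- toggle_params(noise = noise_scales(omega = 100, lam = 1e5))
  a <- stationary_std(simulate_toggle_cle(tp_inf, T = 2e4, dt = 0.01,
                                          seed = 3, init = c(1, 9),
                                          sample_dt = 1), "A", 2000)
  b <- stationary_std(simulate_toggle_cle(tp_fast, T = 2e4, dt = 0.01,
                                          seed = 4, init = c(1, 9),
                                          sample_dt = 1), "A", 2000)
  expect_lt(abs(a$Sigma - b$Sigma) / b$Sigma, 0.2)
})

test_that("configuration errors are raised before any integration", {
  p <- ref_params()
  expect_error(simulate_cle(p, noise_scales(1, 1), T = 100, dt = 50), "tau")
  expect_error(simulate_cle(p, noise_scales(1, 1), T = 100, dt = 0.01,
                            sample_dt = 0.025), "multiple")
})
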