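test_that("hill repression matches its defining values and domain rules", {
  expect_equal(hill_repression(24201.01, 24201.01, 4.78), 0.5)
  expect_equal(hill_repression(0, 10, 3), 1)
  expect_equal(hill_repression(2 * 7, 7, 2), 0.2)
  expect_equal(hill_repression(5, Inf, 2), 1)  # constitutive limit
  expect_error(hill_repression(-1, 10, 2), "nonnegative")
})

test_that("hill repression is strictly decreasing and its derivative negative", {
  set.seed(42)
  for (i in 1:25) {
    P0 <- runif(1, 0.1, 1e4); h <- runif(1, 0.5, 8)
    P <- sort(runif(20, 1e-3, 5 * P0))
    f <- hill_repression(P, P0, h)
    expect_true(all(diff(f) < 0))
    expect_true(all(hill_derivative(P, P0, h) < 0))
  }
})

test_that("hill derivative agrees with a central finite difference", {
  set.seed(7)
  for (i in 1:25) {
    P0 <- runif(1, 0.5, 1e4); h <- runif(1, 0.6, 8)
    P <- runif(5, 0.05 * P0, 4 * P0)
    eps <- 1e-6 * P
    fd <- (hill_repression(P + eps, P0, h) - hill_repression(P - eps, P0, h)) /
      (2 * eps)
    expect_equal(hill_derivative(P, P0, h), fd, tolerance = 1e-6)
  }
  expect_equal(hill_derivative(100, 100, 3), -3 / (4 * 100))
  expect_equal(hill_derivative(0, 10, 2), 0)
  expect_error(hill_derivative(0, 10, 0.5), "diverges")
})

test_that("feedback fixed point solves the stationarity equations", {
  fp <- solve_fixed_point(ref_params())
  p <- ref_params()
  K <- p$alpha_M * p$alpha_P / (p$mu_M * p$mu_P)
  expect_lt(abs(fp$P_star * (1 + (fp$P_star / p$P0)^p$h) - K) / fp$P_star, 1e-8)
  expect_lt(abs(p$alpha_P * fp$M_star - p$mu_P * fp$P_star), 1e-8 * fp$P_star)
  # no-repression limit: P* = K
  p2 <- feedback_params(P0 = 1e25)
  expect_equal(solve_fixed_point(p2)$P_star, K, tolerance = 1e-10)
})

test_that("fixed point agrees with an independent bisection oracle", {
  p <- ref_params()
  K <- p$alpha_M * p$alpha_P / (p$mu_M * p$mu_P)
  g <- function(P) P * (1 + (P / p$P0)^p$h) - K
  lo <- 0; hi <- K
  for (i in 1:200) {  # plain repeated halving, independent of the solver
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(solve_fixed_point(p)$P_star, (lo + hi) / 2, tolerance = 1e-8)
})

test_that("toggle fixed points contain the exact high/low pair", {
  fps <- toggle_fixed_points(toggle_params())
  expect_equal(nrow(fps), 3L)
  expect_equal(fps$A[1], 1, tolerance = 1e-9)
  expect_equal(fps$B[1], 9, tolerance = 1e-9)
  expect_equal(fps$A[3], 9, tolerance = 1e-9)
  expect_equal(fps$B[3], 1, tolerance = 1e-9)
  # symmetric solution is the positive root of x^3 + 9 x - 90
  roots <- polyroot(c(-90, 9, 0, 1))
  x <- Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 0])
  expect_equal(fps$A[2], x, tolerance = 1e-9)
  expect_equal(fps$B[2], x, tolerance = 1e-9)
  expect_lt(max(toggle_residual(fps, toggle_params())), 1e-10)
})

test_that("toggle fixed-point set is scale-invariant and swap-symmetric", {
  a <- toggle_fixed_points(toggle_params(alpha = 1, mu = 0.1))
  b <- toggle_fixed_points(toggle_params(alpha = 5, mu = 0.5))
  expect_equal(a$A, b$A, tolerance = 1e-9)
  expect_equal(a$B, b$B, tolerance = 1e-9)
  # swapping channels permutes the set
  expect_equal(sort(a$A), sort(a$B), tolerance = 1e-9)
})

test_that("DDE integration holds the fixed point and matches the linear cascade", {
  p <- ref_params()
  fp <- solve_fixed_point(p)
  tr <- integrate_dde(p, T = 500, dt = 0.5, history = c(fp$M_star, fp$P_star))
  expect_lt(max(abs(tr$P - fp$P_star)) / fp$P_star, 1e-6)
  # no feedback (f == 1), zero delay: closed-form two-exponential solution
  p2 <- small_params(P0 = 1e30, tau = 0)
  tr2 <- integrate_dde(p2, T = 50, dt = 0.002, history = c(0, 0))
  cf <- cascade_closed_form(tr2$time, p2$alpha_M, p2$alpha_P, p2$mu_M,
                            p2$mu_P, 0, 0)
  expect_equal(tr2$M, cf$M, tolerance = 1e-6)
  expect_equal(tr2$P, cf$P, tolerance = 1e-6)
})

test_that("DDE relaxes to the fixed point from empty history", {
  p <- ref_params()
  fp <- solve_fixed_point(p)
  tr <- integrate_dde(p, T = 5000, dt = 0.1, history = c(0, 0))
  expect_lt(abs(tr$P[nrow(tr)] - fp$P_star) / fp$P_star, 0.01)
  # decaying oscillations: early overshoot above the fixed point
  expect_gt(max(tr$P), fp$P_star * 1.05)
})

test_that("DDE integration converges as the step shrinks", {
  p <- ref_params()
  e <- sapply(c(0.44, 0.22, 0.11), function(dt) {
    tr <- integrate_dde(p, T = 1000, dt = dt, history = c(0, 0))
    tr$P[nrow(tr)]
  })
  err1 <- abs(e[1] - e[3]); err2 <- abs(e[2] - e[3])
  expect_lt(err2, err1)
})

test_that("DDE agrees with an independent solver on the reference set", {
  skip_if_not_installed("deSolve")
  p <- ref_params()
  rhs <- function(t, y, parms) {
    Pd <- if (t < p$tau) 0 else deSolve::lagvalue(t - p$tau, 2)
    list(c(p$alpha_M * hill_repression(Pd, p$P0, p$h) - p$mu_M * y[1],
           p$alpha_P * y[1] - p$mu_P * y[2]))
  }
  times <- seq(0, 1000, by = 1)
  ref <- deSolve::dede(c(0, 0), times, rhs, NULL)
  tr <- integrate_dde(p, T = 1000, dt = 0.05, history = c(0, 0))
  idx <- match(times, tr$time)
  scale <- max(ref[, 3])
  expect_lt(max(abs(tr$P[idx] - ref[, 3])) / scale, 1e-3)
})

test_that("parameter validation rejects unusable values", {
  expect_error(feedback_params(mu_M = -1), "positive")
  expect_error(feedback_params(h = 0), "positive")
  expect_error(noise_scales(omega = 0), "positive")
  expect_error(toggle_params(mu = 0), "positive")
  expect_error(integrate_dde(ref_params(), T = 100, dt = 50), "tau")
  # degenerate-but-valid limits
  expect_silent(feedback_params(alpha_M = 0))
  expect_silent(feedback_params(tau = 0))
  expect_silent(noise_scales(omega = Inf, lam = Inf))
})
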