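test_that("pure-death system goes extinct and stays extinct", {
  p <- feedback_params(alpha_M = 0, alpha_P = 21.56, mu_M = 0.1, mu_P = 0.1,
                       h = 2, P0 = 100, tau = 1)
  tr <- simulate_full(p, noise_scales(omega = 1, lam = 1), T = 500,
                      sample_dt = 1, seed = 3, init = c(50, 50))
  expect_equal(tr$M[nrow(tr)], 0)
  expect_equal(tr$P[nrow(tr)], 0)
  # once both hit zero nothing can be produced again
  t0 <- min(which(tr$M == 0 & tr$P == 0))
  expect_true(all(tr$M[t0:nrow(tr)] == 0))
  expect_true(all(tr$P[t0:nrow(tr)] == 0))
})

test_that("unrepressed stationary mRNA matches the immigration-death mean", {
  # no feedback (huge P0), promoter stays ON; translation de-weighted so the
  # protein channel stays cheap without affecting the mRNA law
  p <- feedback_params(alpha_M = 39.93, alpha_P = 0.01, mu_M = log(2) / 30,
                       mu_P = 1, h = 4.78, P0 = 1e12, tau = 33)
  tr <- simulate_full(p, noise_scales(omega = 1, lam = 1), T = 6000,
                      sample_dt = 1, seed = 11, init = "fixed-point")
  m <- mean(tr$M[tr$time >= 500])
  target <- p$alpha_M / p$mu_M  # 1728 molecules at Omega = 1
  expect_lt(abs(m - target) / target, 0.02)
})

test_that("stationary mRNA law is Poisson in the no-delay no-feedback reduction", {
  # lam = Inf selects the averaged Hill propensity; P0 huge makes it constant
  p <- feedback_params(alpha_M = 5, alpha_P = 0.001, mu_M = 1, mu_P = 1,
                       h = 2, P0 = 1e12, tau = 0)
  tr <- simulate_full(p, noise_scales(omega = 1, lam = Inf), T = 8e5,
                      sample_dt = 8, seed = 21, init = c(5, 0))
  n <- tr$M[tr$time >= 80]  # samples 8 relaxation times apart
  lambda_hat <- p$alpha_M / p$mu_M
  kmax <- max(n)
  obs <- tabulate(n + 1, nbins = kmax + 1)
  pr <- dpois(0:kmax, lambda_hat)
  pr[kmax + 1] <- pr[kmax + 1] + ppois(kmax, lambda_hat, lower.tail = FALSE)
  keep <- pr * length(n) >= 5
  obs2 <- obs[keep]; pr2 <- pr[keep]
  if (any(!keep)) {
    obs2 <- c(obs2, sum(obs[!keep]))
    pr2 <- c(pr2, sum(pr[!keep]))
  }
  gof <- suppressWarnings(chisq.test(obs2, p = pr2 / sum(pr2)))
  expect_gt(gof$p.value, 0.01)
})

test_that("sampled concentrations are integer multiples of 1/Omega", {
  p <- ref_params()
  tr <- simulate_full(p, noise_scales(omega = 7, lam = 1), T = 200,
                      sample_dt = 1, seed = 5)
  expect_true(all(abs(tr$M * 7 - round(tr$M * 7)) < 1e-9))
  expect_true(all(abs(tr$P * 7 - round(tr$P * 7)) < 1e-9))
  expect_true(all(tr$sigma %in% c(0L, 1L)))
})

test_that("identical seeds reproduce trajectories bit for bit", {
  p <- ref_params()
  ns <- noise_scales(omega = 1, lam = 0.1)
  a <- simulate_full(p, ns, T = 300, sample_dt = 1, seed = 99)
  b <- simulate_full(p, ns, T = 300, sample_dt = 1, seed = 99)
  expect_identical(a$M, b$M)
  expect_identical(a$P, b$P)
  expect_identical(a$sigma, b$sigma)
  c <- simulate_full(p, ns, T = 300, sample_dt = 1, seed = 100)
  expect_false(identical(a$P, c$P))
})

test_that("delay bookkeeping balances initiations, arrivals and queue residue", {
  p <- ref_params()
  tr <- simulate_full(p, noise_scales(omega = 1, lam = 0.1), T = 2000,
                      sample_dt = 1, seed = 7)
  meta <- trajectory_meta(tr)
  expect_gt(meta$n_initiated, 0)
  expect_equal(meta$n_initiated, meta$n_arrived + meta$queue_residue)
})

test_that("fast switching approaches the averaged-promoter tier", {
  # Sigma_P with a large but finite bursting parameter matches the
  # lam = Inf reduction within Monte-Carlo resolution (scaled system size)
  p <- ref_params()
  sig <- function(lam, seeds) {
    trs <- lapply(seeds, function(s)
      simulate_full(p, noise_scales(omega = 10, lam = lam), T = 2500,
                    sample_dt = 1, seed = s))
    sapply(trs, function(tr) stationary_std(tr, "P", 500)$Sigma)
  }
  s_fast <- sig(1e4, 1:4)
  s_inf <- sig(Inf, 11:14)
  se <- sqrt(var(s_fast) / 4 + var(s_inf) / 4)
  expect_lt(abs(mean(s_fast) - mean(s_inf)), max(2 * se, 0.05 * mean(s_inf)))
})

test_that("toggle SSA settles into one asymmetric state in the fast-bursting regime", {
  tr <- simulate_toggle_ssa(toggle_params(), T = 5000, sample_dt = 1, seed = 2)
  mA <- mean(tr$A[tr$time >= 1000]); mB <- mean(tr$B[tr$time >= 1000])
  expect_lt(abs(max(mA, mB) - 9) / 9, 0.15)
  expect_lt(abs(min(mA, mB) - 1), 0.5)
})

test_that("slow-bursting toggle shows transitions and alpha = 0 decays", {
  tp <- toggle_params(noise = noise_scales(omega = 100, lam = 1))
  tr <- simulate_toggle_ssa(tp, T = 1e5, sample_dt = 1, seed = 4)
  sm <- stats::filter(tr$A, rep(1 / 1000, 1000), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(any(diff(sm > 4) == 1) && any(diff(sm > 4) == -1))
  tp0 <- toggle_params(alpha = 0, noise = noise_scales(omega = 10, lam = 1))
  tr0 <- simulate_toggle_ssa(tp0, T = 200, sample_dt = 1, seed = 1,
                             init = c(5, 5))
  expect_equal(tr0$A[nrow(tr0)], 0)
  expect_equal(tr0$B[nrow(tr0)], 0)
})
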