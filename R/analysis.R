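#' Stationary mean and standard deviation of a trajectory
#'
#' Time-average mean and standard deviation `Sigma` of a channel over the
#' retained grid points `t >= discard`. For an ensemble (a list of
#' trajectories on the same grid) the per-trajectory mean is removed and
#' the sums of squared deviations are pooled across trajectories, which is
#' exactly the variance of the concatenated mean-removed series; the
#' reported `mean` is the global mean.
#'
#' @param traj a `burst_trajectory`, or a list of them on identical grids.
#' @param channel channel name, e.g. `"P"` or `"A"`.
#' @param discard equilibration time to drop, min (default 0).
#' @return A list of class `stationary_stats` with `mean`, `Sigma`,
#'   `n_effective` (retained sample count) and `discard`.
#' @examples
#' traj <- simulate_cle(feedback_params(), noise_scales(100, 10),
#'                      T = 2000, seed = 1, sample_dt = 1)
#' stationary_std(traj, "P", discard = 200)
#' @export
stationary_std <- function(traj, channel, discard = 0) {
  trajs <- if (inherits(traj, "burst_trajectory")) list(traj) else traj
  stopifnot(length(trajs) >= 1L)
  n_tot <- 0; ss <- 0; s <- 0
  for (tr in trajs) {
    stopifnot(inherits(tr, "burst_trajectory"), channel %in% names(tr))
    x <- tr[[channel]][tr$time >= discard]
    if (length(x) < 2L)
      stop("no retained samples after discarding ", discard, " min", call. = FALSE)
    m <- mean(x)
    ss <- ss + sum((x - m)^2)
    s <- s + sum(x)
    n_tot <- n_tot + length(x)
  }
  structure(list(mean = s / n_tot, Sigma = sqrt(ss / n_tot),
                 n_effective = n_tot, discard = discard),
            class = "stationary_stats")
}

#' @export
print.stationary_stats <- function(x, ...) {
  cat(sprintf("mean = %.6g cu, Sigma = %.6g cu (n = %d, discard %g min)\n",
              x$mean, x$Sigma, x$n_effective, x$discard))
  invisible(x)
}

#' Relative error between two standard deviations
#'
#' `r_Sigma = |sigma - sigma_ref| / sigma_ref`, the diagnostic used to
#' quantify how far an approximate tier's stationary fluctuation amplitude
#' is from the full model's.
#'
#' @param sigma standard deviation of the model under test, cu.
#' @param sigma_ref reference (full-model) standard deviation, cu, > 0.
#' @return Dimensionless relative error >= 0.
#' @examples
#' relative_error(1.37, 1.0)  # 0.37
#' @export
relative_error <- function(sigma, sigma_ref) {
  stopifnot(is.numeric(sigma), is.numeric(sigma_ref))
  if (any(sigma_ref <= 0)) stop("`sigma_ref` must be positive", call. = FALSE)
  abs(sigma - sigma_ref) / sigma_ref
}

#' Ensemble periodogram
#'
#' Discrete two-sided power spectral density estimated from one or more
#' trajectories on a common uniform grid. Each trajectory's retained window
#' (`t >= discard`) has its own mean subtracted; the rectangular-window
#' periodogram `S(w_k) = dt |X_k|^2 / n` is averaged over the ensemble.
#' The normalisation is fixed so that `(1/2pi) * sum(S) * dw` equals the
#' pooled sample variance exactly (discrete Parseval).
#'
#' @param trajs a `burst_trajectory` or list of them (identical grids).
#' @param channel channel name.
#' @param discard equilibration time to drop, min.
#' @return A `spectrum_result` list with signed angular-frequency grid
#'   `omega` (1/min, ascending), the requested channel's `S`, `d_omega`,
#'   and `convention = "two-sided"`.
#' @examples
#' trs <- lapply(1:4, function(s)
#'   simulate_lna(feedback_params(), noise_scales(100, 10),
#'                T = 1000, seed = s, sample_dt = 1))
#' sp <- ensemble_periodogram(trs, "p", discard = 200)
#' @export
ensemble_periodogram <- function(trajs, channel, discard = 0) {
  if (inherits(trajs, "burst_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  dt <- trajectory_dt(trajs[[1]])
  keep <- trajs[[1]]$time >= discard
  n <- sum(keep)
  if (n < 2L) stop("no retained samples after discard", call. = FALSE)
  S <- numeric(n)
  for (tr in trajs) {
    stopifnot(inherits(tr, "burst_trajectory"), channel %in% names(tr))
    if (nrow(tr) != length(keep) || abs(trajectory_dt(tr) - dt) > 1e-9)
      stop("trajectories must share one common grid", call. = FALSE)
    x <- tr[[channel]][keep]
    x <- x - mean(x)
    S <- S + dt * Mod(stats::fft(x))^2 / n
  }
  S <- S / length(trajs)
  k <- 0:(n - 1)
  omega <- 2 * pi * ifelse(k <= n %/% 2, k, k - n) / (n * dt)
  ord <- order(omega)
  structure(list(omega = omega[ord], S = S[ord],
                 d_omega = 2 * pi / (n * dt), n = n,
                 convention = "two-sided"),
            class = "spectrum_result")
}

#' Integrated variance of a discrete spectrum
#'
#' `(1/2pi) * sum(S) * d_omega`; by the periodogram's normalisation this
#' equals the pooled sample variance of the analysed windows.
#'
#' @param spec a `spectrum_result` from [ensemble_periodogram()].
#' @return variance in cu^2.
#' @export
spectrum_variance <- function(spec) {
  stopifnot(!is.null(spec$S), !is.null(spec$d_omega))
  sum(spec$S) * spec$d_omega / (2 * pi)
}

#' Dwell times of the toggle switch in one bistable configuration
#'
#' Applies a centered moving average of length `window` to both channels,
#' then measures the durations of contiguous runs where the smoothed
#' `high_channel` exceeds `threshold` while the smoothed `low_channel` is
#' below it. The half-window edges (where the centered average is
#' undefined) are discarded rather than padded, and runs touching either
#' end of the valid region are dropped as boundary-censored.
#'
#' @param traj a `burst_trajectory` with the two channels.
#' @param window smoothing window, min (default 1000); must be a multiple
#'   of the grid step.
#' @param threshold state-discrimination threshold, cu (default 4).
#' @param high_channel,low_channel channel names (defaults `"A"`, `"B"`).
#' @return A list of class `waiting_time_sample` with `durations` (min),
#'   `window`, `threshold` and `n`.
#' @examples
#' tp <- toggle_params(noise = noise_scales(omega = 100, lam = 1))
#' tr <- simulate_toggle_ssa(tp, T = 5e4, sample_dt = 1, seed = 1)
#' waiting_times(tr)
#' @export
waiting_times <- function(traj, window = 1000, threshold = 4,
                          high_channel = "A", low_channel = "B") {
  stopifnot(inherits(traj, "burst_trajectory"),
            high_channel %in% names(traj), low_channel %in% names(traj))
  dt <- trajectory_dt(traj)
  k <- round(window / dt)
  if (abs(k * dt - window) > 1e-9 * window || k < 1)
    stop("`window` must be a positive multiple of the grid step", call. = FALSE)
  if (k > nrow(traj)) stop("`window` is longer than the series", call. = FALSE)
  smooth <- function(x) stats::filter(x, rep(1 / k, k), sides = 2)
  hs <- smooth(traj[[high_channel]])
  ls <- smooth(traj[[low_channel]])
  ok <- !is.na(hs) & !is.na(ls)
  cond <- (hs > threshold) & (ls < threshold)
  cond <- cond[ok]
  r <- rle(as.logical(cond))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  inside <- r$values & starts > 1L & ends < length(cond)
  durations <- r$lengths[inside] * dt
  structure(list(durations = durations, window = window,
                 threshold = threshold, n = length(durations)),
            class = "waiting_time_sample")
}

#' @export
print.waiting_time_sample <- function(x, ...) {
  cat(sprintf("%d dwell intervals (window %g min, threshold %g cu)",
              x$n, x$window, x$threshold))
  if (x$n > 0)
    cat(sprintf("; mean %.4g min, sd %.4g min", mean(x$durations),
                stats::sd(x$durations)))
  cat("\n")
  invisible(x)
}
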