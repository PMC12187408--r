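#' Parameters of the delayed auto-negative feedback motif
#'
#' Container for the rate constants, Hill regulation parameters and
#' transcriptional delay of a single auto-repressed gene. The defaults are
#' the experimentally informed reference set for a mouse neural progenitor
#' ultradian oscillator (concentrations in "cu", one molecule per reference
#' nuclear volume; time in minutes).
#'
#' @param alpha_M basal transcription rate while the promoter is ON,
#'   cu/min.
#' @param alpha_P translation rate, 1/min.
#' @param mu_M mRNA degradation rate, 1/min.
#' @param mu_P protein degradation rate, 1/min.
#' @param h Hill coefficient of the repression function (number of protein
#'   molecules that must bind to silence the promoter).
#' @param P0 repression threshold, cu: protein concentration at which the
#'   promoter is OFF half the time.
#' @param tau transcriptional delay, min, between initiation and the mRNA
#'   entering the system.
#'
#' @return An object of class `feedback_params`.
#' @examples
#' fp <- feedback_params()
#' solve_fixed_point(fp)
#' @export
feedback_params <- function(alpha_M = 39.93, alpha_P = 21.56,
                            mu_M = log(2) / 30, mu_P = log(2) / 90,
                            h = 4.78, P0 = 24201.01, tau = 33) {
  for (nm in c("alpha_P", "mu_M", "mu_P", "h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single finite positive number", call. = FALSE)
  }
  # alpha_M = 0 (silent gene) and tau = 0 (no delay) are valid degenerate
  # limits; P0 = Inf disables the feedback
  if (!is.numeric(alpha_M) || length(alpha_M) != 1L || !is.finite(alpha_M) ||
      alpha_M < 0)
    stop("`alpha_M` must be a single finite nonnegative number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("`tau` must be a single finite nonnegative number", call. = FALSE)
  if (!is.numeric(P0) || length(P0) != 1L || is.na(P0) || P0 <= 0)
    stop("`P0` must be positive (Inf allowed)", call. = FALSE)
  structure(list(alpha_M = alpha_M, alpha_P = alpha_P, mu_M = mu_M,
                 mu_P = mu_P, h = h, P0 = P0, tau = tau),
            class = "feedback_params")
}

#' Noise scales: system size and bursting parameter
#'
#' The system size `omega` multiplies all copy numbers at fixed
#' concentration, so copy-number noise scales as `1/sqrt(omega)`. The
#' bursting parameter `lam` sets the timescale of both promoter switching
#' directions, so bursting noise scales as `1/sqrt(lam)`. Either may be
#' `Inf`, which switches the corresponding noise source off exactly and
#' selects the matching reduced model tier.
#'
#' @param omega system size (dimensionless); `Inf` disables copy-number
#'   noise.
#' @param lam bursting parameter, 1/min; `Inf` disables bursting noise
#'   (the promoter is averaged into a Hill function).
#' @param V0 reference nuclear volume, fL (bookkeeping only; concentrations
#'   are defined relative to it).
#' @return An object of class `noise_scales`.
#' @examples
#' noise_scales(omega = 100, lam = 10)
#' noise_scales(omega = Inf, lam = 0.1)  # bursting noise only
#' @export
noise_scales <- function(omega = 1, lam = 0.1, V0 = 523) {
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega <= 0)
    stop("`omega` must be positive (Inf allowed)", call. = FALSE)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0)
    stop("`lam` must be positive (Inf allowed)", call. = FALSE)
  if (!is.numeric(V0) || length(V0) != 1L || !is.finite(V0) || V0 <= 0)
    stop("`V0` must be a finite positive number", call. = FALSE)
  structure(list(omega = omega, lam = lam, V0 = V0), class = "noise_scales")
}

#' Parameters of the bursting toggle switch
#'
#' Two mutually repressing genes A and B, each with its own telegraph
#' promoter silenced by the other gene's protein. Both genes share the same
#' production rate, degradation rate, Hill coefficient and repression
#' threshold. The defaults are the bistable reference set (high state near
#' 9 cu, low state near 1 cu).
#'
#' @param alpha production rate in the promoter ON state, cu/min.
#' @param mu protein degradation rate, 1/min.
#' @param h Hill coefficient.
#' @param P0 repression threshold, cu.
#' @param noise a [noise_scales()] object (no delay in this motif).
#' @return An object of class `toggle_params`.
#' @examples
#' tp <- toggle_params()
#' toggle_fixed_points(tp)
#' @export
toggle_params <- function(alpha = 1, mu = 0.1, h = 2, P0 = 3,
                          noise = noise_scales(omega = 100, lam = 100)) {
  for (nm in c("mu", "h", "P0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single finite positive number", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("`alpha` must be a single finite nonnegative number", call. = FALSE)
  stopifnot(inherits(noise, "noise_scales"))
  structure(list(alpha = alpha, mu = mu, h = h, P0 = P0, noise = noise),
            class = "toggle_params")
}

#' @export
print.feedback_params <- function(x, ...) {
  cat("Auto-negative feedback parameters:\n")
  cat(sprintf("  alpha_M = %g cu/min, alpha_P = %g /min\n", x$alpha_M, x$alpha_P))
  cat(sprintf("  mu_M = %g /min (t1/2 = %.3g min), mu_P = %g /min (t1/2 = %.3g min)\n",
              x$mu_M, log(2) / x$mu_M, x$mu_P, log(2) / x$mu_P))
  cat(sprintf("  h = %g, P0 = %g cu, tau = %g min\n", x$h, x$P0, x$tau))
  invisible(x)
}

#' @export
print.noise_scales <- function(x, ...) {
  cat(sprintf("Noise scales: Omega = %g, lambda = %g /min (V0 = %g fL)\n",
              x$omega, x$lam, x$V0))
  invisible(x)
}

#' @export
print.toggle_params <- function(x, ...) {
  cat(sprintf("Toggle switch: alpha = %g cu/min, mu = %g /min, h = %g, P0 = %g cu\n",
              x$alpha, x$mu, x$h, x$P0))
  print(x$noise)
  invisible(x)
}
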