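#' Deterministic fixed point of the feedback motif
#'
#' Solves the stationarity conditions of the deterministic rate equations:
#' `P* (1 + (P*/P0)^h) = K` with `K = alpha_M * alpha_P / (mu_M * mu_P)`,
#' and `M* = mu_P * P* / alpha_P`. The left side is strictly increasing in
#' `P`, so the root on `[0, K]` is unique; it is bracketed by bisection and
#' polished by Newton iteration to a relative residual below 1e-12.
#'
#' @param params a [feedback_params()] object.
#' @return A list of class `fixed_point` with elements `M_star`, `P_star`
#'   (cu) and `residual` (relative stationarity residual).
#' @examples
#' solve_fixed_point(feedback_params())
#' @export
solve_fixed_point <- function(params) {
  stopifnot(inherits(params, "feedback_params"))
  K <- params$alpha_M * params$alpha_P / (params$mu_M * params$mu_P)
  h <- params$h; P0 <- params$P0
  if (K == 0)
    return(structure(list(M_star = 0, P_star = 0, residual = 0),
                     class = "fixed_point"))
  # g is increasing with g(0) = -K < 0 <= g(K), so bisection cannot fail
  g <- function(P) P * (1 + (P / P0)^h) - K
  lo <- 0; hi <- K
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) <= 1e-15 * K) break
  }
  P_star <- 0.5 * (lo + hi)
  # Newton polish: g'(P) = 1 + (h+1)*(P/P0)^h
  for (i in 1:5) {
    step <- g(P_star) / (1 + (h + 1) * (P_star / P0)^h)
    P_star <- P_star - step
    if (abs(step) <= 1e-15 * P_star) break
  }
  M_star <- params$mu_P * P_star / params$alpha_P
  structure(list(M_star = M_star, P_star = P_star,
                 residual = abs(g(P_star)) / P_star),
            class = "fixed_point")
}

#' @export
print.fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point: M* = %.6g cu, P* = %.6g cu (residual %.2g)\n",
              x$M_star, x$P_star, x$residual))
  invisible(x)
}

#' Deterministic fixed points of the toggle switch
#'
#' Finds all nonnegative solutions of the coupled stationarity equations
#' `A = (alpha/mu) f(B)`, `B = (alpha/mu) f(A)` by scanning the scalar
#' composition map `A -> (alpha/mu) f((alpha/mu) f(A))` for sign changes on
#' a fine grid over `[0, alpha/mu]` and refining each bracket with
#' [stats::uniroot()]. In the bistable regime this returns three points:
#' two asymmetric (high/low and low/high) and one unstable symmetric one.
#'
#' Only the ratio `alpha/mu` enters, so scaling both rates together leaves
#' the fixed-point set unchanged.
#'
#' @param params a [toggle_params()] object.
#' @param n_scan number of scan grid points (default 2000).
#' @return A data frame with one row per fixed point, columns `A` and `B`
#'   (cu), ordered by increasing `A`.
#' @examples
#' toggle_fixed_points(toggle_params())  # (1, 9), symmetric, (9, 1)
#' @export
toggle_fixed_points <- function(params, n_scan = 2000L) {
  stopifnot(inherits(params, "toggle_params"))
  r <- params$alpha / params$mu
  f <- function(x) hill_repression(x, params$P0, params$h)
  comp <- function(A) r * f(r * f(A)) - A
  grid <- seq(0, r, length.out = n_scan + 1L)
  v <- vapply(grid, comp, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(n_scan)) {
    if (v[i] == 0) { roots <- c(roots, grid[i]); next }
    if (sign(v[i]) != sign(v[i + 1L])) {
      rt <- stats::uniroot(comp, c(grid[i], grid[i + 1L]), tol = 1e-14 * max(r, 1))
      roots <- c(roots, rt$root)
    }
  }
  if (v[n_scan + 1L] == 0) roots <- c(roots, r)
  # Newton-free polish via the B equation, then deduplicate
  A <- sort(unique(roots))
  keep <- c(TRUE, diff(A) > 1e-9 * max(r, 1))
  A <- A[keep]
  B <- r * f(A)
  out <- data.frame(A = A, B = B)
  class(out) <- c("toggle_fixed_points", "data.frame")
  out
}

#' Relative stationarity residual of toggle fixed points
#'
#' @param fp data frame from [toggle_fixed_points()].
#' @param params the [toggle_params()] used.
#' @return numeric vector of residuals, one per fixed point.
#' @keywords internal
#' @export
toggle_residual <- function(fp, params) {
  r <- params$alpha / params$mu
  f <- function(x) hill_repression(x, params$P0, params$h)
  pmax(abs(fp$A - r * f(fp$B)), abs(fp$B - r * f(fp$A))) / pmax(fp$A, fp$B, 1)
}
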