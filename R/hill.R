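#' Hill repression function
#'
#' Probability of finding a telegraph promoter in its unbound ON state when
#' switching is fast compared with the rest of the system:
#' `f(P) = 1 / (1 + (P/P0)^h)`. This is the mean transcriptional activity of
#' the promoter at protein concentration `P`, and the regulation function of
#' the deterministic rate equations.
#'
#' `P0 = Inf` is accepted and yields `f == 1` (no repression), the
#' constitutive limit.
#'
#' @param P protein concentration, cu (vectorised); must be nonnegative.
#' @param P0 repression threshold, cu.
#' @param h Hill coefficient, > 0.
#' @return Value(s) in (0, 1].
#' @examples
#' hill_repression(24201.01, 24201.01, 4.78)  # 0.5 at the threshold
#' @export
hill_repression <- function(P, P0, h) {
  stopifnot(is.numeric(P), length(P0) == 1L, P0 > 0, length(h) == 1L, h > 0)
  if (any(P < 0)) stop("`P` must be nonnegative; clamp before calling", call. = FALSE)
  if (!is.finite(P0)) return(rep_len(1, length(P)))
  1 / (1 + (P / P0)^h)
}

#' Derivative of the Hill repression function
#'
#' `f'(P) = -(h/P0) * (P/P0)^(h-1) / (1 + (P/P0)^h)^2`, always nonpositive.
#' Enters the linearised dynamics about the fixed point as the feedback
#' gain.
#'
#' @inheritParams hill_repression
#' @return Value(s) <= 0, units 1/cu. `P0 = Inf` yields 0.
#' @examples
#' hill_derivative(100, 100, 2)  # -h/(4*P0)
#' @export
hill_derivative <- function(P, P0, h) {
  stopifnot(is.numeric(P), length(P0) == 1L, P0 > 0, length(h) == 1L, h > 0)
  if (any(P < 0)) stop("`P` must be nonnegative", call. = FALSE)
  if (!is.finite(P0)) return(rep_len(0, length(P)))
  if (h < 1 && any(P == 0))
    stop("f'(0) diverges for Hill coefficient h < 1", call. = FALSE)
  x <- P / P0
  out <- -(h / P0) * x^(h - 1) / (1 + x^h)^2
  # exact limit at P = 0 for h > 1 (0^(h-1) is already 0; h = 1 gives -1/P0)
  out
}
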