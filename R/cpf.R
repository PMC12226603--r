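#' Control-point function
#'
#' Piecewise-linear scalar function used to parameterize the learnable penalty
#' transforms of the variational network: ordinates `y` at fixed, equispaced
#' knots in a normalized response interval. Evaluation clamps to the boundary
#' ordinate outside the knot range. The identity is represented exactly by
#' `y = knots`.
#'
#' @param y control-point ordinates (length >= 2).
#' @param lo,hi knot range (normalized response interval).
#' @return An object of class `sos_cpf` with fields `knots` and `y`.
#' @export
cpf <- function(y, lo = -1, hi = 1) {
  if (length(y) < 2) stop("a control-point function needs at least 2 knots")
  stopifnot(hi > lo)
  structure(list(knots = seq(lo, hi, length.out = length(y)), y = as.numeric(y)),
            class = "sos_cpf")
}

#' Identity control-point function
#' @param n_knots number of knots.
#' @param lo,hi knot range.
#' @export
cpf_identity <- function(n_knots = 31, lo = -1, hi = 1) {
  k <- seq(lo, hi, length.out = n_knots)
  cpf(k, lo, hi)
}

#' Evaluate a control-point function
#'
#' Piecewise-linear interpolation at each element of `v`; values beyond the
#' knot range are clamped to the boundary ordinate.
#'
#' @param f an [cpf()].
#' @param v numeric vector/matrix of response values.
#' @return Transformed values with the shape of `v`.
#' @export
eval_cpf <- function(f, v) {
  if (!inherits(f, "sos_cpf")) stop("f must be an sos_cpf")
  out <- pwl_eval(f$knots, f$y, v)
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

# -- internal piecewise-linear machinery --------------------------------------
# Knots are always equispaced (enforced by the constructors), which the
# compiled kernels exploit via direct index arithmetic.

pwl_eval <- function(knots, y, v) {
  out <- pwl_eval_eq(y, knots[1], knots[2] - knots[1], as.numeric(v))
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

# derivative with respect to the input (zero in the clamped regions)
pwl_slope <- function(knots, y, v) {
  out <- pwl_slope_eq(y, knots[1], knots[2] - knots[1], as.numeric(v))
  if (is.matrix(v)) dim(out) <- dim(v)
  out
}

# gradient with respect to the ordinates, accumulated over elements:
# returns dy (length nk) for cotangent g on the outputs
pwl_ygrad <- function(knots, v, g) {
  pwl_ygrad_eq(length(knots), knots[1], knots[2] - knots[1],
               as.numeric(v), as.numeric(g))
}
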