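#' Cubic B-spline design with equidistant knots
#'
#' Builds the P-spline basis for a smooth covariate effect: `K` cubic
#' B-spline basis functions on equidistant knots spanning the observed
#' range, extended by `degree` knots on each side so the basis is a
#' partition of unity (every row sums to 1) over the whole range.  The
#' companion second-difference penalty `t(D2) %*% D2` (rank `K - 2`)
#' corresponds to a second-order random-walk prior on the coefficients.
#'
#' @param x covariate values (non-degenerate: `min(x) < max(x)`).
#' @param K number of basis functions, at least 4 (default 20).
#' @param degree spline degree (default 3, cubic).
#' @param range optional length-2 numeric giving the knot span; defaults to
#'   `range(x)`.
#' @return list of class `"spline_block"`: `basis` (n x K matrix),
#'   `penalty` (K x K), `rank` (`K - 2`), `knots`, `degree`, `range`, `x`.
#' @export
bspline_design <- function(x, K = 20, degree = 3, range = NULL) {
  if (K < 4) stop("K must be at least 4")
  if (is.null(range)) range <- base::range(x)
  lo <- range[1]; hi <- range[2]
  if (!(lo < hi)) stop("x is degenerate: min(x) must be < max(x)")
  if (any(x < lo | x > hi)) stop("x outside the knot range")
  n_inner <- K - degree            # interior knot intervals
  h <- (hi - lo) / n_inner
  # exact endpoints: rounding in a cumulative seq() could strand max(x)
  # just outside the admissible knot span
  knots <- c(lo - (degree:1) * h, seq(lo, hi, length.out = n_inner + 1),
             hi + (1:degree) * h)
  B <- splines::splineDesign(knots, x, ord = degree + 1, outer.ok = FALSE)
  D2 <- diff(diag(K), differences = 2)
  list(basis = B, penalty = crossprod(D2), rank = K - 2L,
       knots = knots, degree = degree, range = c(lo, hi), x = x)
}

#' Evaluate a spline block's basis on new values
#'
#' @param block a `"spline_block"` from [bspline_design()].
#' @param newx values inside the block's range (no extrapolation).
#' @return matrix of basis evaluations, one row per value of `newx`.
#' @export
bspline_eval <- function(block, newx) {
  if (any(newx < block$range[1] | newx > block$range[2]))
    stop("extrapolation error: values outside the fitted covariate range")
  splines::splineDesign(block$knots, newx, ord = block$degree + 1,
                        outer.ok = FALSE)
}
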