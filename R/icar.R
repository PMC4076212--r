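#' Intrinsic CAR precision matrix
#'
#' The (unscaled) precision of the intrinsic Gaussian Markov random field
#' on a region graph: `Q = D - A` with `D` the diagonal of neighbour
#' counts and `A` the adjacency matrix.  `Q` is symmetric, has zero row
#' sums, and rank `R - c` where `c` is the number of connected components.
#'
#' @param g a [region_graph].
#' @return R x R symmetric matrix with region ids as dimnames.
#' @export
icar_precision <- function(g) {
  R <- length(g$regions)
  Q <- matrix(0, R, R, dimnames = list(g$regions, g$regions))
  for (i in seq_len(R)) {
    nb <- match(g$neighbors[[i]], g$regions)
    Q[i, nb] <- -1
    Q[i, i] <- length(nb)
  }
  Q
}

#' Draw from the intrinsic CAR distribution
#'
#' Samples region effects with covariance `tau2 * pinv(Q)` on the
#' orthogonal complement of the null space, i.e. from the intrinsic GMRF
#' with precision `Q / tau2` constrained to sum to zero within every
#' connected component.  Implemented by spectral decomposition of `Q`.
#'
#' @param g a [region_graph].
#' @param tau2 variance parameter, positive.
#' @param n number of draws.
#' @return if `n = 1` a named vector of effects, else an `n` x R matrix.
#' @export
draw_icar_effects <- function(g, tau2, n = 1) {
  if (length(g$regions) == 0) stop("empty graph")
  if (!is.numeric(tau2) || tau2 <= 0) stop("tau2 must be positive")
  Q <- icar_precision(g)
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, pos, drop = FALSE]
  lam <- eg$values[pos]
  z <- matrix(rnorm(n * length(lam)), length(lam), n)
  draws <- t(V %*% (z / sqrt(lam)) * sqrt(tau2))
  colnames(draws) <- g$regions
  if (n == 1) drop(draws) else draws
}
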