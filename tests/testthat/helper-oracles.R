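# Independent oracles used across tests.

# Cox-de Boor recursion for a single B-spline basis function B_{i,ord}(x)
# over knot vector `knots` (1-based i, ord = degree + 1).
coxdeboor <- function(x, i, ord, knots) {
  if (ord == 1) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  d1 <- knots[i + ord - 1] - knots[i]
  d2 <- knots[i + ord] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * coxdeboor(x, i, ord - 1, knots) else 0
  t2 <- if (d2 > 0) (knots[i + ord] - x) / d2 *
      coxdeboor(x, i + 1, ord - 1, knots) else 0
  t1 + t2
}

# Moore-Penrose pseudo-inverse via eigendecomposition (symmetric input).
sym_pinv <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

# Exact Mann-Whitney p-value by enumeration of all group assignments.
mwu_exact_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  u_stat <- function(ix) {
    rx <- rank(vals)[ix]
    u1 <- sum(rx) - nx * (nx + 1) / 2
    min(u1, nx * ny - u1)
  }
  obs <- u_stat(seq_len(nx))
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, u_stat)
  mean(us <= obs)
}

# Deterministic grid quadrature for the intercept-only Bernoulli logit
# posterior with a N(0, v0) prior.
intercept_posterior_quadrature <- function(k, n, v0 = 1e6,
                                           lo = -10, hi = 10, m = 40001) {
  gr <- seq(lo, hi, length.out = m)
  lp <- k * gr - n * log1p(exp(gr)) - gr^2 / (2 * v0)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mu <- sum(gr * w)
  list(mean = mu, sd = sqrt(sum((gr - mu)^2 * w)))
}

# Small well-behaved simulated logistic data set for fixed-effect tests.
sim_fixed_effects_data <- function(n, beta, seed) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1,
             urban = rbinom(n, 1, 0.3),
             wealth_hi = rbinom(n, 1, 0.4))
  eta <- drop(X %*% beta)
  list(X = X, y = rbinom(n, 1, plogis(eta)), eta = eta)
}
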