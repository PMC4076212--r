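test_that("intercept-only Gibbs posterior matches grid quadrature", {
  y <- c(rep(1, 7), rep(0, 3))
  d <- gibbs_sampler(y, config = mcmc_config(iterations = 30000,
                                             burnin = 2000, thin = 2,
                                             seed = 42))
  oracle <- intercept_posterior_quadrature(7, 10)
  expect_lt(abs(mean(d$beta[, 1]) - oracle$mean), 0.02)
  expect_lt(abs(sd(d$beta[, 1]) - oracle$sd), 0.02)
})

test_that("fixed-effects Gibbs matches the IRLS MLE within posterior uncertainty", {
  d <- sim_fixed_effects_data(2000, c(-1.3, log(1.24), log(1.8)), seed = 77)
  mle <- fit_logistic_irls(d$X, d$y)
  draws <- gibbs_sampler(d$y, fixed = d$X,
                         config = mcmc_config(iterations = 4000,
                                              burnin = 1000, thin = 2,
                                              seed = 5))
  pm <- colMeans(draws$beta)
  psd <- apply(draws$beta, 2, sd)
  expect_true(all(abs(pm - mle$coefficients) < 3 * psd))
  # odds-ratio scale too
  expect_true(all(abs(exp(pm) - exp(mle$coefficients)) <
                    3 * exp(pm) * psd))
})

test_that("the same seed and config reproduce draws bit-identically", {
  cfg <- sim_config(n = 400, graph = make_lattice_graph(2), seed = 3)
  sim <- simulate_survey(cfg)
  aset <- build_analysis_set(sim$records)
  mc <- mcmc_config(iterations = 200, burnin = 50, thin = 2, seed = 12)
  f1 <- fit_geoadditive(aset, cfg$graph, fixed_covariates = "residence",
                        K = 6, config = mc)
  f2 <- fit_geoadditive(aset, cfg$graph, fixed_covariates = "residence",
                        K = 6, config = mc)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$tau2, f2$tau2)
})

test_that("saved draws satisfy the sum-to-zero identification exactly", {
  cfg <- sim_config(n = 800, graph = make_lattice_graph(3), seed = 19)
  sim <- simulate_survey(cfg)
  aset <- build_analysis_set(sim$records)
  draws <- fit_geoadditive(aset, cfg$graph, fixed_covariates = "residence",
                           K = 8,
                           config = mcmc_config(iterations = 300, burnin = 100,
                                                thin = 2, seed = 2))
  for (nm in names(draws$splines)) {
    fvals <- draws$gamma[[nm]] %*% t(draws$splines[[nm]]$basis)
    expect_lt(max(abs(rowMeans(fvals))), 1e-10)
  }
  expect_lt(max(abs(rowSums(draws$u))), 1e-10)
  expect_lt(max(abs(rowSums(draws$v))), 1e-10)
})

test_that("each Gaussian full conditional centres on the normal-equations solution", {
  # tiny instance: freeze omega and eta, average many conditional draws
  set.seed(31)
  n <- 40
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, 0.5)
  kappa <- y - 0.5
  omega <- rpolyagamma(rnorm(n, 0, 0.5))
  Prec <- crossprod(X * sqrt(omega)) + diag(1e-6, 3)
  rhs <- drop(crossprod(X, kappa))
  mu_oracle <- drop(solve(Prec, rhs))       # independent dense solver
  draws <- replicate(20000, geoadd:::draw_gaussian_block(Prec, rhs))
  expect_equal(rowMeans(draws), mu_oracle, tolerance = 0.02)
  # empirical covariance matches the inverse precision
  expect_equal(cov(t(draws)), solve(Prec), tolerance = 0.05)
})

test_that("with a nearly flat smoothing prior the fit approaches the unpenalised MLE", {
  set.seed(8)
  n <- 400
  x <- runif(n, 15, 49)
  f <- function(a) 0.8 * sin(pi * (a - 15) / 34)
  y <- rbinom(n, 1, plogis(-0.5 + f(x) - mean(f(x))))
  bl <- bspline_design(x, K = 6)
  # hyperprior concentrated on huge tau2 => effectively no penalty
  draws <- gibbs_sampler(y, splines = list(age = bl),
                         config = mcmc_config(iterations = 6000, burnin = 1000,
                                              thin = 2, a = 10, b = 1e6,
                                              seed = 4))
  eta_pm <- rowMeans(cbind(1, bl$basis) %*%
                       t(cbind(draws$beta[, 1],
                               draws$gamma$age)))
  Xmle <- cbind(1, bl$basis[, -1])   # drop one column: partition of unity
  mle <- suppressWarnings(glm(y ~ Xmle - 1, family = binomial()))
  eta_mle <- drop(Xmle %*% coef(mle))
  expect_lt(sqrt(mean((eta_pm - eta_mle)^2)), 0.25)
  expect_gt(cor(eta_pm, eta_mle), 0.98)
})

test_that("a region absent from the graph is refused before sampling", {
  cfg <- sim_config(n = 200, graph = make_lattice_graph(2), seed = 3)
  sim <- simulate_survey(cfg)
  aset <- build_analysis_set(sim$records)
  g_wrong <- make_lattice_graph(3)
  expect_error(
    gibbs_sampler(aset$data$y,
                  spatial = list(region = paste0("zz", seq_len(nrow(aset$data))),
                                 graph = g_wrong),
                  config = mcmc_config(iterations = 20, burnin = 5, seed = 1)),
    "missing from graph")
})
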