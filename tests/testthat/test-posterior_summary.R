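fake_draws <- function(beta, labels = NULL, u = NULL, v = NULL,
                       splines = NULL, gamma = NULL) {
  structure(list(beta = beta, labels = labels, u = u, v = v,
                 splines = splines, gamma = gamma,
                 tau2 = matrix(numeric(0), nrow(beta), 0)),
            class = "posterior_draws")
}

test_that("summarize_fixed collapses constant and symmetric draws correctly", {
  B <- cbind(`(Intercept)` = rep(0, 500), `residence:urban` = rep(log(2), 500))
  labels <- data.frame(column = colnames(B),
                       variable = c("(Intercept)", "residence"),
                       level = c("", "urban"))
  tab <- summarize_fixed(fake_draws(B, labels))
  urb <- tab[tab$level == "urban", ]
  expect_equal(c(urb$por, urb$lower, urb$upper), rep(2, 3))
  expect_equal(tab$por[tab$level == "(reference)"], 1)

  set.seed(1)
  B2 <- cbind(`(Intercept)` = rnorm(4000), `residence:urban` = rnorm(4000, 0, 0.3))
  tab2 <- summarize_fixed(fake_draws(B2, labels))
  urb2 <- tab2[tab2$level == "urban", ]
  expect_equal(urb2$por, 1, tolerance = 0.05)
  expect_lt(urb2$lower, 1)
  expect_gt(urb2$upper, 1)
  expect_match(format_or(urb2$por, urb2$lower, urb2$upper),
               "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}, \\d+\\.\\d{2}\\)$")
  expect_warning(summarize_fixed(fake_draws(B[1:50, , drop = FALSE], labels)),
                 "100")
})

test_that("point summary flag switches between exp(mean) and mean(exp)", {
  set.seed(2)
  B <- cbind(`(Intercept)` = rnorm(2000), `w:x` = rnorm(2000, 1, 0.6))
  labels <- data.frame(column = colnames(B), variable = c("(Intercept)", "w"),
                       level = c("", "x"))
  t1 <- summarize_fixed(fake_draws(B, labels), point = "exp_mean")
  t2 <- summarize_fixed(fake_draws(B, labels), point = "mean_exp")
  expect_equal(t1$por[2], exp(mean(B[, 2])))
  expect_equal(t2$por[2], mean(exp(B[, 2])))
  expect_gt(t2$por[2], t1$por[2])   # Jensen
})

test_that("constant-coefficient spline draws give a flat centred curve", {
  x <- runif(300, 15, 49)
  bl <- bspline_design(x, K = 8)
  G <- matrix(2.5, 200, 8)          # constant coefficients => constant f
  d <- fake_draws(cbind(`(Intercept)` = rep(0, 200)),
                  splines = list(age = bl), gamma = list(age = G))
  cv <- nonlinear_curve(d, "age")
  expect_true(all(abs(cv$mean) < 1e-10))
  expect_true(all(abs(cv$upper - cv$lower) < 1e-10))
})

test_that("the credible band of a null smooth covers zero at most grid points", {
  # Pointwise 80% bands around a truly flat effect are calibrated across
  # replicate data sets.  A single replicate is nearly all-or-nothing: the
  # RW2 prior leaves the linear component unpenalised, so a chance trend
  # in one data set moves the whole band off zero at once (the posterior
  # tracks the MLE of that trend, which is correct behaviour).  The check
  # therefore pools coverage over replicates and allows Monte-Carlo slack
  # below the nominal level.
  cover <- vapply(1:30, function(r) {
    set.seed(100 + r)
    n <- 500
    x <- runif(n, 15, 49)
    y <- rbinom(n, 1, 0.3)          # no age effect in truth
    bl <- bspline_design(x, K = 10)
    draws <- gibbs_sampler(y, splines = list(age = bl),
                           config = mcmc_config(iterations = 800,
                                                burnin = 300, thin = 2,
                                                seed = 200 + r))
    cv <- nonlinear_curve(draws, "age", level = 0.80)
    mean(cv$lower <= 0 & cv$upper >= 0)
  }, numeric(1))
  expect_gte(mean(cover), 0.70)     # nominal 0.80 minus 2 SE over replicates
  expect_gte(mean(cover >= 0.9), 0.5)
})

test_that("map categorisation applies the credible-sign rule", {
  set.seed(5)
  nd <- 1000
  u <- cbind(pos = rnorm(nd, 1, 0.2), none = rnorm(nd, 0, 0.5),
             neg = rnorm(nd, -1, 0.2))
  v <- matrix(0, nd, 3, dimnames = list(NULL, colnames(u)))
  d <- fake_draws(cbind(`(Intercept)` = rep(0, nd)), u = u, v = v)
  m <- categorize_map(d, level = 0.80)
  expect_equal(m$category, c("positive", "none", "negative"))
  expect_equal(m$por, exp(colMeans(u)), ignore_attr = TRUE)
  expect_true(all(m$lower <= m$por & m$por <= m$upper))
  expect_warning(categorize_map(d, observed_regions = c("pos", "none")),
                 "neg")
})

test_that("widening the nominal level never creates significance", {
  set.seed(13)
  nd <- 2000
  u <- matrix(rnorm(nd * 6, rep(seq(-0.8, 0.8, length.out = 6), each = nd),
                    0.5), nd, 6, dimnames = list(NULL, paste0("r", 1:6)))
  v <- matrix(0, nd, 6, dimnames = dimnames(u))
  d <- fake_draws(cbind(`(Intercept)` = rep(0, nd)), u = u, v = v)
  m80 <- categorize_map(d, level = 0.80)
  m95 <- categorize_map(d, level = 0.95)
  sig95 <- m95$category != "none"
  expect_true(all(m80$category[sig95] == m95$category[sig95]))
})

test_that("null-effect regions are categorised 'none' at roughly the nominal rate", {
  set.seed(23)
  hits <- replicate(300, {
    x <- rnorm(400, 0, 1)           # posterior draws around a true zero
    q <- quantile(x, c(0.1, 0.9))
    q[1] <= 0 && q[2] >= 0
  })
  expect_gt(mean(hits), 0.7)        # nominal 80%, Monte-Carlo slack
})

test_that("GeoJSON export annotates every polygon and round-trips", {
  m <- data.frame(region = c("r1_1", "r1_2", "r2_1", "r2_2"),
                  por = c(2.32, 1.0, 0.48, 1.1),
                  lower = c(1.62, 0.8, 0.36, 0.9),
                  upper = c(3.40, 1.3, 0.61, 1.4),
                  prob_positive = c(1, 0.5, 0, 0.6),
                  category = c("positive", "none", "negative", "none"))
  poly <- lattice_polygons(2)
  out <- tempfile(fileext = ".geojson")
  export_map(m, poly, out = out)
  back <- jsonlite::read_json(out)
  expect_length(back$features, 4)
  props <- back$features[[1]]$properties
  i <- match(props$region, m$region)
  expect_equal(props$por, m$por[i])
  expect_equal(props$cr_low, m$lower[i])
  expect_equal(props$category, m$category[i])
  expect_true(all(vapply(back$features,
                         function(f) !is.null(f$properties$color_category),
                         logical(1))))

  # missing polygon for one region is an error naming it
  m2 <- rbind(m, data.frame(region = "r9_9", por = 1, lower = 1, upper = 1,
                            prob_positive = 0.5, category = "none"))
  expect_error(export_map(m2, poly), "r9_9")
})
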