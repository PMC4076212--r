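test_that("lattice graphs have the right rook structure", {
  g2 <- make_lattice_graph(2)
  expect_equal(length(g2$regions), 4)
  expect_equal(sum(lengths(g2$neighbors)) / 2, 4)
  g3 <- make_lattice_graph(3)
  expect_equal(length(g3$regions), 9)
  expect_equal(sum(lengths(g3$neighbors)) / 2, 12)
  g5 <- make_lattice_graph(5)
  interior <- sprintf("r%d_%d", rep(2:4, each = 3), rep(2:4, 3))
  expect_true(all(lengths(g5$neighbors[interior]) == 4))
  expect_equal(max(g5$component), 1)
  expect_error(make_lattice_graph(1), "m must be")
})

test_that("ICAR draws satisfy the sum-to-zero constraint and vanish as tau2 -> 0", {
  g <- make_lattice_graph(3)
  set.seed(4)
  x <- draw_icar_effects(g, tau2 = 1)
  expect_lt(abs(sum(x)), 1e-10)
  x0 <- draw_icar_effects(g, tau2 = 1e-12)
  expect_true(all(abs(x0) < 1e-5))

  # per-component sums on a disconnected graph
  g2 <- region_graph(c("A", "B", "C", "D"),
                     list(A = "B", B = "A", C = "D", D = "C"))
  xx <- draw_icar_effects(g2, tau2 = 1, n = 20)
  for (k in 1:2)
    expect_true(all(abs(rowSums(xx[, g2$component == k, drop = FALSE])) < 1e-10))
  expect_error(draw_icar_effects(g, tau2 = -1), "tau2")
})

test_that("ICAR draw covariance matches tau2 * pinv(Q) on a 3-node path", {
  g <- region_graph(c("A", "B", "C"), list(A = "B", B = c("A", "C"), C = "B"))
  Q <- icar_precision(g)
  set.seed(11)
  draws <- draw_icar_effects(g, tau2 = 1, n = 50000)
  emp <- cov(draws)
  expect_true(max(abs(emp - sym_pinv(Q))) < 0.05)
})

test_that("simulated prevalence tracks the configured intercept", {
  cfg <- sim_config(n = 50000, graph = make_lattice_graph(4),
                    beta = list(), intercept = qlogis(0.209),
                    f_age = NULL, f_page = NULL,
                    tau2_spat = 1e-12, tau2_unstr = 0,
                    p_underweight = 0, seed = 21)
  sim <- simulate_survey(cfg)
  aset <- build_analysis_set(sim$records)
  p_hat <- mean(aset$data$y)
  se <- sqrt(0.209 * 0.791 / 50000)
  expect_lt(abs(p_hat - 0.209), 3 * se)
  expect_equal(aset$ledger$underweight_excluded, 0)
})

test_that("the underweight stratum hits its configured rate", {
  cfg <- sim_config(n = 20000, graph = make_lattice_graph(3),
                    p_underweight = 0.12, seed = 22)
  sim <- simulate_survey(cfg)
  frac <- mean(sim$records$bmi < 18.5)
  se <- sqrt(0.12 * 0.88 / 20000)
  expect_lt(abs(frac - 0.12), 3 * se)
})

test_that("the same seed reproduces the simulation bit-identically", {
  cfg <- sim_config(n = 2000, graph = make_lattice_graph(3), seed = 5)
  expect_identical(simulate_survey(cfg)$records, simulate_survey(cfg)$records)
})

test_that("category frequencies converge to the configured marginals", {
  cfg <- sim_config(n = 100000, graph = make_lattice_graph(3), seed = 31)
  sim <- simulate_survey(cfg)
  for (v in names(cfg$category_probs)) {
    p <- cfg$category_probs[[v]]
    emp <- as.vector(table(sim$records[[v]])) / cfg$n
    se <- sqrt(p * (1 - p) / cfg$n)
    expect_true(all(abs(emp - p) <= 3 * se + 1e-12),
                info = paste("marginals for", v))
  }
})

test_that("generated BMI categories agree exactly with the latent assignment", {
  cfg <- sim_config(n = 20000, graph = make_lattice_graph(3),
                    p_underweight = 0.1, seed = 41)
  sim <- simulate_survey(cfg)
  cat <- categorize_bmi(sim$records$bmi)
  y <- sim$truth$y
  expect_true(all(cat[is.na(y)] == "underweight"))
  expect_true(all(cat[!is.na(y) & y == 1] %in% c("overweight", "obese")))
  expect_true(all(cat[!is.na(y) & y == 0] == "normal"))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(category_probs = list(residence = c(rural = 0.5, urban = 0.4))),
               "sum to 1")
  expect_error(sim_config(tau2_spat = -1))
  g <- make_lattice_graph(2)
  expect_error(sim_config(graph = g,
                          beta = list(residence = c(suburban = 1))),
               "not all present")
})
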