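#' Simulation configuration for a DHS-like survey
#'
#' Defines the generative model for synthetic individual records: marginal
#' covariate distributions, per-level log-odds effects, smooth age
#' effects, and structured (intrinsic CAR) plus unstructured region
#' effects on a region graph.  Defaults emulate the 2008 Nigerian survey
#' conditions: covariate marginals follow the published whole-sample
#' percentages, effect sizes follow the published adjusted odds ratios,
#' the respondent-age effect peaks near 45 years and the partner-age
#' effect near 70 years, 12% of women are underweight, and the intercept
#' is calibrated so overall overweight/obesity prevalence is close to
#' 20.9%.
#'
#' @param n number of individuals.
#' @param graph a [region_graph]; default [nigeria_graph()].
#' @param beta named list of named numeric vectors: per-level log-odds
#'   effects for each categorical covariate (reference level implicitly
#'   0).  `NULL` entries mean no effect.
#' @param intercept log-odds intercept; default calibrated as described
#'   above (`NA` requests calibration to `target_prevalence`).
#' @param target_prevalence overall case probability used to calibrate the
#'   intercept when `intercept` is `NA` (default 0.209).
#' @param f_age,f_page smooth log-odds effects of respondent age (15--49)
#'   and partner age (15--95); each is centred over the drawn ages before
#'   entering the linear predictor.  Defaults:
#'   `0.9 * sin(pi * (a - 15) / 60)` (maximum at 45) and
#'   `0.8 * sin(pi * (a - 15) / 110)` (maximum at 70).  Set to `NULL` for
#'   no effect.
#' @param tau2_spat,tau2_unstr variances of the structured and
#'   unstructured region effects (0 disables a component).
#' @param p_underweight probability a woman is underweight (BMI drawn
#'   uniformly in [15, 18.5), excluded downstream); default 0.12.
#' @param category_probs named list of named probability vectors for the
#'   categorical covariates; defaults follow the published whole-sample
#'   marginals.
#' @param region_probs optional region sampling weights (default uniform).
#' @param seed RNG seed.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n = 25000, graph = nigeria_graph(),
                       beta = default_sim_beta(),
                       intercept = NA_real_, target_prevalence = 0.209,
                       f_age = function(a) 0.9 * sin(pi * (a - 15) / 60),
                       f_page = function(a) 0.8 * sin(pi * (a - 15) / 110),
                       tau2_spat = 0.3, tau2_unstr = 0.05,
                       p_underweight = 0.12,
                       category_probs = default_category_probs(),
                       region_probs = NULL, seed = 1L) {
  stopifnot(n >= 1, tau2_spat >= 0, tau2_unstr >= 0,
            p_underweight >= 0, p_underweight <= 1)
  for (v in names(category_probs)) {
    p <- category_probs[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("category_probs for '", v, "' must be non-negative and sum to 1")
  }
  for (v in names(beta)) {
    if (!is.null(category_probs[[v]]) &&
        !all(names(beta[[v]]) %in% names(category_probs[[v]])))
      stop("beta levels for '", v, "' not all present in category_probs")
  }
  if (is.na(intercept)) {
    shift <- sum(vapply(names(beta), function(v) {
      p <- category_probs[[v]]
      sum(p[names(beta[[v]])] * beta[[v]])
    }, numeric(1)))
    intercept <- qlogis(target_prevalence) - shift
  }
  structure(list(n = as.integer(n), graph = graph, beta = beta,
                 intercept = intercept, f_age = f_age, f_page = f_page,
                 tau2_spat = tau2_spat, tau2_unstr = tau2_unstr,
                 p_underweight = p_underweight,
                 category_probs = category_probs,
                 region_probs = region_probs, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_category_probs <- function() {
  list(
    educ_respondent = c(none = 0.503, primary = 0.229, secondary = 0.221,
                        higher = 0.047),
    educ_partner = c(none = 0.414, primary = 0.214, secondary = 0.264,
                     higher = 0.108),
    residence = c(rural = 0.734, urban = 0.266),
    religion = c(catholic = 0.086, other_christian = 0.326, islam = 0.567,
                 traditionalist = 0.019, other = 0.002),
    wealth = c(poorest = 0.265, poorer = 0.240, middle = 0.196,
               richer = 0.166, richest = 0.133),
    ethnicity = c(Ekoi = 0.015, Fulani = 0.096, Hausa = 0.282,
                  Ibibio = 0.016, Igala = 0.012, Igbo = 0.105,
                  `Ijaw/Izon` = 0.031, `Kanuri/Beriberi` = 0.033,
                  Tiv = 0.028, Yoruba = 0.108, Others = 0.274))
}

#' @rdname sim_config
#' @export
default_sim_beta <- function() {
  list(
    educ_respondent = log(c(primary = 1.17, secondary = 1.49, higher = 1.68)),
    educ_partner = log(c(primary = 0.83, secondary = 0.81, higher = 0.96)),
    residence = log(c(urban = 1.24)),
    religion = log(c(other_christian = 0.77, islam = 0.74,
                     traditionalist = 0.75, other = 1.49)),
    wealth = log(c(poorer = 1.19, middle = 1.89, richer = 2.44,
                   richest = 3.45)),
    ethnicity = log(c(Fulani = 3.10, Hausa = 4.29, Ibibio = 4.79,
                      Igala = 7.47, Igbo = 6.41, `Ijaw/Izon` = 6.22,
                      `Kanuri/Beriberi` = 3.47, Tiv = 4.53, Yoruba = 5.44,
                      Others = 4.78)))
}

rtrunc_int <- function(n, mean, sd, lo, hi) {
  x <- round(rnorm(n, mean, sd))
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  as.integer(x)
}

#' Simulate a survey with known ground truth
#'
#' Draws covariates from the configured marginals (independently), assigns
#' each woman to a region, computes the latent log-odds
#' `eta = intercept + beta'x + f_age(age) + f_page(page) + u_s + v_s`
#' with centred smooths and ICAR/iid region effects, and generates the
#' outcome: with probability `p_underweight` a BMI uniform in [15, 18.5)
#' (no outcome model); otherwise `y ~ Bernoulli(plogis(eta))` and a BMI
#' drawn uniformly inside the destination category ([25, 35) if `y = 1`,
#' [18.5, 25) otherwise), so that WHO categorisation is exactly
#' invertible.
#'
#' @param config a [sim_config()].
#' @return list of class `"sim_survey"`: `records` (data.frame in the
#'   [read_records()] schema) and `truth` (list with `spatial_effects`,
#'   `unstructured_effects`, `beta`, `intercept`, centred effect grids
#'   `f_age_grid` / `f_page_grid`, latent `eta` and `y`).
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n
  g <- config$graph
  R <- length(g$regions)

  draw_cat <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  rec <- data.frame(id = sprintf("id%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  rec$age_respondent <- rtrunc_int(n, 29.3, 7.1, 15, 49)
  rec$age_partner <- rtrunc_int(n, 40.9, 12.8, 15, 95)
  for (v in names(config$category_probs))
    rec[[v]] <- draw_cat(config$category_probs[[v]])
  rp <- config$region_probs %||% rep(1 / R, R)
  rec$state <- factor(sample(g$regions, n, replace = TRUE, prob = rp),
                      levels = g$regions)

  eta <- rep(config$intercept, n)
  for (v in names(config$beta)) {
    bv <- config$beta[[v]]
    eff <- bv[as.character(rec[[v]])]
    eff[is.na(eff)] <- 0            # reference / unlisted levels
    eta <- eta + eff
  }
  age_grid <- 15:49
  page_grid <- 15:95
  f_age_grid <- rep(0, length(age_grid))
  f_page_grid <- rep(0, length(page_grid))
  if (!is.null(config$f_age)) {
    fa <- config$f_age(rec$age_respondent)
    fa_c <- fa - mean(fa)
    eta <- eta + fa_c
    f_age_grid <- config$f_age(age_grid) - mean(fa)
  }
  if (!is.null(config$f_page)) {
    fp <- config$f_page(rec$age_partner)
    fp_c <- fp - mean(fp)
    eta <- eta + fp_c
    f_page_grid <- config$f_page(page_grid) - mean(fp)
  }
  u <- if (config$tau2_spat > 0) {
    draw_icar_effects(g, config$tau2_spat)
  } else setNames(rep(0, R), g$regions)
  v <- if (config$tau2_unstr > 0) {
    vv <- rnorm(R, 0, sqrt(config$tau2_unstr))
    setNames(vv - mean(vv), g$regions)
  } else setNames(rep(0, R), g$regions)
  sidx <- as.integer(rec$state)
  eta <- eta + u[sidx] + v[sidx]

  underweight <- runif(n) < config$p_underweight
  y <- ifelse(underweight, NA_integer_,
              rbinom(n, 1, plogis(eta)))
  bmi <- numeric(n)
  bmi[underweight] <- runif(sum(underweight), 15, 18.5)
  ok1 <- !underweight & y == 1
  ok0 <- !underweight & y == 0
  bmi[ok1] <- runif(sum(ok1), 25, 35)
  bmi[ok0] <- runif(sum(ok0), 18.5, 25)
  rec$bmi <- bmi

  truth <- list(spatial_effects = u, unstructured_effects = v,
                beta = config$beta, intercept = config$intercept,
                age_grid = age_grid, f_age_grid = f_age_grid,
                page_grid = page_grid, f_page_grid = f_page_grid,
                eta = eta, y = y)
  structure(list(records = rec, truth = truth, config = config),
            class = "sim_survey")
}
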