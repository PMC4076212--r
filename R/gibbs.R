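#' MCMC configuration
#'
#' @param iterations total Gibbs iterations (default 12000).
#' @param burnin discarded initial iterations (default 2000).
#' @param thin keep every `thin`-th post-burn-in iteration (default 10).
#' @param a,b inverse-gamma hyperparameters shared by every variance
#'   (default 0.001, 0.001 — a conventional diffuse choice).
#' @param fixed_prior_var Gaussian prior variance for fixed effects
#'   (default 1e6, effectively flat).
#' @param seed RNG seed.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 12000, burnin = 2000, thin = 10,
                        a = 0.001, b = 0.001, fixed_prior_var = 1e6,
                        seed = 1L) {
  stopifnot(burnin < iterations, thin >= 1, a > 0, b > 0,
            fixed_prior_var > 0)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 a = a, b = b, fixed_prior_var = fixed_prior_var,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# One draw from N(Prec^{-1} rhs, Prec^{-1}) via the Cholesky of Prec.
draw_gaussian_block <- function(Prec, rhs) {
  L <- chol(Prec)                       # upper triangular: Prec = t(L) L
  mu <- backsolve(L, forwardsolve(t(L), rhs))
  mu + backsolve(L, rnorm(length(rhs)))
}

#' Gibbs sampler for the Bayesian geo-additive logit model
#'
#' Samples the posterior of the binary geo-additive model
#' \deqn{logit P(y_i = 1) = x_i' \beta + \sum_j f_j(z_{ij}) + u_{s_i} + v_{s_i}}
#' with diffuse Gaussian priors on the fixed effects \eqn{\beta}, P-spline
#' (second-order random walk) priors on each smooth's basis coefficients,
#' an intrinsic CAR prior on the structured region effects `u`, iid
#' Gaussian unstructured region effects `v`, and inverse-gamma priors on
#' every variance.  The logistic likelihood is handled by Polya-Gamma data
#' augmentation, so every full conditional is Gaussian or inverse-gamma
#' and the chain needs no tuning.
#'
#' After every iteration each smooth and each spatial component is
#' re-centred to sum to zero (exactly, using the B-spline partition of
#' unity) with the removed mean transferred into the intercept, which
#' resolves the intrinsic priors' level non-identifiability.
#'
#' @param y binary response vector.
#' @param fixed design matrix for fixed effects, first column the
#'   intercept (use [build_design()]), or `NULL` for intercept only.
#' @param splines named list of `"spline_block"`s ([bspline_design()]),
#'   or `NULL`.
#' @param spatial `NULL`, or a list with `region` (factor of region ids
#'   per observation), `graph` (a [region_graph] covering every observed
#'   region) and optional `unstructured = TRUE`.
#' @param config an [mcmc_config()].
#' @return object of class `"posterior_draws"`: matrices `beta`
#'   (draws x p), `u`, `v` (draws x R), list `gamma` of draws x K
#'   matrices, matrix `tau2`, plus `labels`, `splines`, `graph`, `config`.
#' @export
gibbs_sampler <- function(y, fixed = NULL, splines = NULL, spatial = NULL,
                          config = mcmc_config()) {
  n <- length(y)
  stopifnot(all(y %in% c(0, 1)))
  X <- if (is.null(fixed)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else as.matrix(fixed)
  if (nrow(X) != n) stop("fixed design does not match y")
  p <- ncol(X)
  kappa <- y - 0.5

  has_spat <- !is.null(spatial)
  if (has_spat) {
    g <- spatial$graph
    region <- factor(as.character(spatial$region), levels = g$regions)
    if (anyNA(region))
      stop("observed region missing from graph: ",
           paste(unique(setdiff(as.character(spatial$region), g$regions)),
                 collapse = ", "))
    ridx <- as.integer(region)
    R <- length(g$regions)
    Q <- icar_precision(g)
    rankQ <- R - max(g$component)
    use_v <- isTRUE(spatial$unstructured %||% TRUE)
    comp <- g$component
    obs_per_comp <- tabulate(comp[ridx], max(comp))
  }
  nsp <- length(splines)
  sp_names <- names(splines) %||% if (nsp) paste0("s", seq_len(nsp)) else NULL

  # state
  beta <- rep(0, p)
  gamma <- lapply(splines, function(b) rep(0, ncol(b$basis)))
  tau2_sp <- rep(0.1, nsp)
  if (has_spat) {
    u <- rep(0, R); v <- rep(0, R)
    tau2_u <- 0.1; tau2_v <- 0.1
  }

  n_save <- (config$iterations - config$burnin) %/% config$thin
  out_beta <- matrix(NA_real_, n_save, p, dimnames = list(NULL, colnames(X)))
  out_gamma <- lapply(splines, function(b) matrix(NA_real_, n_save, ncol(b$basis)))
  out_tau2 <- matrix(NA_real_, n_save, nsp + if (has_spat) 2 else 0)
  colnames(out_tau2) <- c(if (nsp) paste0("tau2_", sp_names),
                          if (has_spat) c("tau2_spat", "tau2_unstr"))
  if (has_spat) {
    out_u <- matrix(NA_real_, n_save, R, dimnames = list(NULL, g$regions))
    out_v <- out_u
  }

  set.seed(config$seed)
  isave <- 0L
  prior_fixed <- diag(1 / config$fixed_prior_var, p)

  for (it in seq_len(config$iterations)) {
    # current linear predictor
    eta <- drop(X %*% beta)
    if (nsp) for (j in seq_len(nsp))
      eta <- eta + drop(splines[[j]]$basis %*% gamma[[j]])
    if (has_spat) eta <- eta + u[ridx] + v[ridx]
    if (any(!is.finite(eta)))
      stop("non-finite linear predictor at iteration ", it)

    omega <- rpolyagamma(eta)

    # fixed effects
    eta_m <- eta - drop(X %*% beta)
    Prec <- crossprod(X * sqrt(omega)) + prior_fixed
    rhs <- drop(crossprod(X, kappa - omega * eta_m))
    beta <- draw_gaussian_block(Prec, rhs)
    eta <- eta_m + drop(X %*% beta)

    # spline blocks
    if (nsp) for (j in seq_len(nsp)) {
      B <- splines[[j]]$basis
      contrib <- drop(B %*% gamma[[j]])
      eta_m <- eta - contrib
      Prec <- crossprod(B * sqrt(omega)) +
        splines[[j]]$penalty / tau2_sp[j] +
        diag(1e-8, ncol(B))
      rhs <- drop(crossprod(B, kappa - omega * eta_m))
      gamma[[j]] <- draw_gaussian_block(Prec, rhs)
      eta <- eta_m + drop(B %*% gamma[[j]])
    }

    if (has_spat) {
      # structured ICAR block
      eta_m <- eta - u[ridx]
      sw <- as.vector(tapply(omega, factor(ridx, levels = seq_len(R)), sum,
                             default = 0))
      sr <- as.vector(tapply(kappa - omega * eta_m,
                             factor(ridx, levels = seq_len(R)), sum,
                             default = 0))
      Prec <- Q / tau2_u + diag(sw + 1e-8, R)
      u <- draw_gaussian_block(Prec, sr)
      eta <- eta_m + u[ridx]

      # unstructured block: diagonal full conditional
      if (use_v) {
        eta_m <- eta - v[ridx]
        sr <- as.vector(tapply(kappa - omega * eta_m,
                               factor(ridx, levels = seq_len(R)), sum,
                               default = 0))
        prec_v <- sw + 1 / tau2_v
        v <- rnorm(R, sr / prec_v, 1 / sqrt(prec_v))
        eta <- eta_m + v[ridx]
      }
    }

    # re-centre intrinsic blocks; the mean moves into the intercept
    if (nsp) for (j in seq_len(nsp)) {
      cj <- mean(drop(splines[[j]]$basis %*% gamma[[j]]))
      gamma[[j]] <- gamma[[j]] - cj   # rows sum to 1, so f drops by cj exactly
      beta[1] <- beta[1] + cj
    }
    if (has_spat) {
      comp_means <- as.vector(tapply(u, comp, mean))
      u <- u - comp_means[comp]
      # exact for a connected graph; observation-weighted otherwise
      beta[1] <- beta[1] + sum(comp_means * obs_per_comp) / n
      if (use_v) {
        cv <- mean(v)
        v <- v - cv
        beta[1] <- beta[1] + cv
      }
    }

    # variances
    if (nsp) for (j in seq_len(nsp)) {
      qf <- drop(crossprod(gamma[[j]], splines[[j]]$penalty %*% gamma[[j]]))
      tau2_sp[j] <- 1 / rgamma(1, config$a + splines[[j]]$rank / 2,
                               config$b + qf / 2)
    }
    if (has_spat) {
      qf <- drop(crossprod(u, Q %*% u))
      tau2_u <- 1 / rgamma(1, config$a + rankQ / 2, config$b + qf / 2)
      if (use_v)
        tau2_v <- 1 / rgamma(1, config$a + R / 2,
                             config$b + sum(v^2) / 2)
    }

    # save
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
      isave <- isave + 1L
      out_beta[isave, ] <- beta
      if (nsp) for (j in seq_len(nsp)) out_gamma[[j]][isave, ] <- gamma[[j]]
      if (has_spat) {
        out_u[isave, ] <- u
        out_v[isave, ] <- v
      }
      tt <- c(if (nsp) tau2_sp, if (has_spat) c(tau2_u, tau2_v))
      if (length(tt)) out_tau2[isave, ] <- tt
    }
  }

  structure(list(beta = out_beta[seq_len(isave), , drop = FALSE],
                 gamma = lapply(out_gamma, function(m) m[seq_len(isave), , drop = FALSE]),
                 u = if (has_spat) out_u[seq_len(isave), , drop = FALSE],
                 v = if (has_spat) out_v[seq_len(isave), , drop = FALSE],
                 tau2 = out_tau2[seq_len(isave), , drop = FALSE],
                 splines = splines,
                 graph = if (has_spat) g,
                 config = config),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$beta), "saved draws;",
      ncol(x$beta), "fixed effect(s);",
      length(x$gamma), "smooth(s);",
      if (!is.null(x$u)) paste(ncol(x$u), "regions") else "no spatial block",
      "\n")
  invisible(x)
}

#' Fit the geo-additive model to an analysis set
#'
#' Convenience wrapper: builds the fixed-effect design (categorical
#' covariates, reference levels first), cubic P-spline blocks for
#' respondent and partner age, and the spatial blocks from a region graph,
#' then runs [gibbs_sampler()].
#'
#' @param aset an `"analysis_set"`.
#' @param graph a [region_graph] covering the observed states.
#' @param fixed_covariates categorical fixed-effect columns.
#' @param smooth continuous columns receiving P-spline smooths.
#' @param K basis size per smooth (default 20).
#' @param unstructured include the iid region effect (default TRUE).
#' @param config an [mcmc_config()].
#' @return a `"posterior_draws"` with the design `labels` attached.
#' @export
fit_geoadditive <- function(aset, graph,
                            fixed_covariates = c("educ_respondent",
                                                 "educ_partner", "residence",
                                                 "religion", "wealth",
                                                 "ethnicity"),
                            smooth = c("age_respondent", "age_partner"),
                            K = 20, unstructured = TRUE,
                            config = mcmc_config()) {
  d <- aset$data
  des <- build_design(d, covariates = fixed_covariates)
  blocks <- lapply(smooth, function(v) bspline_design(d[[v]], K = K))
  names(blocks) <- smooth
  draws <- gibbs_sampler(d$y, fixed = des$X, splines = blocks,
                         spatial = list(region = d$state, graph = graph,
                                        unstructured = unstructured),
                         config = config)
  draws$labels <- des$labels
  draws
}
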