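#' Grouped-age factors for the marginal model
#'
#' Respondent age is grouped <=25 / 26-35 / 36-49 and partner age
#' <=30 / 31-40 / 41+, with the youngest group as reference.
#'
#' @param age numeric ages.
#' @return factor of age groups.
#' @export
group_age_respondent <- function(age) {
  cut(age, breaks = c(-Inf, 25, 35, 49), labels = c("<=25", "26-35", "36-49"))
}

#' @rdname group_age_respondent
#' @export
group_age_partner <- function(age) {
  cut(age, breaks = c(-Inf, 30, 40, Inf), labels = c("<=30", "31-40", "41+"))
}

#' Dummy-coded design matrix for the marginal logistic model
#'
#' Intercept plus treatment-coded dummies for every non-reference level of
#' each requested covariate; continuous ages are grouped via
#' [group_age_respondent()] / [group_age_partner()].  Reference levels come
#' first in the codebook factors, so each dummy is named
#' `<variable>:<level>`.
#'
#' @param data analysis-set data.frame.
#' @param covariates covariate columns to include, in order.
#' @return list with `X` (numeric matrix, first column intercept),
#'   `labels` (data.frame mapping columns to variable and level) and the
#'   row-aligned outcome `y` if present.
#' @export
build_design <- function(data,
                         covariates = c("age_respondent", "age_partner",
                                        "educ_respondent", "educ_partner",
                                        "residence", "religion", "wealth",
                                        "ethnicity", "state")) {
  covariates <- intersect(covariates, names(data))
  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  labels <- data.frame(column = "(Intercept)", variable = "(Intercept)",
                       level = "", stringsAsFactors = FALSE)
  for (v in covariates) {
    x <- data[[v]]
    if (v == "age_respondent") x <- group_age_respondent(x)
    if (v == "age_partner") x <- group_age_partner(x)
    x <- droplevels(as.factor(x))
    lev <- levels(x)
    if (length(lev) < 2) next
    for (l in lev[-1]) {
      cn <- paste0(v, ":", l)
      cols[[cn]] <- as.numeric(x == l)
      labels <- rbind(labels,
                      data.frame(column = cn, variable = v, level = l,
                                 stringsAsFactors = FALSE))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design error: collinear column(s): ", paste(dep, collapse = ", "))
  }
  list(X = X, labels = labels, y = data$y)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson / IRLS for the Bernoulli logit model, iterated until the
#' deviance changes by less than `tol` (default 1e-8) or `max_iter`
#' iterations.  The deviance is asserted non-increasing at every step
#' (with step-halving if a full Newton step would increase it).  Probable
#' complete separation (a coefficient beyond +/-15 while the deviance is
#' still falling) raises a warning.
#'
#' @param X design matrix (first column typically the intercept), full
#'   column rank.
#' @param y binary response vector in {0, 1}.
#' @param tol convergence tolerance on the deviance change.
#' @param max_iter maximum iterations.
#' @return object of class `"logit_fit"`: `coefficients`, `vcov`,
#'   `se`, `converged`, `iterations`, `deviance`, `logLik`.
#' @export
fit_logistic_irls <- function(X, y, tol = 1e-8, max_iter = 100) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (qr(X)$rank < ncol(X)) stop("design error: X is rank-deficient")
  beta <- rep(0, ncol(X))
  dev <- -2 * sum(dbinom(y, 1, plogis(drop(X %*% beta)), log = TRUE))
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    beta_new <- fit$coefficients
    # step-halving guards monotone deviance on near-separated data
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      dev_new <- -2 * sum(dbinom(y, 1, plogis(drop(X %*% cand)), log = TRUE))
      if (dev_new <= dev + 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    stopifnot(dev_new <= dev + 1e-8)
    delta <- dev - dev_new
    beta <- cand
    dev <- dev_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (any(abs(beta) > 15))
    warning("possible complete separation: |coefficient| > 15")
  if (!converged)
    warning("IRLS did not converge in ", max_iter, " iterations")
  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- chol2inv(chol(XtWX))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(coefficients = setNames(beta, colnames(X)),
                 vcov = vcov, se = sqrt(diag(vcov)),
                 converged = converged, iterations = iter,
                 deviance = dev, logLik = -dev / 2),
            class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("logistic fit:", length(x$coefficients), "coefficients,",
      x$iterations, "IRLS iterations,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(deviance %.2f)\n", x$deviance))
  invisible(x)
}

#' Odds-ratio table from a maximum-likelihood logistic fit
#'
#' Wald intervals: `exp(coef +/- z * SE)`.  Reference levels of each
#' covariate are included as rows printing OR 1.00 with no interval,
#' matching epidemiological table conventions.
#'
#' @param fit a `"logit_fit"` (must have converged).
#' @param labels label data.frame from [build_design()]; optional.
#' @param level confidence level, default 0.95.
#' @return data.frame with variable, level, or, lower, upper.
#' @export
or_table <- function(fit, labels = NULL, level = 0.95) {
  if (!fit$converged) stop("fit did not converge; refusing to summarise")
  z <- qnorm(1 - (1 - level) / 2)
  co <- fit$coefficients
  se <- fit$se
  if (is.null(labels)) {
    labels <- data.frame(column = names(co), variable = names(co),
                         level = "", stringsAsFactors = FALSE)
  }
  rows <- list()
  for (v in unique(labels$variable)) {
    if (v == "(Intercept)") next
    sub <- labels[labels$variable == v, , drop = FALSE]
    lev_fitted <- sub$level
    # reference row
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "(reference)", or = 1, lower = NA_real_,
      upper = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sub))) {
      cn <- sub$column[k]
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = lev_fitted[k], or = exp(co[cn]),
        lower = exp(co[cn] - z * se[cn]), upper = exp(co[cn] + z * se[cn]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format an odds ratio with its interval, table style
#'
#' @param or,lower,upper numeric vectors.
#' @return character vector like `"1.24 (1.14, 1.36)"`.
#' @export
format_or <- function(or, lower, upper) {
  ifelse(is.na(lower), sprintf("%.2f", or),
         sprintf("%.2f (%.2f, %.2f)", or, lower, upper))
}
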