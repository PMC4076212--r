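#' Parameter-recovery report for a simulated survey
#'
#' Compares posterior summaries from a geo-additive fit against the known
#' ground truth of the simulation that produced the data: per-coefficient
#' bias and credible-interval coverage for the fixed effects, peak
#' location and RMSE of the smooth age effects, and rank correlation,
#' RMSE and coverage for the total regional effects.
#'
#' @param sim a `"sim_survey"` from [simulate_survey()].
#' @param draws a `"posterior_draws"` fitted to (the analysis set of)
#'   `sim$records`.
#' @param level credible level for coverage checks (default 0.95).
#' @return list of class `"recovery_report"` with elements `fixed`
#'   (data.frame: label, truth, estimate, lower, upper, covered),
#'   `smooths` (per smooth: true and estimated peak, rmse), and `spatial`
#'   (rank_correlation, rmse, coverage, table).
#' @export
parameter_recovery <- function(sim, draws, level = 0.95) {
  stopifnot(inherits(sim, "sim_survey"), inherits(draws, "posterior_draws"))
  truth <- sim$truth
  alpha <- (1 - level) / 2

  # fixed effects: match configured beta levels to design columns
  fixed <- NULL
  if (!is.null(draws$labels)) {
    rows <- list()
    for (v in names(truth$beta)) {
      for (l in names(truth$beta[[v]])) {
        cn <- paste0(v, ":", l)
        if (!cn %in% colnames(draws$beta)) next
        x <- draws$beta[, cn]
        qs <- quantile(x, c(alpha, 1 - alpha), names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          label = cn, truth = unname(truth$beta[[v]][l]),
          estimate = mean(x), lower = qs[1], upper = qs[2],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      fixed <- do.call(rbind, rows)
      fixed$covered <- fixed$truth >= fixed$lower & fixed$truth <= fixed$upper
    }
  }

  # smooths: peak location and RMSE on the truth grid
  smooths <- list()
  grids <- list(age_respondent = list(x = truth$age_grid, f = truth$f_age_grid),
                age_partner = list(x = truth$page_grid, f = truth$f_page_grid))
  for (nm in names(draws$splines)) {
    gr <- grids[[nm]]
    if (is.null(gr)) next
    rng <- draws$splines[[nm]]$range
    keep <- gr$x >= rng[1] & gr$x <= rng[2]   # clip to fitted range
    gx <- gr$x[keep]
    gf <- gr$f[keep] - mean(gr$f[keep])       # re-centre on the clipped grid
    cv <- nonlinear_curve(draws, nm, grid = gx, level = level)
    smooths[[nm]] <- list(
      true_peak = gx[which.max(gf)],
      est_peak = cv$x[which.max(cv$mean)],
      rmse = sqrt(mean((cv$mean - gf)^2)),
      curve = cv)
  }

  # total spatial effects
  spatial <- NULL
  if (!is.null(draws$u)) {
    true_tot <- truth$spatial_effects + truth$unstructured_effects
    tot <- draws$u + draws$v
    common <- intersect(colnames(tot), names(true_tot))
    est <- colMeans(tot)[common]
    lo <- apply(tot[, common, drop = FALSE], 2, quantile, alpha)
    hi <- apply(tot[, common, drop = FALSE], 2, quantile, 1 - alpha)
    tr <- true_tot[common]
    spatial <- list(
      rank_correlation = cor(tr, est, method = "spearman"),
      rmse = sqrt(mean((est - tr)^2)),
      coverage = mean(tr >= lo & tr <= hi),
      table = data.frame(region = common, truth = unname(tr),
                         estimate = unname(est), lower = unname(lo),
                         upper = unname(hi), stringsAsFactors = FALSE))
  }

  structure(list(fixed = fixed, smooths = smooths, spatial = spatial,
                 level = level),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery report (", x$level * 100, "% intervals)\n", sep = "")
  if (!is.null(x$fixed))
    cat("  fixed effects:", nrow(x$fixed), "checked;",
        sum(x$fixed$covered), "covered; mean |bias| =",
        sprintf("%.3f", mean(abs(x$fixed$estimate - x$fixed$truth))), "\n")
  for (nm in names(x$smooths)) {
    s <- x$smooths[[nm]]
    cat("  smooth ", nm, ": peak ", s$est_peak, " (true ", s$true_peak,
        "), rmse ", sprintf("%.3f", s$rmse), "\n", sep = "")
  }
  if (!is.null(x$spatial))
    cat("  spatial: rank corr", sprintf("%.3f", x$spatial$rank_correlation),
        "; rmse", sprintf("%.3f", x$spatial$rmse),
        "; coverage", sprintf("%.2f", x$spatial$coverage), "\n")
  invisible(x)
}
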