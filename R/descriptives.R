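#' Crude prevalence from a pair of counts
#'
#' @param n1 count of cases (y = 1).
#' @param n0 count of non-cases (y = 0).
#' @param digits decimal places for reporting (default 1, matching survey
#'   tables).
#' @return percentage `100 * n1 / (n1 + n0)` rounded to `digits`.
#' @export
crude_prevalence <- function(n1, n0, digits = 1) {
  if (any(n1 < 0) || any(n0 < 0)) stop("counts must be non-negative")
  tot <- n1 + n0
  if (any(tot == 0)) stop("empty stratum: prevalence undefined")
  round(100 * n1 / tot, digits)
}

#' Pearson chi-square test on an r x c contingency table
#'
#' Classical Pearson statistic sum((O - E)^2 / E) with df = (r-1)(c-1) and
#' an upper-tail chi-square p-value, without continuity correction.
#'
#' @param tab matrix of counts (typically r x 2: covariate levels by
#'   outcome).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal total: expected counts undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties.  Exact enumeration is used when
#' the smaller sample has at most `exact_max` observations and there are no
#' ties; otherwise the normal approximation with tie-corrected variance and
#' continuity correction.  The reported U is the smaller of the two
#' one-sided statistics.
#'
#' @param x,y numeric samples.
#' @param exact_max switch to the exact null distribution when
#'   `min(length(x), length(y)) <= exact_max` (default 8).
#' @return list with `U`, `p.value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both samples")
    return(list(U = length(x) * length(y) / 2, p.value = 1,
                method = "degenerate"))
  }
  exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  u1 <- unname(wt$statistic)                  # U for x over y
  u <- min(u1, length(x) * length(y) - u1)
  list(U = u, p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Crude odds ratio from a 2 x 2 table
#'
#' Cross-product ratio `ad / (bc)` with the Woolf (log) confidence
#' interval `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d cell counts: exposed cases, exposed non-cases, unexposed
#'   cases, unexposed non-cases.
#' @param level confidence level (default 0.95).
#' @param correction add 0.5 to every cell (Haldane-Anscombe) instead of
#'   failing on a zero cell.
#' @return list with `or`, `lower`, `upper`.
#' @export
crude_odds_ratio <- function(a, b, c, d, level = 0.95, correction = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("counts must be non-negative")
  if (any(cells == 0)) {
    if (!correction)
      stop("zero cell; set correction = TRUE for the 0.5 continuity correction")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  lo <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - level) / 2)
  list(or = exp(lo), lower = exp(lo - z * se), upper = exp(lo + z * se))
}

#' Outcome cross-tabulation by a categorical covariate
#'
#' Counts and percentages of overweight/obese vs normal weight per level of
#' `by`, with the Pearson chi-square test for the full table.  Row
#' percentages (share overweight/obese within each stratum) mirror
#' by-covariate prevalence tables; column percentages (share of the sample
#' in each stratum) mirror whole-sample description tables.
#'
#' @param aset an `"analysis_set"` (or its `data`).
#' @param by name of a factor column.
#' @return data.frame of class `"cross_tab"` with per-level counts `n1`,
#'   `n0`, row percentage `pct_case`, column percentage `pct_of_sample`,
#'   and attributes `statistic`, `df`, `p.value`.
#' @export
cross_tab <- function(aset, by) {
  d <- if (inherits(aset, "analysis_set")) aset$data else aset
  if (!by %in% names(d)) stop("no column '", by, "'")
  f <- droplevels(as.factor(d[[by]]))
  n1 <- as.vector(tapply(d$y, f, sum, default = 0L))
  n  <- as.vector(table(f))
  n0 <- n - n1
  out <- data.frame(level = levels(f), n1 = n1, n0 = n0,
                    pct_case = round(100 * n1 / pmax(n, 1), 1),
                    pct_of_sample = round(100 * n / sum(n), 1),
                    stringsAsFactors = FALSE)
  ok <- n > 0
  ct <- chi_square_test(cbind(n1, n0)[ok, , drop = FALSE])
  attr(out, "statistic") <- ct$statistic
  attr(out, "df") <- ct$df
  attr(out, "p.value") <- ct$p.value
  class(out) <- c("cross_tab", "data.frame")
  out
}

#' Whole-sample descriptive summary
#'
#' Mean (SD) of continuous variables and column percentages of every
#' categorical variable, in the style of a baseline-characteristics table.
#'
#' @param records a records data.frame (pre- or post-exclusion).
#' @return named list: `continuous` (data.frame variable/mean/sd/n) and
#'   `categorical` (data.frame variable/level/n/pct).
#' @export
describe_sample <- function(records) {
  cont_vars <- intersect(c("age_respondent", "age_partner", "bmi"),
                         names(records))
  cont <- do.call(rbind, lapply(cont_vars, function(v) {
    x <- records[[v]]
    data.frame(variable = v, mean = mean(x, na.rm = TRUE),
               sd = sd(x, na.rm = TRUE), n = sum(!is.na(x)))
  }))
  cat_vars <- names(records)[vapply(records, is.factor, logical(1))]
  cats <- do.call(rbind, lapply(cat_vars, function(v) {
    tab <- table(records[[v]], useNA = "no")
    data.frame(variable = v, level = names(tab), n = as.vector(tab),
               pct = round(100 * as.vector(tab) / sum(tab), 1))
  }))
  list(continuous = cont, categorical = cats)
}

#' Compare two outcome groups over all covariates
#'
#' For each continuous covariate a Mann-Whitney U test between cases and
#' non-cases; for each categorical covariate a chi-square test on the
#' level-by-outcome table.
#'
#' @param aset an `"analysis_set"`.
#' @return data.frame with variable, test, statistic and p-value.
#' @export
group_comparisons <- function(aset) {
  d <- aset$data
  cont_vars <- intersect(c("age_respondent", "age_partner"), names(d))
  rows <- lapply(cont_vars, function(v) {
    ok <- !is.na(d[[v]])
    mw <- mann_whitney_u(d[[v]][ok & d$y == 1], d[[v]][ok & d$y == 0])
    data.frame(variable = v, test = "Mann-Whitney U",
               statistic = mw$U, p.value = mw$p.value)
  })
  cat_vars <- setdiff(names(d)[vapply(d, is.factor, logical(1))],
                      "bmi_category")
  rows <- c(rows, lapply(cat_vars, function(v) {
    ctab <- cross_tab(d, v)
    data.frame(variable = v, test = "chi-square",
               statistic = attr(ctab, "statistic"),
               p.value = attr(ctab, "p.value"))
  }))
  do.call(rbind, rows)
}
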