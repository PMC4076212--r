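#' Body mass index
#'
#' BMI (Quetelet index) = weight in kilograms divided by height in metres
#' squared.
#'
#' @param weight_kg weight in kg, positive.
#' @param height_m height in metres, positive.
#' @return BMI in kg/m^2 (vectorised).
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0))
    stop("weight and height must be positive and finite")
  weight_kg / height_m^2
}

#' WHO BMI category
#'
#' WHO adult bands: underweight below 18.5 kg/m^2; normal weight 18.5 to
#' below 25; overweight 25 to below 30; obese 30 and above.  The upper
#' bounds are half-open, so 24.95 is normal and 29.95 overweight.
#'
#' @param bmi BMI in kg/m^2, positive (vectorised).
#' @return factor with levels `underweight < normal < overweight < obese`.
#' @export
categorize_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("bmi must be positive and finite")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Build the analysis set for the binary overweight/obesity outcome
#'
#' Applies the two analysis exclusions in a fixed order: first underweight
#' women (BMI < 18.5) are removed, then records with any missing value in
#' the model covariates (complete-case analysis).  The binary outcome is
#' y = 1 for overweight/obese (BMI >= 25), y = 0 for normal weight.
#'
#' @param records validated records (see [read_records()]).
#' @param covariates character vector of covariate columns required
#'   complete; defaults to the full model set.
#' @return list of class `"analysis_set"`: `data` (records with added
#'   `bmi_category` and outcome `y`), and `ledger` with counts `input`,
#'   `underweight_excluded`, `incomplete_excluded`, `retained` (the three
#'   last always sum to `input`).
#' @export
build_analysis_set <- function(records,
                               covariates = c("age_respondent", "age_partner",
                                              "educ_respondent", "educ_partner",
                                              "residence", "religion",
                                              "wealth", "ethnicity", "state")) {
  covariates <- intersect(covariates, names(records))
  n_in <- nrow(records)
  cat <- categorize_bmi(records$bmi)
  uw <- cat == "underweight"
  kept <- records[!uw, , drop = FALSE]
  kept_cat <- cat[!uw]
  cc <- stats::complete.cases(kept[, covariates, drop = FALSE])
  out <- kept[cc, , drop = FALSE]
  out$bmi_category <- droplevels(kept_cat[cc])
  out$y <- as.integer(kept_cat[cc] %in% c("overweight", "obese"))
  rownames(out) <- NULL
  ledger <- list(input = n_in,
                 underweight_excluded = sum(uw),
                 incomplete_excluded = sum(!cc),
                 retained = nrow(out))
  if (ledger$retained == 0) stop("no records retained after exclusions")
  structure(list(data = out, ledger = ledger), class = "analysis_set")
}

#' @export
print.analysis_set <- function(x, ...) {
  l <- x$ledger
  cat("analysis_set:", l$retained, "records retained of", l$input,
      "\n  excluded:", l$underweight_excluded, "underweight,",
      l$incomplete_excluded, "incomplete\n  outcome: ",
      sum(x$data$y), "overweight/obese (",
      sprintf("%.1f%%", 100 * mean(x$data$y)), ")\n")
  invisible(x)
}
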