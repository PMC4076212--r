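#' Read individual survey records
#'
#' Reads a CSV of individual records (one woman per row) and validates it
#' against a codebook.  Mandatory columns: `id`, `age_respondent`,
#' `residence`, `religion`, `wealth`, `ethnicity`, `state`,
#' `educ_respondent`, plus either `bmi` or the pair `weight_kg`,
#' `height_m` (BMI is then computed as weight / height^2).  Optional:
#' `age_partner`, `educ_partner` (missing for unpartnered women).  Empty
#' strings and `"."` denote missing values.
#'
#' Rows whose mandatory fields cannot be parsed (non-numeric age or BMI,
#' age outside 15--49, non-positive BMI) are dropped and counted in the
#' `"dropped"` attribute.  An unknown category label is an error naming the
#' row and the offending value, since it indicates a codebook mismatch
#' rather than ordinary missingness.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @param codebook a `"codebook"`, default [default_codebook()].
#' @return A `data.frame` of validated records with attribute `"dropped"`
#'   (number of unparseable rows removed).  Categorical columns are factors
#'   with codebook level order; `state` labels are canonicalised through
#'   the known print aliases (e.g. "Oye" -> "Oyo").
#' @export
read_records <- function(path, codebook = default_codebook()) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "."), fileEncoding = "UTF-8")
  mandatory <- c("id", "age_respondent", "educ_respondent", "residence",
                 "religion", "wealth", "ethnicity", "state")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  has_bmi <- "bmi" %in% names(raw)
  has_wh <- all(c("weight_kg", "height_m") %in% names(raw))
  if (!has_bmi && !has_wh)
    stop("schema error: need a 'bmi' column or both 'weight_kg' and 'height_m'")
  if (!has_bmi) raw$bmi <- raw$weight_kg / raw$height_m^2
  raw$state <- canonical_state(as.character(raw$state))

  cat_vars <- c("educ_respondent", "educ_partner", "residence", "religion",
                "wealth", "ethnicity", "state")
  for (v in intersect(cat_vars, names(raw))) {
    vals <- raw[[v]]
    bad <- which(!is.na(vals) & !(vals %in% codebook[[v]]))
    if (length(bad))
      stop("codebook error: unknown ", v, " label '", vals[bad[1]],
           "' in row ", bad[1])
  }

  ok <- !is.na(raw$age_respondent) & raw$age_respondent >= 15 &
    raw$age_respondent <= 49 & !is.na(raw$bmi) & raw$bmi > 0
  dropped <- sum(!ok)
  if (dropped)
    message(dropped, " row(s) with unparseable mandatory fields dropped")
  out <- raw[ok, , drop = FALSE]
  for (v in intersect(cat_vars, names(out))) {
    out[[v]] <- factor(out[[v]], levels = codebook[[v]])
  }
  out$id <- as.character(out$id)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Write individual records to CSV
#'
#' Round-trip companion of [read_records()]: missing values are written as
#' empty fields, factors as their labels.
#'
#' @param records data.frame of records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  for (v in names(out)) if (is.factor(out[[v]])) out[[v]] <- as.character(out[[v]])
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8",
            quote = TRUE)
  invisible(path)
}
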