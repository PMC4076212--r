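#' Published overweight/obesity cross-tabulation counts
#'
#' Case (overweight/obese) and control (normal weight) counts per
#' covariate stratum and per state for the 2008 Nigerian survey of women
#' aged 15-49, as printed in the published baseline table, together with
#' the printed row percentages and the count of underweight women excluded
#' from the binary analysis.  State labels are canonicalised through the
#' same aliases as [read_records()].
#'
#' @return data.frame with columns variable, level, n_case, pct_case,
#'   n_control, pct_control; attribute `"underweight_excluded"` holds the
#'   excluded count.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "table2_counts.csv", package = "geoadd",
                      mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  uw <- tab$n_case[tab$variable == "excluded" & tab$level == "underweight"]
  tab <- tab[tab$variable != "excluded", , drop = FALSE]
  tab$level[tab$variable == "state"] <-
    canonical_state(tab$level[tab$variable == "state"])
  rownames(tab) <- NULL
  attr(tab, "underweight_excluded") <- uw
  tab
}
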