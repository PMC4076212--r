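#' Default variable codebook
#'
#' Ordered category labels for every categorical survey variable, with the
#' reference level first.  The reference levels follow the conventions of
#' DHS overweight/obesity analyses for Nigeria: no education, Catholic,
#' poorest wealth quintile, Ekoi ethnicity, rural residence and Yobe state.
#'
#' @param graph optional [region_graph]; when supplied its region ids
#'   (re-ordered so the reference region comes first) replace the default
#'   Nigeria state list.
#' @return A named list of character vectors, class `"codebook"`.  Each
#'   element's first entry is the reference level.
#' @export
default_codebook <- function(graph = NULL) {
  states <- if (is.null(graph)) nigeria_region_names() else graph$regions
  ref <- if ("Yobe" %in% states) "Yobe" else states[1]
  cb <- list(
    educ_respondent = c("none", "primary", "secondary", "higher"),
    educ_partner    = c("none", "primary", "secondary", "higher"),
    residence       = c("rural", "urban"),
    religion        = c("catholic", "other_christian", "islam",
                        "traditionalist", "other"),
    wealth          = c("poorest", "poorer", "middle", "richer", "richest"),
    ethnicity       = c("Ekoi", "Fulani", "Hausa", "Ibibio", "Igala",
                        "Igbo", "Ijaw/Izon", "Kanuri/Beriberi", "Tiv",
                        "Yoruba", "Others"),
    state           = c(ref, setdiff(states, ref))
  )
  structure(cb, class = "codebook")
}

#' Read / write a codebook as YAML
#'
#' @param path file path.
#' @return `read_codebook()` returns a `"codebook"`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  cb <- yaml::read_yaml(path)
  cb <- lapply(cb, as.character)
  validate_codebook(structure(cb, class = "codebook"))
}

#' @rdname read_codebook
#' @param codebook a `"codebook"` object.
#' @export
write_codebook <- function(codebook, path) {
  yaml::write_yaml(unclass(codebook), path)
  invisible(path)
}

validate_codebook <- function(cb) {
  needed <- c("educ_respondent", "educ_partner", "residence", "religion",
              "wealth", "ethnicity", "state")
  missing <- setdiff(needed, names(cb))
  if (length(missing))
    stop("codebook lacks variables: ", paste(missing, collapse = ", "))
  for (v in needed) {
    if (anyDuplicated(cb[[v]]))
      stop("codebook variable '", v, "' has duplicated levels")
  }
  cb
}

# State names as printed in the aggregated 31-region analysis (30 states +
# the federal capital, with six pairs of post-1996 split states merged).
nigeria_region_names <- function() {
  c("Abia", "Abuja", "Adamawa", "Akwa Ibom", "Anambra", "Bauchi/Gombe",
    "Benue", "Borno", "Cross River", "Delta", "Edo", "Enugu/Ebonyi",
    "Imo", "Jigawa", "Kaduna", "Kano", "Katsina", "Kebbi", "Kogi",
    "Kwara", "Lagos", "Nassarawa/Plateau", "Niger", "Ogun", "Ondo/Ekiti",
    "Osun", "Oyo", "Rivers/Bayelsa", "Sokoto/Zamfara", "Taraba", "Yobe")
}

# Aliases occasionally seen in print for the same regions.
state_aliases <- function() {
  c("Oye" = "Oyo",
    "Enungu/Ebonyi" = "Enugu/Ebonyi",
    "Crossriver" = "Cross River",
    "Cross river" = "Cross River")
}

canonical_state <- function(x) {
  al <- state_aliases()
  hit <- x %in% names(al)
  x[hit] <- al[x[hit]]
  x
}
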