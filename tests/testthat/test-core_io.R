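make_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

base_rows <- function(n = 3) {
  data.frame(id = paste0("w", seq_len(n)),
             age_respondent = c(22, 35, 49)[seq_len(n)],
             age_partner = c(30, 45, 60)[seq_len(n)],
             bmi = c(21.0, 27.5, 31.2)[seq_len(n)],
             educ_respondent = "primary", educ_partner = "none",
             residence = "urban", religion = "islam", wealth = "middle",
             ethnicity = "Hausa", state = "Lagos",
             stringsAsFactors = FALSE)
}

test_that("well-formed records load unchanged and round-trip bit-identically", {
  p <- make_records_csv(base_rows())
  rec <- read_records(p)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "dropped"), 0)
  expect_s3_class(rec$wealth, "factor")
  expect_equal(levels(rec$wealth)[1], "poorest")

  p2 <- tempfile(fileext = ".csv")
  write_records(rec, p2)
  rec2 <- read_records(p2)
  attr(rec, "dropped") <- attr(rec2, "dropped") <- NULL
  expect_identical(rec, rec2)
})

test_that("unknown category labels fail naming the label; missing columns fail", {
  d <- base_rows()
  d$wealth[2] <- "richest2"
  expect_error(read_records(make_records_csv(d)), "richest2")
  d2 <- base_rows()
  d2$state <- NULL
  expect_error(read_records(make_records_csv(d2)), "state")
})

test_that("bmi is computed from weight and height when absent", {
  d <- base_rows()
  d$bmi <- NULL
  d$weight_kg <- c(60, 81, 70)
  d$height_m <- c(1.65, 1.80, 1.55)
  rec <- read_records(make_records_csv(d))
  expect_equal(rec$bmi, c(60 / 1.65^2, 81 / 1.80^2, 70 / 1.55^2))
  expect_equal(rec$bmi[1], 22.038, tolerance = 1e-4)
})

test_that("unparseable mandatory fields are dropped with a count", {
  d <- base_rows()
  d$age_respondent[2] <- 12      # outside 15-49
  d$bmi[3] <- NA
  expect_message(rec <- read_records(make_records_csv(d)), "2 row")
  expect_equal(nrow(rec), 1)
  expect_equal(attr(rec, "dropped"), 2)
})

test_that("state print aliases are canonicalised", {
  d <- base_rows()
  d$state <- c("Oye", "Enungu/Ebonyi", "Crossriver")
  rec <- read_records(make_records_csv(d))
  expect_equal(as.character(rec$state),
               c("Oyo", "Enugu/Ebonyi", "Cross River"))
})

test_that("adjacency files parse, symmetrise and find components", {
  p <- tempfile()
  writeLines(c("3", "A 1 B", "B 2 A C", "C 1 B"), p)
  g <- read_adjacency(p)
  expect_equal(g$neighbors, list(A = "B", B = c("A", "C"), C = "B"))
  expect_equal(max(g$component), 1)

  # one-sided A->B symmetrised with a warning
  writeLines(c("2", "A 1 B", "B 0"), p)
  expect_warning(g2 <- read_adjacency(p), "symmetrised")
  expect_equal(g2$neighbors$B, "A")

  # two disjoint pairs -> two components
  writeLines(c("4", "A 1 B", "B 1 A", "C 1 D", "D 1 C"), p)
  g3 <- read_adjacency(p)
  expect_equal(max(g3$component), 2)

  # undeclared neighbour id is an error
  writeLines(c("2", "A 1 Z", "B 0"), p)
  expect_error(read_adjacency(p), "Z")
})

test_that("adjacency round-trips through write_adjacency", {
  g <- make_lattice_graph(3)
  p <- tempfile()
  write_adjacency(g, p)
  g2 <- read_adjacency(p)
  expect_identical(g$neighbors, g2$neighbors)
  expect_identical(g$component, g2$component)
})

test_that("the shipped Nigeria fixture is a 31-region symmetric connected graph", {
  g <- nigeria_graph()
  expect_equal(length(g$regions), 31)
  expect_equal(max(g$component), 1)
  for (r in g$regions) {
    for (s in g$neighbors[[r]]) expect_true(r %in% g$neighbors[[s]])
  }
  merged <- c("Bauchi/Gombe", "Ondo/Ekiti", "Nassarawa/Plateau",
              "Rivers/Bayelsa", "Sokoto/Zamfara", "Enugu/Ebonyi")
  expect_true(all(merged %in% g$regions))
  expect_true(all(g$regions %in% default_codebook()$state))
})

test_that("codebooks round-trip through YAML and validate reference levels", {
  cb <- default_codebook()
  expect_equal(cb$wealth[1], "poorest")
  expect_equal(cb$religion[1], "catholic")
  expect_equal(cb$ethnicity[1], "Ekoi")
  expect_equal(cb$state[1], "Yobe")
  expect_equal(cb$residence[1], "rural")
  p <- tempfile(fileext = ".yaml")
  write_codebook(cb, p)
  expect_equal(unclass(read_codebook(p)), unclass(cb))
})
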