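#' Region adjacency graph
#'
#' A `region_graph` holds an ordered set of region ids, a symmetric
#' neighbour structure and the partition into connected components.  It is
#' the spatial index for the structured (intrinsic CAR) effect: two regions
#' are neighbours when they share a boundary.
#'
#' @param regions character vector of unique region ids.
#' @param neighbors named list (one element per region, same order) of
#'   character vectors of adjacent region ids.  Symmetry is enforced:
#'   one-sided entries are symmetrised with a warning.
#' @return An object of class `"region_graph"` with elements `regions`,
#'   `neighbors` and `component` (integer component label per region).
#' @export
region_graph <- function(regions, neighbors) {
  regions <- as.character(regions)
  if (anyDuplicated(regions)) stop("duplicated region ids")
  if (!setequal(names(neighbors), regions) ||
      length(neighbors) != length(regions))
    stop("neighbors must be a named list covering every region exactly once")
  neighbors <- neighbors[regions]
  bad <- setdiff(unique(unlist(neighbors)), regions)
  if (length(bad))
    stop("neighbour id(s) not among declared regions: ",
         paste(bad, collapse = ", "))
  for (r in regions) {
    if (r %in% neighbors[[r]]) stop("self-loop at region ", r)
  }
  asym <- FALSE
  for (r in regions) {
    for (s in neighbors[[r]]) {
      if (!(r %in% neighbors[[s]])) {
        neighbors[[s]] <- c(neighbors[[s]], r)
        asym <- TRUE
      }
    }
  }
  if (asym) warning("asymmetric adjacency input symmetrised")
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  g <- structure(list(regions = regions, neighbors = neighbors),
                 class = "region_graph")
  g$component <- graph_components(g)
  g
}

graph_components <- function(g) {
  edges <- graph_edges(g)
  ig <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = g$regions))
  comp <- igraph::components(ig)$membership
  as.integer(comp[g$regions])
}

graph_edges <- function(g) {
  from <- rep(g$regions, lengths(g$neighbors))
  to <- unlist(g$neighbors, use.names = FALSE)
  keep <- match(from, g$regions) < match(to, g$regions)
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", length(x$regions), "regions,",
      nrow(graph_edges(x)), "edges,",
      max(x$component), "component(s)\n")
  invisible(x)
}

#' Number of regions / edges in a region graph
#' @param g a [region_graph].
#' @return integer count.
#' @export
n_regions <- function(g) length(g$regions)

#' Read a region adjacency file
#'
#' Plain-text neighbour-list format: first line the region count `R`; then
#' one line per region with the region id, its neighbour count, and the
#' neighbour ids, all whitespace-separated.  Region ids containing spaces
#' must be quoted.
#'
#' @param path file path.
#' @return a [region_graph]; one-sided adjacencies are symmetrised with a
#'   warning.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n) || n < 1) stop("first line must be the region count")
  if (length(lines) < n + 1)
    stop("expected ", n, " region lines, found ", length(lines) - 1)
  regions <- character(n)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    tok <- scan(text = lines[i + 1], what = character(), quiet = TRUE)
    regions[i] <- tok[1]
    k <- suppressWarnings(as.integer(tok[2]))
    if (is.na(k) || length(tok) != 2 + k)
      stop("malformed line for region ", tok[1],
           ": neighbour count does not match listed ids")
    neigh[[i]] <- if (k > 0) tok[-(1:2)] else character()
  }
  names(neigh) <- regions
  region_graph(regions, neigh)
}

#' Write a region adjacency file
#' @param g a [region_graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(g, path) {
  quote_id <- function(x) ifelse(grepl("\\s", x), shQuote(x, "cmd"), x)
  lines <- c(as.character(length(g$regions)),
             vapply(g$regions, function(r) {
               nb <- g$neighbors[[r]]
               paste(c(quote_id(r), length(nb), quote_id(nb)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Rook-adjacency lattice graph
#'
#' An `m` by `m` grid whose cells are regions and whose edges connect
#' horizontally or vertically adjacent cells.  Used as a compact synthetic
#' geography for recovery experiments.
#'
#' @param m lattice side, an integer >= 2.
#' @return a connected [region_graph] with `m^2` regions named `"r<i>_<j>"`.
#' @export
make_lattice_graph <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 2 || m != round(m))
    stop("m must be a single integer >= 2")
  m <- as.integer(m)
  idx <- expand.grid(i = seq_len(m), j = seq_len(m))
  nm <- sprintf("r%d_%d", idx$i, idx$j)
  neigh <- vector("list", m * m)
  names(neigh) <- nm
  for (k in seq_len(m * m)) {
    i <- idx$i[k]; j <- idx$j[k]
    nb <- character()
    if (i > 1) nb <- c(nb, sprintf("r%d_%d", i - 1, j))
    if (i < m) nb <- c(nb, sprintf("r%d_%d", i + 1, j))
    if (j > 1) nb <- c(nb, sprintf("r%d_%d", i, j - 1))
    if (j < m) nb <- c(nb, sprintf("r%d_%d", i, j + 1))
    neigh[[k]] <- nb
  }
  region_graph(nm, neigh)
}

#' Nigeria 31-region adjacency graph
#'
#' Adjacency between the 30 pre-1996 Nigerian states plus Abuja (FCT),
#' with the six post-1996 split pairs (Bauchi/Gombe, Ondo/Ekiti,
#' Nassarawa/Plateau, Rivers/Bayelsa, Sokoto/Zamfara, Enugu/Ebonyi) kept
#' merged, matching the aggregation used for state-level mapping.  Shipped
#' as a plain-text fixture in `inst/extdata/nigeria_adjacency.txt`.
#'
#' @return a connected [region_graph] with 31 regions.
#' @export
nigeria_graph <- function() {
  read_adjacency(system.file("extdata", "nigeria_adjacency.txt",
                             package = "geoadd", mustWork = TRUE))
}
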