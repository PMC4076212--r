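#' Posterior odds-ratio table for fixed effects
#'
#' Summarises each fixed-effect coefficient as the posterior odds ratio
#' POR = exp(posterior mean of the log-odds effect), with an equal-tailed
#' credible region `exp(quantiles)` and the posterior probability of a
#' positive effect.  Reference levels print POR 1.00 with no interval.
#'
#' @param draws a `"posterior_draws"` (from [gibbs_sampler()] /
#'   [fit_geoadditive()]).
#' @param level credible level (default 0.95).
#' @param point `"exp_mean"` (default: exp of the posterior mean) or
#'   `"mean_exp"` (posterior mean of the exponentiated effect).
#' @return data.frame with variable, level, por, lower, upper,
#'   prob_positive.
#' @export
summarize_fixed <- function(draws, level = 0.95, point = c("exp_mean", "mean_exp")) {
  point <- match.arg(point)
  B <- draws$beta
  if (is.null(B) || nrow(B) == 0) stop("no saved draws")
  if (nrow(B) < 100)
    warning("fewer than 100 saved draws: credible quantiles are unstable")
  alpha <- (1 - level) / 2
  labels <- draws$labels %||% data.frame(column = colnames(B),
                                         variable = colnames(B), level = "",
                                         stringsAsFactors = FALSE)
  rows <- list()
  for (v in unique(labels$variable)) {
    if (v == "(Intercept)") next
    sub <- labels[labels$variable == v, , drop = FALSE]
    rows[[length(rows) + 1]] <- data.frame(
      variable = v, level = "(reference)", por = 1, lower = NA_real_,
      upper = NA_real_, prob_positive = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(nrow(sub))) {
      x <- B[, sub$column[k]]
      pt <- if (point == "exp_mean") exp(mean(x)) else mean(exp(x))
      qs <- quantile(x, c(alpha, 1 - alpha), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = sub$level[k], por = pt,
        lower = exp(qs[1]), upper = exp(qs[2]),
        prob_positive = mean(x > 0), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior curve of a nonlinear (smooth) effect
#'
#' Pointwise posterior mean and equal-tailed credible band of a centred
#' P-spline smooth, evaluated on a grid inside the observed covariate
#' range.  Each saved draw's curve is centred to mean zero over the
#' observed covariate values before summarising, matching the sum-to-zero
#' identification of the fitted smooth.
#'
#' @param draws a `"posterior_draws"`.
#' @param smooth name or index of the smooth.
#' @param grid evaluation grid (default 200 points over the fitted range).
#' @param level credible level (default 0.80, the conventional level for
#'   nonlinear-effect displays in this model family).
#' @return data.frame with grid `x`, `mean`, `lower`, `upper`.
#' @export
nonlinear_curve <- function(draws, smooth = 1, grid = NULL, level = 0.80) {
  block <- draws$splines[[smooth]]
  if (is.null(block)) stop("no such smooth: ", smooth)
  G <- draws$gamma[[smooth]]
  if (is.null(grid))
    grid <- seq(block$range[1], block$range[2], length.out = 200)
  Bg <- bspline_eval(block, grid)
  curves <- G %*% t(Bg)                       # draws x grid
  # centre each draw over the observed covariate values
  obs_mean <- rowMeans(G %*% t(block$basis))
  curves <- curves - obs_mean
  alpha <- (1 - level) / 2
  data.frame(x = grid,
             mean = colMeans(curves),
             lower = apply(curves, 2, quantile, alpha),
             upper = apply(curves, 2, quantile, 1 - alpha))
}

#' Total spatial effect summaries and sign-categorised map
#'
#' The total residual spatial effect of region `r` is `u_r + v_r`
#' (structured plus unstructured) per draw.  Each region is summarised by
#' its POR = exp(posterior mean) with an equal-tailed credible region,
#' and categorised at the nominal level: `"positive"` if the lower
#' credible bound of the effect exceeds 0 (higher odds), `"negative"` if
#' the upper bound is below 0, `"none"` otherwise.
#'
#' @param draws a `"posterior_draws"` with a spatial block.
#' @param level nominal credible level for the sign rule (default 0.80).
#' @param observed_regions optional character vector of regions with data;
#'   regions absent from it are flagged `prior_only = TRUE`.
#' @return data.frame with region, por, lower, upper (odds-ratio scale),
#'   `prob_positive`, `category` and `prior_only`.
#' @export
categorize_map <- function(draws, level = 0.80, observed_regions = NULL) {
  if (is.null(draws$u)) stop("draws contain no spatial block")
  tot <- draws$u + draws$v
  alpha <- (1 - level) / 2
  m <- colMeans(tot)
  lo <- apply(tot, 2, quantile, alpha)
  hi <- apply(tot, 2, quantile, 1 - alpha)
  category <- ifelse(lo > 0, "positive", ifelse(hi < 0, "negative", "none"))
  out <- data.frame(region = colnames(tot), por = exp(m),
                    lower = exp(lo), upper = exp(hi),
                    prob_positive = colMeans(tot > 0),
                    category = category, stringsAsFactors = FALSE)
  out$prior_only <- if (is.null(observed_regions)) FALSE else
    !(out$region %in% observed_regions)
  if (any(out$prior_only))
    warning("region(s) without observations summarised from prior-dominated ",
            "draws: ", paste(out$region[out$prior_only], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Annotate region polygons with posterior map summaries
#'
#' Reads a GeoJSON FeatureCollection whose features carry a region id
#' (property `region` by default), attaches `por`, `cr_low`, `cr_high`,
#' `category` and a fill colour to each feature, and optionally writes the
#' annotated GeoJSON.  Colours: continuous red (high POR) to green (low)
#' for the odds map; black/grey/white for positive/none/negative in the
#' significance map.
#'
#' @param map data.frame from [categorize_map()].
#' @param polygons path to a GeoJSON file, or a parsed list as returned by
#'   `jsonlite::read_json`.
#' @param out optional output GeoJSON path.
#' @param id_property feature property holding the region id.
#' @return the annotated FeatureCollection (invisibly if `out` given).
#' @export
export_map <- function(map, polygons, out = NULL, id_property = "region") {
  fc <- if (is.character(polygons)) jsonlite::read_json(polygons) else polygons
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection")
  ids <- vapply(fc$features, function(f) {
    as.character(f$properties[[id_property]] %||% NA_character_)
  }, character(1))
  missing_poly <- setdiff(map$region, ids)
  missing_map <- setdiff(ids, map$region)
  if (length(missing_poly) || length(missing_map))
    stop("region id mismatch; no polygon for: ",
         paste(missing_poly, collapse = ", "),
         if (length(missing_map)) paste0("; no summary for: ",
                                         paste(missing_map, collapse = ", ")))
  # red = high odds, green = low, interpolated on log-POR rank
  rel <- rank(map$por) / nrow(map)
  or_col <- grDevices::rgb(rel, 1 - rel, 0)
  cat_col <- c(positive = "#000000", none = "#808080", negative = "#ffffff")
  for (k in seq_along(fc$features)) {
    i <- match(ids[k], map$region)
    fc$features[[k]]$properties$por <- map$por[i]
    fc$features[[k]]$properties$cr_low <- map$lower[i]
    fc$features[[k]]$properties$cr_high <- map$upper[i]
    fc$features[[k]]$properties$category <- map$category[i]
    fc$features[[k]]$properties$color_por <- or_col[i]
    fc$features[[k]]$properties$color_category <-
      unname(cat_col[map$category[i]])
  }
  if (!is.null(out)) {
    jsonlite::write_json(fc, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(fc))
  }
  fc
}

#' Square-lattice GeoJSON polygons
#'
#' Unit-square polygons for the regions of [make_lattice_graph()], so the
#' synthetic geography can exercise the map-export path.
#'
#' @param m lattice side.
#' @return a GeoJSON FeatureCollection (list).
#' @export
lattice_polygons <- function(m) {
  feats <- list()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    ring <- list(c(j - 1, i - 1), c(j, i - 1), c(j, i), c(j - 1, i),
                 c(j - 1, i - 1))
    feats[[length(feats) + 1]] <- list(
      type = "Feature",
      properties = list(region = sprintf("r%d_%d", i, j)),
      geometry = list(type = "Polygon", coordinates = list(ring)))
  }
  list(type = "FeatureCollection", features = feats)
}
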