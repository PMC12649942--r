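#' Closed-hull membership test
#'
#' Tests whether points lie inside or on the boundary of the convex hull of a
#' set of vertices in the (d13C, d15N) plane, by half-plane (cross-product)
#' tests against each hull edge. Boundary points count as inside, so
#' degenerate zero-spread settings behave predictably. A degenerate hull
#' (fewer than 3 distinct vertices, or collinear vertices) contains nothing.
#'
#' @param points Numeric matrix (m x 2) of query points.
#' @param vertices Numeric matrix (k x 2) whose convex hull defines the
#'   region; need not be ordered.
#' @param tol Numeric slack for the boundary test.
#' @return Logical vector of length m.
#' @export
point_in_hull <- function(points, vertices, tol = 1e-9) {
  points <- rbind(points)
  hull_idx <- grDevices::chull(vertices[, 1], vertices[, 2])
  hv <- vertices[hull_idx, , drop = FALSE]
  if (nrow(hv) < 3 || hull_area(hv) <= tol)
    return(rep(FALSE, nrow(points)))
  # chull returns vertices clockwise; traverse edges and require every cross
  # product on the same side (or on the edge)
  nh <- nrow(hv)
  inside <- rep(TRUE, nrow(points))
  for (e in seq_len(nh)) {
    a <- hv[e, ]; b <- hv[if (e == nh) 1L else e + 1L, ]
    cr <- (b[1] - a[1]) * (points[, 2] - a[2]) -
          (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (cr <= tol)  # clockwise: interior is right of edge
    if (!any(inside)) break
  }
  inside
}

#' Area of a convex polygon
#'
#' Shoelace formula over the convex hull of the supplied vertices.
#'
#' @param vertices Numeric matrix (k x 2).
#' @return Area (per-mil squared); 0 for degenerate (collinear) input.
#' @export
hull_area <- function(vertices) {
  idx <- grDevices::chull(vertices[, 1], vertices[, 2])
  if (length(idx) < 3) return(0)
  hv <- vertices[idx, , drop = FALSE]
  x <- hv[, 1]; y <- hv[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Monte-Carlo mixing-polygon (point-pattern) diagnostic
#'
#' At each iteration, trophic discrimination factors are drawn from
#' Normal(mean, SD) per tracer and each source mean from
#' Normal(mean, SD/sqrt(n)) (its standard error); source SDs are held at
#' their point estimates. The convex hull of the TEF-corrected source points
#' is constructed and every consumer (and optionally every grid-cell centre)
#' is tested for membership. Accumulated over iterations this yields each
#' consumer's inclusion proportion, a coverage raster of the feasible mixing
#' region, and a hull-area trace whose running variance indicates Monte-Carlo
#' stability.
#'
#' @param consumers Consumer sample table.
#' @param sources Source-summary table (>= 3 sources for a non-degenerate
#'   hull).
#' @param tef A [tef_spec()].
#' @param n_iter Number of iterations (default 1500).
#' @param grid_resolution Cells per axis for the coverage raster (default
#'   300); `NULL` or 0 skips the raster.
#' @param seed Integer seed.
#' @param pad Fractional padding of the data bounding box for the raster.
#' @param resample_sds Also resample source SDs via a scaled chi-square
#'   (sensitivity mode); default FALSE.
#' @return Object of class `mixspace_result`: `per_consumer_inclusion`,
#'   `hull_area_trace`, `running_variance`, `degenerate` (flags per
#'   iteration), and when a raster was requested `grid` (list `x`, `y`,
#'   `freq` matrix).
#' @export
run_mixspace <- function(consumers, sources, tef, n_iter = 1500,
                         grid_resolution = 300, seed = 1L, pad = 0.1,
                         resample_sds = FALSE) {
  consumers <- validate_samples(consumers)
  sources <- validate_sources(sources)
  if (nrow(sources) < 3) stop("need >= 3 sources for a mixing polygon")
  if (n_iter < 1) stop("n_iter must be >= 1")
  K <- nrow(sources)
  pts <- cbind(consumers$d13C, consumers$d15N)

  use_grid <- !is.null(grid_resolution) && grid_resolution > 0
  if (use_grid) {
    corr0 <- cbind(sources$mean_d13C + tef$mean_d13C,
                   sources$mean_d15N + tef$mean_d15N)
    ext <- rbind(pts, corr0)
    rngx <- range(ext[, 1]); rngy <- range(ext[, 2])
    px <- diff(rngx) * pad; py <- diff(rngy) * pad
    gx <- seq(rngx[1] - px, rngx[2] + px, length.out = grid_resolution)
    gy <- seq(rngy[1] - py, rngy[2] + py, length.out = grid_resolution)
    gpts <- cbind(rep(gx, times = grid_resolution),
                  rep(gy, each = grid_resolution))
    gcount <- numeric(nrow(gpts))
  }

  set.seed(seed)
  incl <- numeric(nrow(pts))
  areas <- numeric(n_iter)
  degen <- logical(n_iter)
  df <- pmax(sources$n - 1, 1)
  for (it in seq_len(n_iter)) {
    t13 <- stats::rnorm(1, tef$mean_d13C, tef$sd_d13C)
    t15 <- stats::rnorm(1, tef$mean_d15N, tef$sd_d15N)
    s13 <- sources$sd_d13C
    s15 <- sources$sd_d15N
    if (resample_sds) {
      # scaled chi-square draw of each source SD (df = n - 1), propagated
      # into the standard error used for the mean draw
      s13 <- s13 * sqrt(stats::rchisq(K, df) / df)
      s15 <- s15 * sqrt(stats::rchisq(K, df) / df)
    }
    m13 <- stats::rnorm(K, sources$mean_d13C, s13 / sqrt(sources$n))
    m15 <- stats::rnorm(K, sources$mean_d15N, s15 / sqrt(sources$n))
    corr <- cbind(m13 + t13, m15 + t15)
    a <- hull_area(corr)
    areas[it] <- a
    if (a <= 0) { degen[it] <- TRUE; next }
    incl <- incl + point_in_hull(pts, corr)
    if (use_grid) gcount <- gcount + point_in_hull(gpts, corr)
  }
  rv <- running_variance(areas)
  out <- list(n_iter = n_iter,
              per_consumer_inclusion = stats::setNames(incl / n_iter,
                                                       consumers$sample_id),
              hull_area_trace = areas,
              running_variance = rv,
              degenerate = degen,
              seed = seed)
  if (use_grid)
    out$grid <- list(x = gx, y = gy,
                     freq = matrix(gcount / n_iter, grid_resolution,
                                   grid_resolution))
  structure(out, class = "mixspace_result")
}

running_variance <- function(x) {
  n <- length(x)
  rv <- numeric(n)
  if (n >= 2)
    rv[2:n] <- vapply(2:n, function(i) stats::var(x[1:i]), numeric(1))
  rv
}

#' @export
print.mixspace_result <- function(x, ...) {
  cat("Mixing-polygon diagnostic:", x$n_iter, "iterations\n")
  cat(sprintf("  median inclusion %.3f (range %.3f-%.3f) over %d consumers\n",
              stats::median(x$per_consumer_inclusion),
              min(x$per_consumer_inclusion), max(x$per_consumer_inclusion),
              length(x$per_consumer_inclusion)))
  cat(sprintf("  hull area: mean %.2f permil^2, final running variance %.4f\n",
              mean(x$hull_area_trace), x$running_variance[x$n_iter]))
  invisible(x)
}

#' Per-consumer inclusion summary with low-feasibility flags
#'
#' Inclusion proportions below `flag_below` (default 0.2) indicate consumers
#' frequently excluded from the mixing polygon — a symptom of measurement
#' error, a missing source, or misspecified discrimination factors.
#'
#' @param result A `mixspace_result`.
#' @param flag_below Flagging threshold.
#' @return Data frame `sample_id, inclusion, flagged`.
#' @export
inclusion_summary <- function(result, flag_below = 0.2) {
  stopifnot(inherits(result, "mixspace_result"))
  p <- result$per_consumer_inclusion
  data.frame(sample_id = names(p), inclusion = as.numeric(p),
             flagged = as.numeric(p) < flag_below,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stability check on the hull-area running variance
#'
#' Declares the Monte-Carlo run stabilized at the first iteration where the
#' relative change of the running variance over the trailing `window`
#' iterations falls below `tol`. An all-constant trace (zero-spread settings)
#' stabilizes at iteration 1.
#'
#' @param result A `mixspace_result`.
#' @param window Trailing window length (iterations); must be < `n_iter`.
#' @param tol Relative-change tolerance (default 0.05).
#' @return List `stabilized` (flag) and `iteration` (first stabilization
#'   index, `NA` if never).
#' @export
convergence_check <- function(result, window = 100, tol = 0.05) {
  stopifnot(inherits(result, "mixspace_result"))
  n <- result$n_iter
  if (window >= n) stop("window must be smaller than n_iter")
  rv <- result$running_variance
  if (all(rv == 0)) return(list(stabilized = TRUE, iteration = 1L))
  for (i in seq.int(window + 2L, n)) {
    prev <- rv[i - window]
    if (prev > 0 && abs(rv[i] - prev) / prev < tol)
      return(list(stabilized = TRUE, iteration = i))
  }
  list(stabilized = FALSE, iteration = NA_integer_)
}

#' Iso-frequency contour of the coverage raster
#'
#' Extracts contour polylines at a coverage level (default 0.6) from the
#' mixing-space raster, e.g. the band containing cells feasible in >= 60% of
#' iterations.
#'
#' @param result A `mixspace_result` fitted with a grid.
#' @param level Coverage frequency in (0, 1).
#' @return List of polylines (each a list with `x`, `y`), as from
#'   [grDevices::contourLines()].
#' @export
coverage_contour <- function(result, level = 0.6) {
  stopifnot(inherits(result, "mixspace_result"))
  if (is.null(result$grid)) stop("result has no coverage grid")
  grDevices::contourLines(result$grid$x, result$grid$y, result$grid$freq,
                          levels = level)
}
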