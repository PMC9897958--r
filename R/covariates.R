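#' Composition groups for the seven cover classes
#'
#' Maps each land-cover code to the composition group used by the percent
#' metrics: forest, developed, or open.  The default matches the synthetic
#' classification of [landcover_classes()] (forest = class 3, developed =
#' class 6, open = class 5); reclassified real data can supply its own
#' mapping.
#'
#' @param forest,developed,open integer class codes per group.
#' @param nclass number of classes.
#' @return integer vector `group` of length `nclass` (0 = no group).
#' @export
class_groups <- function(forest = 3L, developed = 6L, open = 5L,
                         nclass = 7L) {
  g <- integer(nclass)
  g[forest] <- 1L; g[developed] <- 2L; g[open] <- 3L
  g
}

# circular-window membership lookup for a radius in meters
window_mask <- function(radius, res) {
  m <- floor(radius / res + 1e-9)
  d <- outer((-m:m)^2, (-m:m)^2, "+")
  list(mrad = m, win = sqrt(d) * res <= radius + 1e-9)
}

#' Moving-window landscape metrics
#'
#' Computes, for every cell (or a subset of cells), seven landscape-level
#' metrics over the circular window of the given radius (cells whose centres
#' lie within `radius` of the focal cell centre; windows truncate at the
#' raster border):
#'
#' * `for`, `dev`, `open` - percent of window cells in the forest, developed
#'   and open composition groups;
#' * `ED` - edge density, m/ha: total rook-adjacent unlike-pair edge length
#'   over window area;
#' * `IJI` - interspersion-juxtaposition index, percent; defined only when
#'   at least three classes are present in the window (`NA` otherwise);
#' * `PRD` - patch richness density, classes per 100 ha;
#' * `AI` - aggregation index, percent: proportion-weighted ratio of like
#'   adjacencies to the maximum possible for each class's area.
#'
#' Adjacencies use the rook rule with single counting, and both cells of a
#' pair must lie inside the window.
#'
#' @param landscape integer-class [grid_raster].
#' @param radius window radius, m (>= cell size).
#' @param cells optional data.frame with `row`, `col` to restrict
#'   computation to specific focal cells.
#' @param group composition-group mapping (see [class_groups()]).
#' @param nclass number of classes.
#' @return with `cells`: a numeric matrix (one row per cell, 7 named
#'   columns); otherwise a named list of seven [grid_raster] bands.
#' @export
moving_window_metrics <- function(landscape, radius, cells = NULL,
                                  group = class_groups(), nclass = 7L) {
  if (radius < landscape$res) stop("radius smaller than one cell")
  wm <- window_mask(radius, landscape$res)
  vals <- landscape$values
  storage.mode(vals) <- "integer"
  if (!is.null(cells)) {
    out <- .mw_metrics_cells(vals, nclass, group,
                             as.integer(cells$row), as.integer(cells$col),
                             wm$mrad, wm$win, landscape$res)
    return(out)
  }
  bands <- .mw_metrics_full(vals, nclass, group, wm$mrad, wm$win,
                            landscape$res)
  lapply(bands, function(m) grid_raster(m, landscape$xmin, landscape$ymin,
                                        landscape$res))
}

#' Multi-grain metric stack
#'
#' [moving_window_metrics()] at each grain radius, as full rasters.
#'
#' @param landscape integer-class [grid_raster].
#' @param radii grain radii, m.
#' @inheritParams moving_window_metrics
#' @return nested list `stack[[as.character(radius)]][[metric]]`.
#' @export
metric_stack <- function(landscape, radii = c(175, 250, 350, 500),
                         group = class_groups(), nclass = 7L) {
  setNames(lapply(radii, function(r)
    moving_window_metrics(landscape, r, group = group, nclass = nclass)),
    as.character(radii))
}

#' Euclidean distance raster
#'
#' Distance (m) from every cell centre to the nearest target: either the
#' nearest cell centre of a raster class, or the nearest point of a set of
#' polylines densified to at most `densify` meters between vertices.
#'
#' @param landscape integer-class [grid_raster].
#' @param target_class class code(s) defining raster targets.
#' @param lines list of two-column coordinate matrices (vector targets);
#'   exactly one of `target_class` / `lines` must be given.
#' @param densify maximum vertex spacing for line targets, m.
#' @return a [grid_raster] of distances, m.
#' @export
distance_raster <- function(landscape, target_class = NULL, lines = NULL,
                            densify = 10) {
  if (is.null(target_class) == is.null(lines))
    stop("give exactly one of target_class or lines")
  if (!is.null(target_class)) {
    tgt <- landscape$values %in% target_class
    if (!any(tgt)) stop("empty target set")
    dim(tgt) <- dim(landscape$values)
    d <- sqrt(.edt_squared(tgt)) * landscape$res
  } else {
    pts <- do.call(rbind, lapply(lines, densify_line, densify = densify))
    if (is.null(pts) || nrow(pts) == 0) stop("empty target set")
    d <- .dist_cells_to_points(nrow(landscape$values),
                               ncol(landscape$values), landscape$xmin,
                               landscape$ymin, landscape$res,
                               pts[, 1], pts[, 2])
  }
  grid_raster(d, landscape$xmin, landscape$ymin, landscape$res)
}

densify_line <- function(coords, densify = 10) {
  if (nrow(coords) < 2) return(coords)
  out <- list()
  for (i in seq_len(nrow(coords) - 1)) {
    a <- coords[i, ]; b <- coords[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1, ceiling(len / densify))
    tt <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    out[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  rbind(do.call(rbind, out), coords[nrow(coords), , drop = FALSE])
}

#' Attribute covariates to point locations
#'
#' Nearest-cell lookup (northwest tie-break on cell edges) of any mix of
#' distance rasters and metric bands, one row per point.  Rows where any
#' band is undefined (e.g. IJI in a window with fewer than three classes)
#' are flagged.
#'
#' @param x,y point coordinates.
#' @param rasters named list of [grid_raster]s on a shared grid.
#' @return data.frame of covariate values with a logical column
#'   `any_undefined`.
#' @export
extract_covariates <- function(x, y, rasters) {
  out <- raster_extract(rasters, x, y)
  out$any_undefined <- !complete.cases(out)
  out
}
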