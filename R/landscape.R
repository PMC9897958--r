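#' Land-cover class codes used by the synthetic landscapes
#'
#' Seven cover types on the 30-m grid: 1 open water, 2 wetland, 3 forest,
#' 4 agriculture, 5 open (pasture/shrub/grassland), 6 developed, 7 other.
#'
#' @return named integer vector of class codes.
#' @export
landcover_classes <- function() {
  c(water = 1L, wetland = 2L, forest = 3L, agriculture = 4L,
    open = 5L, developed = 6L, other = 7L)
}

#' Landscape generator configuration
#'
#' @param extent_cells grid side length in cells (square extent).
#' @param resolution cell size, m.
#' @param class_proportions 7 nonnegative fractions summing to 1, in the
#'   class order of [landcover_classes()].
#' @param clumping spatial aggregation in `[0, 1)`: 0 gives an iid mosaic,
#'   values near the percolation threshold give large coherent patches.
#' @param seed integer RNG seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(extent_cells = 300, resolution = 30,
                             class_proportions = c(0.05, 0.10, 0.18, 0.45,
                                                   0.18, 0.03, 0.01),
                             clumping = 0.5, seed = 1L) {
  if (length(class_proportions) != 7 || any(class_proportions < 0))
    stop("class_proportions must be 7 nonnegative fractions")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (extent_cells < 50)
    stop("extent must be at least 50 cells per side")
  if (clumping < 0 || clumping >= 1) stop("clumping must be in [0, 1)")
  structure(list(extent_cells = as.integer(extent_cells),
                 resolution = resolution,
                 class_proportions = class_proportions,
                 clumping = clumping, seed = as.integer(seed)),
            class = "landscape_config")
}

#' Generate a categorical patch-mosaic landscape
#'
#' Modified-random-clusters generator: cells are first marked with
#' probability proportional to `clumping` (capped below the percolation
#' threshold), marked cells are grouped into rook-adjacency clusters, whole
#' clusters are assigned to cover classes by sampling proportional to each
#' class's remaining area deficit, and unassigned cells take the class of the
#' nearest assigned cell (breadth-first fill).  `clumping = 0` reduces to an
#' iid multinomial mosaic.
#'
#' @param config a [landscape_config].
#' @return a [grid_raster] of integer class codes 1..7.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  n <- config$extent_cells
  p <- config$class_proportions
  withr_seed(config$seed, {
    if (config$clumping == 0) {
      cls <- matrix(sample.int(7L, n * n, replace = TRUE, prob = p), n, n)
    } else {
      # keep the percolation map subcritical so clusters stay finite
      p_mark <- 0.55 * config$clumping
      occ <- matrix(runif(n * n) < p_mark, n, n)
      lab <- .cc_label(occ)
      ncl <- attr(lab, "n")
      if (ncl == 0) {
        cls <- matrix(sample.int(7L, n * n, replace = TRUE, prob = p), n, n)
      } else {
        sizes <- tabulate(lab[lab > 0], nbins = ncl)
        assign <- integer(ncl)
        deficit <- p * n * n
        for (cl in sample.int(ncl)) {
          w <- pmax(deficit, 0)
          k <- if (sum(w) > 0) sample.int(7L, 1L, prob = w)
               else sample.int(7L, 1L, prob = p)
          assign[cl] <- k
          deficit[k] <- deficit[k] - sizes[cl]
        }
        cls <- matrix(0L, n, n)
        cls[lab > 0] <- assign[lab[lab > 0]]
        # seed any class that clusters missed so every class can appear
        for (k in which(p > 0 & tabulate(cls[cls > 0], 7L) == 0)) {
          free <- which(cls == 0L)
          if (length(free))
            cls[sample(free, max(1L, round(p[k] * n * n * 0.5)))] <- k
        }
        cls <- .bfs_fill(cls)
      }
    }
    grid_raster(cls, xmin = 0, ymin = 0, res = config$resolution)
  })
}

#' Synthesize linear features (streams or roads) across the extent
#'
#' Each polyline is a smoothed random walk entering on one side of the extent
#' and leaving on the opposite side.
#'
#' @param landscape a [grid_raster] giving the extent.
#' @param n_lines number of polylines.
#' @param step walk step length, m.
#' @param wiggle bearing innovation sd, radians.
#' @param seed RNG seed.
#' @return list of two-column coordinate matrices.
#' @export
simulate_linear_features <- function(landscape, n_lines = 2, step = 120,
                                     wiggle = 0.25, seed = 1L) {
  xmax <- raster_xmax(landscape); ymax <- raster_ymax(landscape)
  withr_seed(seed, {
    lapply(seq_len(n_lines), function(i) {
      horiz <- runif(1) < 0.5
      if (horiz) {
        pos <- c(0, runif(1, 0.2, 0.8) * ymax); bearing <- 0
      } else {
        pos <- c(runif(1, 0.2, 0.8) * xmax, 0); bearing <- pi / 2
      }
      pts <- list(pos)
      repeat {
        bearing <- bearing + rnorm(1, 0, wiggle)
        pos <- pos + step * c(cos(bearing), sin(bearing))
        pos[2] <- min(max(pos[2], 0), ymax)
        pos[1] <- min(max(pos[1], 0), xmax)
        pts[[length(pts) + 1]] <- pos
        if ((horiz && pos[1] >= xmax) || (!horiz && pos[2] >= ymax)) break
        if (length(pts) > 10000) break
      }
      do.call(rbind, pts)
    })
  })
}

# run code under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}
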