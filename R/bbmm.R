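#' Brownian motion variance of a trajectory segment (leave-one-out ML)
#'
#' Every second interior fix is scored under the Brownian bridge implied by
#' its two neighbours: with time fraction
#' `alpha = (t_i - t_{i-1}) / (t_{i+1} - t_{i-1})`, the bridge mean is the
#' linear interpolation of the neighbours and its variance is
#' `T alpha (1 - alpha) sigma2m + ((1 - alpha)^2 + alpha^2 + 1) delta^2`,
#' where `delta` is the GPS location error: the `(1 - alpha)^2` and
#' `alpha^2` terms carry the neighbours' observation error into the
#' interpolated mean and the final `delta^2` is the scored fix's own error
#' (omitting it biases the estimate upward by about `2 delta^2` per hour on
#' hourly data).  The diffusion parameter
#' `sigma2m` maximizes the summed bivariate-normal log density, optimized in
#' one dimension on the log scale.
#'
#' @param x,y coordinates, m.
#' @param time POSIXct or numeric hours.
#' @param location_error GPS error sd `delta`, m.
#' @param lower,upper search bounds for `sigma2m`, m^2/h.
#' @return list with `sigma2m` (m^2/h), `loglik`, `n_scored`.
#' @export
estimate_bm_variance <- function(x, y, time, location_error = 20,
                                 lower = 1e-2, upper = 1e7) {
  stopifnot(location_error > 0)
  n <- length(x)
  if (n < 3) stop("need at least 3 relocations")
  th <- if (inherits(time, "POSIXct"))
    as.numeric(time - time[1], units = "hours") else as.numeric(time)
  idx <- seq(2, n - 1, by = 2)
  a <- idx - 1; b <- idx + 1
  Tt <- th[b] - th[a]
  alpha <- (th[idx] - th[a]) / Tt
  mx <- (1 - alpha) * x[a] + alpha * x[b]
  my <- (1 - alpha) * y[a] + alpha * y[b]
  d2 <- (x[idx] - mx)^2 + (y[idx] - my)^2
  err <- ((1 - alpha)^2 + alpha^2 + 1) * location_error^2
  nll <- function(ls) {
    v <- Tt * alpha * (1 - alpha) * exp(ls) + err
    sum(log(v) + d2 / (2 * v))  # + const
  }
  opt <- optimize(nll, c(log(lower), log(upper)), tol = 1e-8)
  list(sigma2m = exp(opt$minimum),
       loglik = -opt$objective - length(idx) * log(2 * pi),
       n_scored = length(idx))
}

#' Brownian bridge utilization distribution on a grid
#'
#' The UD is the duration-weighted average over consecutive-fix bridges of
#' the bivariate normal position density, integrated over the bridge time
#' fraction by a trapezoid rule.  Quadrature nodes start at
#' `quad_nodes` and are doubled until the total-variation change of the
#' normalized UD is below `quad_tol`.
#'
#' @param x,y,time trajectory segment (time as POSIXct or numeric hours).
#' @param sigma2m Brownian motion variance, m^2/h.
#' @param location_error GPS error sd, m.
#' @param res grid resolution, m.
#' @param margin_sd margin around the fixes, in bridge standard deviations.
#' @param quad_nodes initial number of quadrature nodes (>= 2).
#' @param quad_tol total-variation convergence tolerance (set `Inf` to skip
#'   the refinement pass).
#' @param grid optional [grid_raster] defining the grid explicitly.
#' @return a [grid_raster] of cell probabilities summing to 1, with the
#'   truncated-mass fraction in `attr(, "truncation")`.
#' @export
compute_bbmm_ud <- function(x, y, time, sigma2m, location_error = 20,
                            res = 30, margin_sd = 3, quad_nodes = 10,
                            quad_tol = 1e-3, grid = NULL) {
  th <- if (inherits(time, "POSIXct"))
    as.numeric(time - time[1], units = "hours") else as.numeric(time)
  if (is.null(grid)) {
    Tmax <- max(diff(th))
    sdmax <- sqrt(0.25 * Tmax * sigma2m + location_error^2)
    m <- margin_sd * sdmax + res
    xmin <- floor((min(x) - m) / res) * res
    ymin <- floor((min(y) - m) / res) * res
    nc <- ceiling((max(x) + m - xmin) / res)
    nr <- ceiling((max(y) + m - ymin) / res)
  } else {
    xmin <- grid$xmin; ymin <- grid$ymin; res <- grid$res
    nr <- nrow(grid$values); nc <- ncol(grid$values)
  }
  acc <- function(K) {
    v <- .bbmm_ud_accumulate(x, y, th, sigma2m, location_error^2, K,
                             xmin, ymin, res, nr, nc, 4.5)
    v / sum(v)
  }
  K <- max(2L, as.integer(quad_nodes))
  ud <- acc(K)
  if (is.finite(quad_tol)) {
    repeat {
      K2 <- 2L * K
      ud2 <- acc(K2)
      tv <- 0.5 * sum(abs(ud2 - ud))
      ud <- ud2; K <- K2
      if (tv < quad_tol || K >= 160L) break
    }
  }
  out <- grid_raster(ud, xmin = xmin, ymin = ymin, res = res)
  # edge mass indicates truncation by the grid
  edge <- sum(ud[1, ]) + sum(ud[nrow(ud), ]) + sum(ud[, 1]) +
    sum(ud[, ncol(ud)])
  if (edge > 1e-3)
    warning(sprintf("UD grid may truncate mass (edge mass %.2g)", edge))
  attr(out, "truncation") <- edge
  attr(out, "quad_nodes") <- K
  out
}

#' Extract a UD isopleth as a home-range region
#'
#' Cells are ranked by probability and the smallest top-ranked set whose
#' total mass reaches `level` is selected; the region is the union of those
#' cells.
#'
#' @param ud a [grid_raster] of cell probabilities (see [compute_bbmm_ud()]).
#' @param level isopleth level in (0, 1].
#' @return a `home_range` object: logical cell `mask` plus grid metadata,
#'   `level`, and the contained mass `mass`.
#' @export
extract_isopleth <- function(ud, level = 0.95) {
  stopifnot(level > 0, level <= 1)
  p <- ud$values
  if (sum(p) == 0) stop("empty UD")
  mask <- matrix(FALSE, nrow(p), ncol(p))
  if (level >= 1) {
    mask[p > 0] <- TRUE
    mass <- sum(p[mask])
  } else {
    o <- order(p, decreasing = TRUE)
    cs <- cumsum(p[o])
    k <- which(cs >= level - 1e-12)[1]
    mask[o[seq_len(k)]] <- TRUE
    mass <- cs[k]
  }
  structure(list(mask = mask, xmin = ud$xmin, ymin = ud$ymin,
                 res = ud$res, level = level, mass = mass),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("home_range: %.0f%% isopleth, %d cells, %.3f km^2\n",
              100 * x$level, sum(x$mask), hr_area(x) / 1e6))
  invisible(x)
}

#' Area of a home-range region
#' @param hr a `home_range`.
#' @return area in m^2.
#' @export
hr_area <- function(hr) sum(hr$mask) * hr$res^2

#' Point-in-home-range test
#' @param hr a `home_range`.
#' @param x,y point coordinates.
#' @return logical vector; points off the UD grid are outside.
#' @export
hr_contains <- function(hr, x, y) {
  g <- grid_raster(hr$mask, hr$xmin, hr$ymin, hr$res)
  idx <- cell_of(g, x, y)
  inside <- rep(FALSE, length(x))
  ok <- !is.na(idx$row)
  inside[ok] <- hr$mask[cbind(idx$row[ok], idx$col[ok])]
  inside
}

#' Distance outside a home-range region
#'
#' Euclidean distance from each point to the region boundary; 0 for points
#' inside the region.
#'
#' @param hr a `home_range`.
#' @param x,y point coordinates.
#' @return numeric distances, m.
#' @export
hr_distance_outside <- function(hr, x, y) {
  d <- numeric(length(x))
  inside <- hr_contains(hr, x, y)
  out <- which(!inside)
  if (length(out)) {
    # boundary cells: region cells with a rook neighbour outside the region
    m <- hr$mask
    nb <- matrix(FALSE, nrow(m), ncol(m))
    nb[-1, ] <- nb[-1, ] | !m[-nrow(m), ]
    nb[-nrow(m), ] <- nb[-nrow(m), ] | !m[-1, ]
    nb[, -1] <- nb[, -1] | !m[, -ncol(m)]
    nb[, -ncol(m)] <- nb[, -ncol(m)] | !m[, -1]
    nb[1, ] <- nb[nrow(m), ] <- nb[, 1] <- nb[, ncol(m)] <- TRUE
    bd <- which(m & nb, arr.ind = TRUE)
    cx <- hr$xmin + (bd[, 2] - 0.5) * hr$res
    cy <- hr$ymin + (bd[, 1] - 0.5) * hr$res
    d[out] <- .min_dist_points_to_cells(x[out], y[out], cx, cy, hr$res / 2)
  }
  d
}
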