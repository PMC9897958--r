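#' Smooth synthetic covariate raster
#'
#' White noise on a coarse grid, bilinearly interpolated to the target
#' resolution and standardized to mean 0, sd 1 — a cheap stand-in for a
#' spatially autocorrelated habitat covariate.
#'
#' @param ncell cells per side.
#' @param res cell size, m.
#' @param range_cells coarse-grid spacing (controls autocorrelation range).
#' @param seed RNG seed.
#' @return a [grid_raster].
#' @export
simulate_covariate_raster <- function(ncell = 100, res = 30,
                                      range_cells = 10, seed = 1L) {
  withr_seed(seed, {
    k <- ceiling(ncell / range_cells) + 2
    coarse <- matrix(rnorm(k * k), k, k)
    pos <- (seq_len(ncell) - 0.5) / range_cells + 1
    i0 <- floor(pos); fr <- pos - i0
    m <- coarse[i0, i0] * outer(1 - fr, 1 - fr) +
      coarse[i0 + 1, i0] * outer(fr, 1 - fr) +
      coarse[i0, i0 + 1] * outer(1 - fr, fr) +
      coarse[i0 + 1, i0 + 1] * outer(fr, fr)
    m <- (m - mean(m)) / sd(m)
    grid_raster(m, 0, 0, res)
  })
}

#' Simulate step-selection data with known coefficients
#'
#' For each stratum, `J + 1` candidate steps share a random start point;
#' lengths are gamma and turns von Mises from the supplied kernel (the
#' previous bearing is uniform).  One candidate is marked used by sampling
#' with probability proportional to `exp(beta' x)` over the covariate
#' values at candidate endpoints.  Candidates falling off the raster are
#' rejected and resampled (up to 100 attempts each).
#'
#' @param rasters named list of covariate [grid_raster]s.
#' @param true_beta named coefficient vector over (a subset of) the raster
#'   names.
#' @param kernel a `movement_kernel` (or list with `shape`, `scale`, `mu`,
#'   `kappa`).
#' @param n_strata number of strata.
#' @param J available steps per stratum (>= 1).
#' @param seed RNG seed.
#' @return step design data.frame (`stratum`, `case`, `x1`, `y1`, `x2`,
#'   `y2`, `sl`, `ta`, covariate columns) with `attr(, "true_beta")`.
#' @export
simulate_ssf_steps <- function(rasters, true_beta, kernel, n_strata = 500,
                               J = 50, seed = 1L) {
  stopifnot(J >= 1)
  r1 <- rasters[[1]]
  xmax <- raster_xmax(r1); ymax <- raster_ymax(r1)
  margin <- min(qgamma(0.99, kernel$shape, scale = kernel$scale),
                0.25 * (xmax - r1$xmin))
  withr_seed(seed, {
    K <- J + 1
    N <- n_strata * K
    x0 <- rep(runif(n_strata, r1$xmin + margin, xmax - margin), each = K)
    y0 <- rep(runif(n_strata, r1$ymin + margin, ymax - margin), each = K)
    bear0 <- rep(runif(n_strata, -pi, pi), each = K)
    lens <- rgamma(N, kernel$shape, scale = kernel$scale)
    turns <- rvonmises(N, kernel$mu, kernel$kappa)
    xs <- x0 + lens * cos(bear0 + turns)
    ys <- y0 + lens * sin(bear0 + turns)
    off <- function() xs < r1$xmin | xs > xmax | ys < r1$ymin | ys > ymax
    att <- 0
    bad <- which(off())
    while (length(bad)) {
      att <- att + 1
      if (att > 100) stop("candidates fall off-raster repeatedly")
      lens[bad] <- rgamma(length(bad), kernel$shape, scale = kernel$scale)
      turns[bad] <- rvonmises(length(bad), kernel$mu, kernel$kappa)
      xs[bad] <- x0[bad] + lens[bad] * cos(bear0[bad] + turns[bad])
      ys[bad] <- y0[bad] + lens[bad] * sin(bear0[bad] + turns[bad])
      bad <- bad[xs[bad] < r1$xmin | xs[bad] > xmax | ys[bad] < r1$ymin |
                   ys[bad] > ymax]
    }
    cov <- raster_extract(rasters, xs, ys)
    eta <- rep(0, N)
    for (v in names(true_beta)) eta <- eta + true_beta[[v]] * cov[[v]]
    # used step sampled per stratum with P ~ exp(eta) (Gumbel argmax trick)
    g <- eta - log(-log(runif(N)))
    gm <- matrix(g, nrow = K)
    used_row <- max.col(t(gm), ties.method = "first")
    case <- integer(N)
    case[(seq_len(n_strata) - 1) * K + used_row] <- 1L
    design <- cbind(
      data.frame(stratum = rep(seq_len(n_strata), each = K), case = case,
                 x1 = x0, y1 = y0, x2 = xs, y2 = ys, sl = lens,
                 ta = turns), cov)
    attr(design, "true_beta") <- true_beta
    design
  })
}
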