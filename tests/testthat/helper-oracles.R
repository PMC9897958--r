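# Independent reference implementations used as oracles.  These are written
# as direct per-window / per-grid enumerations with no code shared with the
# package internals.

# Landscape-level metrics of one circular window by direct enumeration.
# Conventions mirror the documented ones: rook adjacency, single count,
# both cells inside the window; IJI defined only for >= 3 classes present.
oracle_window_metrics <- function(vals, frow, fcol, radius, res,
                                  group = c(0L, 0L, 1L, 0L, 3L, 2L, 0L),
                                  nclass = 7L) {
  nr <- nrow(vals); nc <- ncol(vals)
  inwin <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc &
    sqrt((r - frow)^2 + (c - fcol)^2) * res <= radius + 1e-9
  m <- floor(radius / res + 1e-9)
  gg <- expand.grid(r = (frow - m):(frow + m), c = (fcol - m):(fcol + m))
  g <- gg[inwin(gg$r, gg$c), , drop = FALSE]
  cls <- vals[cbind(g$r, g$c)]
  ncel <- nrow(g)
  area <- ncel * res^2
  cnt <- tabulate(cls, nclass)
  # east and north neighbour pairs, single count
  pr <- NULL
  for (d in list(c(0, 1), c(1, 0))) {
    ok <- inwin(g$r + d[1], g$c + d[2])
    if (any(ok))
      pr <- rbind(pr, cbind(cls[ok],
                            vals[cbind(g$r[ok] + d[1], g$c[ok] + d[2])]))
  }
  like <- integer(nclass)
  pair <- matrix(0, nclass, nclass)
  unlike <- 0L
  if (!is.null(pr)) {
    same <- pr[, 1] == pr[, 2]
    if (any(same)) {
      t1 <- table(factor(pr[same, 1], levels = 1:nclass))
      like <- as.integer(t1)
    }
    if (any(!same)) {
      unlike <- sum(!same)
      a <- pmin(pr[!same, 1], pr[!same, 2])
      b <- pmax(pr[!same, 1], pr[!same, 2])
      for (i in seq_along(a)) pair[a[i], b[i]] <- pair[a[i], b[i]] + 1
    }
  }
  richness <- sum(cnt > 0)
  pct <- function(gid) 100 * sum(cnt[group == gid]) / ncel
  ed <- 10000 * (unlike * res) / area
  iji <- NA_real_
  if (richness >= 3 && unlike > 0) {
    e <- pair[pair > 0] * res
    E <- unlike * res
    iji <- 100 * (-sum((e / E) * log(e / E))) /
      log(0.5 * richness * (richness - 1))
  }
  prd <- 1e6 * richness / area
  ai <- 0
  for (k in which(cnt > 0)) {
    A <- cnt[k]
    n <- floor(sqrt(A))
    mm <- A - n^2
    maxg <- 2 * n * (n - 1) + if (mm == 0) 0 else if (mm <= n)
      2 * mm - 1 else 2 * mm - 2
    if (maxg > 0) ai <- ai + (A / ncel) * (like[k] / maxg)
  }
  c(`for` = pct(1L), dev = pct(2L), open = pct(3L), ED = ed, IJI = iji,
    PRD = prd, AI = 100 * ai)
}

# Conditional-logistic log-likelihood by direct evaluation, and its
# maximizer over a 1-D grid (for single-covariate fixtures).
oracle_clr_loglik <- function(beta, x, stratum, case) {
  sum(vapply(split(seq_along(x), stratum), function(i) {
    eta <- beta * x[i]
    eta[case[i] == 1] - log(sum(exp(eta)))
  }, 0))
}

oracle_clr_grid <- function(x, stratum, case, lo = -5, hi = 5, by = 1e-4) {
  grid <- seq(lo, hi, by = by)
  ll <- vapply(grid, oracle_clr_loglik, 0, x = x, stratum = stratum,
               case = case)
  grid[which.max(ll)]
}

# Brute-force Euclidean distance raster (cell-centre to nearest target
# cell centre).
oracle_distance_raster <- function(vals, target_class, res) {
  tg <- which(array(vals %in% target_class, dim(vals)), arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(vals), ncol(vals))
  for (i in seq_len(nrow(vals)))
    for (j in seq_len(ncol(vals)))
      out[i, j] <- sqrt(min((i - tg[, 1])^2 + (j - tg[, 2])^2)) * res
  out
}

# A correlated 7-metric reference sample.
random_reference <- function(n = 200, p = 7, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  m <- matrix(rnorm(n * p), n) %*% A
  colnames(m) <- paste0("m", 1:p)
  m
}

# A hand-built hourly trajectory: resident cluster at `center` plus
# optional planted segments given as explicit coordinates.
make_fixture_track <- function(n, center = c(0, 0), spread = 250,
                               seed = 1, start = "2012-03-01 00:00:00") {
  set.seed(seed)
  data.frame(
    animal_id = "F1",
    timestamp = as.POSIXct(start, tz = "UTC") + 3600 * (0:(n - 1)),
    x = center[1] + rnorm(n, 0, spread),
    y = center[2] + rnorm(n, 0, spread),
    fix_dim = "3D", hdop = 1.5)
}
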