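#' Steps of an hourly trajectory
#'
#' Consecutive-fix displacement steps with length, absolute bearing and turn
#' angle.  The turn angle is the angle between successive displacement
#' vectors, counterclockwise positive, in `(-pi, pi]`.  Steps spanning a
#' missing hourly fix are flagged (`gap`) and excluded from kernel fitting
#' and strata construction.
#'
#' @param traj trajectory data.frame (`timestamp`, `x`, `y`).
#' @return data.frame with `from`, `to` (fix indices), `x1,y1,x2,y2`,
#'   `length`, `bearing`, `turn` (NA for the first step or after a gap),
#'   `gap`.
#' @export
track_steps <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("need >= 2 fixes")
  dt <- as.numeric(diff(traj$timestamp), units = "hours")
  dx <- diff(traj$x); dy <- diff(traj$y)
  len <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx)
  gap <- abs(dt - 1) > 1e-6
  turn <- c(NA, wrap_angle(diff(bearing)))
  turn[c(FALSE, gap[-length(gap)])] <- NA  # previous step spans a gap
  data.frame(from = 1:(n - 1), to = 2:n,
             x1 = traj$x[-n], y1 = traj$y[-n],
             x2 = traj$x[-1], y2 = traj$y[-1],
             length = len, bearing = bearing, turn = turn, gap = gap)
}

wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi  # convention: (-pi, pi]
  out
}

#' Fit the pooled EHRM movement kernel
#'
#' Gamma step-length distribution and von Mises turn-angle distribution,
#' both by maximum likelihood on steps pooled across individuals (short
#' events alone carry too few steps to fit per animal).  Step lengths of
#' zero are floored at 1 m.  The von Mises mean is the circular mean
#' direction and the concentration solves `A1(kappa) = Rbar` (Bessel-ratio
#' inversion).
#'
#' @param lengths step lengths, m.
#' @param turns turn angles, radians (NAs dropped).
#' @param min_steps minimum number of turn-defined steps.
#' @return a `movement_kernel`: `shape`, `scale` (gamma, m), `mu`, `kappa`
#'   (von Mises, radians), `n`.
#' @export
fit_movement_kernel <- function(lengths, turns, min_steps = 30) {
  turns <- turns[!is.na(turns)]
  lengths <- lengths[!is.na(lengths)]
  if (length(turns) < min_steps || length(lengths) < min_steps)
    stop("insufficient steps to fit the movement kernel")
  lengths <- pmax(lengths, 1)
  if (sd(lengths) == 0)
    stop("degenerate step lengths (all identical)")
  gf <- fitdistrplus::fitdist(lengths, "gamma", method = "mle",
                              start = list(shape = (mean(lengths) /
                                                      sd(lengths))^2,
                                           rate = mean(lengths) /
                                             sd(lengths)^2))
  vm <- fit_vonmises(turns)
  structure(list(shape = unname(gf$estimate["shape"]),
                 scale = 1 / unname(gf$estimate["rate"]),
                 mu = vm$mu, kappa = vm$kappa,
                 n = length(lengths)),
            class = "movement_kernel")
}

#' @export
print.movement_kernel <- function(x, ...) {
  cat(sprintf(
    "movement_kernel: gamma(shape %.3f, scale %.1f m), vonMises(mu %.3f, kappa %.3f), n = %d\n",
    x$shape, x$scale, x$mu, x$kappa, x$n))
  invisible(x)
}

#' Von Mises maximum likelihood
#' @param theta angles, radians.
#' @return list with `mu` (in `(-pi, pi]`) and `kappa`.
#' @export
fit_vonmises <- function(theta) {
  C <- mean(cos(theta)); S <- mean(sin(theta))
  mu <- atan2(S, C)
  rbar <- sqrt(C^2 + S^2)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  cap <- 5e4  # besselI overflows beyond this; use A1(k) ~ 1 - 1/(2k)
  kappa <- if (rbar < 1e-8) 0
  else if (rbar >= a1(cap)) 1 / (2 * (1 - rbar))
  else uniroot(function(k) a1(k) - rbar, c(1e-8, cap), tol = 1e-10)$root
  list(mu = wrap_angle(mu), kappa = kappa)
}

#' Von Mises random deviates (Best-Fisher rejection sampler)
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 1e-8) return(wrap_angle(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.6))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[acc] - 0.5) *
               acos(pmin(pmax(f[acc], -1), 1)))
  }
  wrap_angle(out[seq_len(n)] + mu)
}

#' Generate a stratum of matched random steps
#'
#' `J` available steps sharing the used step's start point, with lengths
#' drawn from the kernel's gamma distribution and absolute bearings equal to
#' `previous_bearing` plus a von Mises turn.  Endpoints falling off the
#' raster extent are rejected and resampled (up to `max_attempts` each);
#' the stratum is flagged if the limit is hit for more than `J/2`
#' candidates.
#'
#' @param used data.frame row with `x1, y1, x2, y2, length, turn`.
#' @param previous_bearing absolute bearing of the preceding step, radians
#'   (`NA` draws a uniform bearing).
#' @param kernel a `movement_kernel`.
#' @param J number of available steps.
#' @param extent optional [grid_raster] whose extent bounds endpoints.
#' @param max_attempts resampling limit per candidate.
#' @return data.frame of `J + 1` steps (`case` = 1 for the used step) with
#'   columns `case, x1, y1, x2, y2, sl, ta` and attribute `"flagged"`.
#' @export
generate_random_steps <- function(used, previous_bearing, kernel, J = 50,
                                  extent = NULL, max_attempts = 100) {
  if (is.na(previous_bearing)) previous_bearing <- runif(1, -pi, pi)
  lens <- rgamma(J, shape = kernel$shape, scale = kernel$scale)
  turns <- rvonmises(J, kernel$mu, kernel$kappa)
  xs <- used$x1 + lens * cos(previous_bearing + turns)
  ys <- used$y1 + lens * sin(previous_bearing + turns)
  failed <- 0L
  if (!is.null(extent)) {
    inb <- function(x, y) x >= extent$xmin & x <= raster_xmax(extent) &
      y >= extent$ymin & y <= raster_ymax(extent)
    for (j in which(!inb(xs, ys))) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        l <- rgamma(1, shape = kernel$shape, scale = kernel$scale)
        t <- rvonmises(1, kernel$mu, kernel$kappa)
        x2 <- used$x1 + l * cos(previous_bearing + t)
        y2 <- used$y1 + l * sin(previous_bearing + t)
        if (inb(x2, y2)) {
          xs[j] <- x2; ys[j] <- y2; lens[j] <- l; turns[j] <- t
          ok <- TRUE
          break
        }
      }
      if (!ok) failed <- failed + 1L
    }
    if (failed > J / 2)
      stop("resampling limit exhausted for more than half the candidates")
  }
  out <- data.frame(
    case = c(1L, rep(0L, J)),
    x1 = used$x1, y1 = used$y1,
    x2 = c(used$x2, xs), y2 = c(used$y2, ys),
    sl = c(used$length, lens),
    ta = c(used$turn, turns))
  attr(out, "flagged") <- failed > 0L
  out
}
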