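test_that("variance estimator hits the lower bound on a noiseless line", {
  x <- seq(0, 5000, by = 100)
  y <- rep(0, length(x))
  est <- estimate_bm_variance(x, y, seq_along(x) - 1, location_error = 1)
  expect_lt(est$sigma2m, 0.02)  # effectively the lower search bound
})

test_that("variance estimate maximizes its own leave-one-out likelihood", {
  set.seed(7)
  n <- 300
  x <- cumsum(rnorm(n, 0, sqrt(1500))) + rnorm(n, 0, 20)
  y <- cumsum(rnorm(n, 0, sqrt(1500))) + rnorm(n, 0, 20)
  est <- estimate_bm_variance(x, y, seq_len(n) - 1, 20)
  # independent grid evaluation of the same objective
  ll <- function(s2) {
    idx <- seq(2, n - 1, by = 2); a <- idx - 1; b <- idx + 1
    al <- 0.5; Tt <- 2
    v <- Tt * al * (1 - al) * s2 + ((1 - al)^2 + al^2 + 1) * 400
    mx <- (x[a] + x[b]) / 2; my <- (y[a] + y[b]) / 2
    d2 <- (x[idx] - mx)^2 + (y[idx] - my)^2
    -sum(log(v) + d2 / (2 * v))
  }
  expect_gte(ll(est$sigma2m), ll(est$sigma2m * 0.5))
  expect_gte(ll(est$sigma2m), ll(est$sigma2m * 2))
})

test_that("diffusion recovery from noisy Brownian tracks is unbiased", {
  r <- experiment_bbmm_recovery(n_rep = 5, sigma2m = 2000, n_fixes = 500,
                                seed = 21)
  expect_lt(mean(r$rel_err), 0.2)
})

test_that("UD mass is conserved and concentrates at coincident fixes", {
  ud <- compute_bbmm_ud(c(1000, 1000), c(500, 500), c(0, 1),
                        sigma2m = 1, location_error = 5, res = 2)
  expect_equal(sum(ud$values), 1, tolerance = 1e-6)
  # >= 99% of mass within 3 location-error sd of the point
  yc <- ud$ymin + (seq_len(nrow(ud$values)) - 0.5) * ud$res
  xc <- ud$xmin + (seq_len(ncol(ud$values)) - 0.5) * ud$res
  d <- sqrt(outer((yc - 500)^2, (xc - 1000)^2, "+"))
  expect_gte(sum(ud$values[d <= 15]), 0.99)
})

test_that("quadrature matches a Monte-Carlo sample of a single bridge", {
  x <- c(0, 400); y <- c(0, 150); th <- c(0, 1)
  s2 <- 3000; derr <- 20
  ud <- compute_bbmm_ud(x, y, th, s2, derr, res = 10, quad_tol = 1e-4)
  set.seed(99)
  nmc <- 1e6
  al <- runif(nmc)
  sd_al <- sqrt(al * (1 - al) * s2 + ((1 - al)^2 + al^2) * derr^2)
  px <- (1 - al) * x[1] + al * x[2] + rnorm(nmc, 0, sd_al)
  py <- (1 - al) * y[1] + al * y[2] + rnorm(nmc, 0, sd_al)
  # compare on 60 m aggregation blocks so Monte-Carlo binomial noise
  # (~ sqrt(m / n)) stays well under the quadrature tolerance
  block <- 6L
  nbr <- ceiling(nrow(ud$values) / block)
  nbc <- ceiling(ncol(ud$values) / block)
  bin_of <- function(r, c) (ceiling(c / block) - 1) * nbr +
    ceiling(r / block)
  idx <- cell_of(ud, px, py)
  ok <- !is.na(idx$row)
  mc <- tabulate(bin_of(idx$row[ok], idx$col[ok]), nbr * nbc) / nmc
  rows <- rep(seq_len(nrow(ud$values)), ncol(ud$values))
  cols <- rep(seq_len(ncol(ud$values)), each = nrow(ud$values))
  qd <- as.numeric(rowsum(as.numeric(ud$values), bin_of(rows, cols)))
  expect_lt(0.5 * sum(abs(mc - qd)), 0.01)
})

test_that("isopleths match the Gaussian closed form, nest, and translate", {
  # isotropic Gaussian UD with sd 300 m on a 30 m grid
  sd_g <- 300
  xs <- seq(-1500, 1500, by = 30)
  g <- outer(dnorm(xs, 0, sd_g), dnorm(xs, 0, sd_g))
  ud <- grid_raster(g / sum(g), xmin = -1515, ymin = -1515, res = 30)
  hr <- extract_isopleth(ud, 0.95)
  area_expected <- pi * sd_g^2 * qchisq(0.95, 2)
  expect_equal(hr_area(hr), area_expected, tolerance = 0.1)
  expect_gte(hr$mass, 0.95)
  hr50 <- extract_isopleth(ud, 0.5)
  expect_true(all(hr$mask[hr50$mask]))  # nesting
  # full-mass isopleth covers all nonzero cells
  hr100 <- extract_isopleth(ud, 1)
  expect_equal(sum(hr100$mask), sum(ud$values > 0))
  # translation equivariance
  ud2 <- grid_raster(ud$values, xmin = ud$xmin + 900, ymin = ud$ymin - 600,
                     res = 30)
  hr2 <- extract_isopleth(ud2, 0.95)
  expect_identical(hr2$mask, hr$mask)
  expect_true(hr_contains(hr, 0, 0))
  expect_true(hr_contains(hr2, 900, -600))
})

test_that("single-cell UD gives a one-cell home range", {
  v <- matrix(0, 5, 5); v[3, 3] <- 1
  hr <- extract_isopleth(grid_raster(v, res = 30), 0.95)
  expect_equal(sum(hr$mask), 1L)
  expect_true(hr_contains(hr, 75, 75))
  expect_equal(hr_distance_outside(hr, 75, 75), 0)
  # 2 cells east of the cell edge
  expect_equal(hr_distance_outside(hr, 150, 75), 60, tolerance = 1e-9)
})
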