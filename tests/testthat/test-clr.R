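toy_design <- function() {
  # three strata, one covariate; used step listed first in each stratum
  data.frame(
    stratum = rep(1:3, each = 3),
    case = rep(c(1L, 0L, 0L), 3),
    x = c(1.0, 0.2, -0.5,
          -0.3, 0.8, 0.1,
          0.7, -0.2, 0.4))
}

test_that("the Newton fit matches a fine grid search on a printed toy", {
  d <- rbind(toy_design(), within(toy_design(), stratum <- stratum + 3),
             within(toy_design(), stratum <- stratum + 6),
             within(toy_design(), stratum <- stratum + 9))
  beta_grid <- oracle_clr_grid(d$x, d$stratum, d$case)
  fit <- clr_fit(matrix(d$x, dimnames = list(NULL, "x")), d$stratum,
                 d$case)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta["x"]), beta_grid, tolerance = 1e-4)
  # and the likelihood at the fit is no worse than on the grid
  expect_gte(oracle_clr_loglik(fit$beta["x"], d$x, d$stratum, d$case),
             oracle_clr_loglik(beta_grid, d$x, d$stratum, d$case) - 1e-8)
})

test_that("estimates and standard errors match survival::clogit", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  rasters <- list(
    c1 = simulate_covariate_raster(120, 30, 8, seed = 51),
    c2 = simulate_covariate_raster(120, 30, 8, seed = 52))
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  d <- simulate_ssf_steps(rasters, c(c1 = -0.5, c2 = 0.3), kern,
                          n_strata = 300, J = 20, seed = 53)
  fit <- clr_fit(as.matrix(d[c("c1", "c2")]), d$stratum, d$case)
  cf <- survival::clogit(case ~ c1 + c2 + strata(stratum), data = d)
  expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-7)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cf)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, unname(logLik(cf)), tolerance = 1e-7,
               ignore_attr = TRUE)
})

test_that("conditional likelihood ignores stratum-constant shifts and", {
  # duplicated available steps
  rasters <- list(c1 = simulate_covariate_raster(100, 30, 6, seed = 61))
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  d <- simulate_ssf_steps(rasters, c(c1 = -0.4), kern, n_strata = 150,
                          J = 10, seed = 62)
  f0 <- clr_fit(matrix(d$c1, dimnames = list(NULL, "c1")), d$stratum,
                d$case)
  d2 <- d
  d2$c1 <- d2$c1 + 7.7 * d2$stratum
  f1 <- clr_fit(matrix(d2$c1, dimnames = list(NULL, "c1")), d2$stratum,
                d2$case)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-8)
  # appending an exact duplicate of the whole candidate set as available
  # steps doubles every stratum's denominator and leaves the fit unchanged
  dup <- d
  dup$case <- 0L
  d3 <- rbind(d, dup)
  f2 <- clr_fit(matrix(d3$c1, dimnames = list(NULL, "c1")), d3$stratum,
                d3$case)
  expect_equal(f2$beta, f0$beta, tolerance = 1e-6)
})

test_that("degenerate designs are flagged rather than fitted", {
  d <- toy_design()
  d <- rbind(d, within(d, stratum <- stratum + 3),
             within(d, stratum <- stratum + 6),
             within(d, stratum <- stratum + 9))
  X <- cbind(x = d$x, flat = rep(c(2, 2, 2), 12)[seq_len(nrow(d))])
  fit <- clr_fit(X, d$stratum, d$case)
  expect_true("flat" %in% fit$flags$no_information)
  expect_true(is.na(fit$beta["flat"]))
  expect_false(is.na(fit$beta["x"]))
  # NA covariates drop whole strata, with a count
  X2 <- cbind(x = d$x)
  X2[2, 1] <- NA
  fit2 <- clr_fit(X2, d$stratum, d$case)
  expect_equal(fit2$flags$dropped_strata, 1L)
  expect_equal(fit2$n_strata, 11L)
})

test_that("AICc follows its closed form and ordering invariance", {
  fit <- list(loglik = -50, k = 2)
  expect_equal(aicc(fit, 100), 104 + 12 / 97)
  expect_equal(aicc(list(loglik = -50, k = 0), 100), 100)
  # AICc > AIC for any finite n
  for (n in c(10, 50, 1000))
    expect_gt(aicc(fit, n), -2 * -50 + 2 * 2)
  expect_error(aicc(fit, 3), "exceed")
  # ordering is invariant to a constant shift of all log-likelihoods
  lls <- c(-100, -98.5, -103)
  a1 <- vapply(lls, function(l) aicc(list(loglik = l, k = 3), 50), 0)
  a2 <- vapply(lls + 7, function(l) aicc(list(loglik = l, k = 3), 50), 0)
  expect_equal(order(a1), order(a2))
})

test_that("Akaike weights have their closed forms", {
  expect_equal(akaike_weights(rep(10, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(w[1], exp(0) / (exp(0) + exp(-1)), tolerance = 1e-12)
  expect_equal(w[2], exp(-1) / (exp(0) + exp(-1)), tolerance = 1e-12)
  set.seed(1)
  expect_equal(sum(akaike_weights(runif(9, 200, 240))), 1,
               tolerance = 1e-12)
})

test_that("variance inflation factors behave on known designs", {
  set.seed(33)
  n <- 500
  x1 <- rnorm(n)
  # orthogonal design: all VIF close to 1
  X <- cbind(a = x1, b = rnorm(n), c = rnorm(n))
  expect_true(all(abs(vif(X) - 1) < 0.05))
  # a duplicated column is perfectly collinear
  v2 <- vif(cbind(a = x1, b = x1))
  expect_true(all(is.infinite(v2)))
  expect_equal(attr(v2, "flagged"), c("a", "b"))
  # R^2 = 0.5 gives VIF about 2
  x2 <- x1 + rnorm(n, 0, sd = sd(x1))
  v3 <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v3["b"]), 2, tolerance = 0.25)
})
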