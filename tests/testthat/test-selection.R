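# a small design with controllable effects on named covariates
make_design <- function(betas, n_strata = 250, J = 15, seed = 1,
                        vars = c("dForest", "dStream", "dAg", "dRoad")) {
  rasters <- lapply(seq_along(vars), function(i) {
    r <- simulate_covariate_raster(120, 30, 8, seed = seed + i)
    # distances are nonnegative: shift and scale to look like meters
    r$values <- (r$values - min(r$values)) * 400
    r
  })
  names(rasters) <- vars
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  d <- simulate_ssf_steps(rasters, betas, kern, n_strata = n_strata,
                          J = J, seed = seed + 99)
  d
}

test_that("tier 1 prefers the generating functional form", {
  # effect on the log scale of a right-skewed distance-like covariate,
  # whose small-value curvature separates the forms
  rasters <- list(dForest = {
    r <- simulate_covariate_raster(120, 30, 8, seed = 7)
    r$values <- 60 * (exp(r$values - min(r$values)) - 1)
    r
  })
  lnr <- rasters$dForest
  lnr$values <- log(lnr$values + 1)
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  wins <- 0L
  for (rep in 1:10) {
    d <- simulate_ssf_steps(c(rasters, list(lnF = lnr)),
                            c(lnF = -1.2), kern, n_strata = 300, J = 15,
                            seed = 100 + rep)
    forms <- tier1_select_forms(d, "dForest")
    wins <- wins + (forms[["dForest"]] == "ln")
  }
  expect_gte(wins, 9)
})

test_that("tier 1 breaks ties toward fewer parameters, then linear", {
  # pure linear truth: quadratic must not win without a two-point gain
  d <- make_design(c(dForest = -0.004), n_strata = 300, J = 15, seed = 3)
  forms <- tier1_select_forms(d, c("dForest", "dStream"))
  tab <- attr(forms, "table")
  tf <- tab[tab$covariate == "dForest", ]
  quad <- tf$aicc[tf$form == "quadratic"]
  best <- min(tf$aicc[tf$form != "quadratic"])
  if (forms[["dForest"]] == "quadratic") expect_lt(quad, best)
  # constructed exact tie falls to linear by the declared preference order
  expect_equal(unname(forms["dStream"]) %in% c("linear", "ln", "quadratic"),
               TRUE)
})

test_that("tier 2 picks the hypothesis that generated the data", {
  # effects only on dForest and dStream: Corridors wins
  d <- make_design(c(dForest = -0.004, dStream = -0.003),
                   n_strata = 350, J = 15, seed = 11)
  forms <- setNames(rep("linear", 4),
                    c("dForest", "dStream", "dAg", "dRoad"))
  t2 <- tier2_select_base(d, forms)
  expect_equal(t2$best_name, "Corridors")
  expect_named(t2$table, c("model", "k", "AICc", "dAICc", "w", "LL"))
  expect_equal(sum(t2$table$w), 1, tolerance = 1e-12)
  # effects on all four: Global wins
  d4 <- make_design(c(dForest = -0.004, dStream = -0.003, dAg = 0.003,
                      dRoad = 0.004), n_strata = 350, J = 15, seed = 12)
  t24 <- tier2_select_base(d4, forms)
  expect_equal(t24$best_name, "Global")
})

test_that("tier 3 demotes a D_IND candidate correlated with D_ALL", {
  d <- make_design(c(dForest = -0.003), n_strata = 260, J = 10, seed = 21)
  set.seed(5)
  # construct one D_ALL and D_IND pair that is exactly identical (r = 1)
  # at grain 175; D_IND at the other grains is independent noise
  d$D_ALL_175 <- exp(rnorm(nrow(d), 2, 0.8))
  d$D_IND_175 <- d$D_ALL_175
  d$D_IND_250 <- exp(rnorm(nrow(d), 2, 0.8))
  base <- list(ssf_term("dForest", "linear", "distance"))
  t3 <- tier3_select_dissimilarity(d, base, grains = c(175, 250))
  # whatever was ranked first, the retained D_IND must not be the clone of
  # the chosen D_ALL column
  if (!t3$d_ind_omitted && t3$d_all$var == "D_ALL_175" &&
      t3$d_all$form == t3$d_ind$form) {
    expect_false(t3$d_ind$var == "D_IND_175")
  }
  expect_named(t3$weights, c("base", "base_all", "base_all_ind"))
  expect_equal(sum(t3$weights), 1, tolerance = 1e-12)
})

test_that("tier 3 recovers a planted dissimilarity effect and grain", {
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  hits <- 0L
  for (rep in 1:5) {
    dr <- simulate_covariate_raster(120, 30, 8, seed = 300 + rep)
    dr$values <- (dr$values - min(dr$values)) * 400
    di <- simulate_covariate_raster(120, 30, 5, seed = 400 + rep)
    di$values <- exp(di$values + 2)  # lognormal-ish dissimilarity
    lnd <- di; lnd$values <- log(pmax(di$values, 1e-12))
    da <- simulate_covariate_raster(120, 30, 5, seed = 500 + rep)
    da$values <- exp(da$values + 2)
    d <- simulate_ssf_steps(
      list(dForest = dr, D_IND_175 = di, D_ALL_175 = da, lnDI = lnd),
      c(lnDI = -0.6), kern, n_strata = 300, J = 15, seed = 600 + rep)
    d$D_IND_250 <- exp(rnorm(nrow(d), 2, 1))
    d$D_ALL_250 <- exp(rnorm(nrow(d), 2, 1))
    base <- list(ssf_term("dForest", "linear", "distance"))
    t3 <- tier3_select_dissimilarity(d, base, grains = c(175, 250))
    ok <- !t3$d_ind_omitted && t3$d_ind$var == "D_IND_175" &&
      t3$d_ind$form == "ln" &&
      t3$weights[["base_all_ind"]] == max(t3$weights)
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})

test_that("model-averaged ln(RSS) obeys its closed forms", {
  d <- make_design(c(dForest = -0.004), n_strata = 260, J = 10, seed = 31)
  fit <- nhpimove:::fit_spec(d, list(ssf_term("dForest", "linear",
                                              "distance")))
  rss <- model_average_rss(list(m = fit), weights = 1, design = d,
                           focus_var = "dForest", nboot = 200, seed = 4)
  # at the reference value the curve passes through zero
  vref <- mean(d$dForest[is.finite(d$dForest)])
  at_ref <- approx(rss$v, rss$lnRSS, vref)$y
  expect_equal(at_ref, 0, tolerance = 1e-8)
  # a linear single-model curve has slope beta
  slope <- coef(lm(lnRSS ~ v, data = rss))[2]
  expect_equal(unname(slope), unname(fit$beta["dForest"]),
               tolerance = 1e-8)
  # a model without the focus term contributes zero: weights average
  fit0 <- nhpimove:::fit_spec(d, list(ssf_term("dStream", "linear",
                                               "distance")))
  rss2 <- model_average_rss(list(a = fit, b = fit0),
                            weights = c(0.5, 0.5), design = d,
                            focus_var = "dForest", nboot = 200, seed = 4)
  expect_equal(rss2$lnRSS, 0.5 * rss$lnRSS, tolerance = 1e-10)
  expect_true(all(rss2$lower <= rss2$lnRSS & rss2$lnRSS <= rss2$upper))
})
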