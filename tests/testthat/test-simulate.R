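test_that("trajectories are deterministic and stay home without events", {
  cfg <- track_config(hr_center = c(1e4, 1e4), n_fixes = 24 * 35,
                      events = list(), seed = 8)
  t1 <- simulate_track(cfg)
  t2 <- simulate_track(cfg)
  expect_identical(t1$relocs, t2$relocs)
  # mean-reverting residency: excursions beyond 4 sigma are rare
  d <- sqrt((t1$relocs$x - 1e4)^2 + (t1$relocs$y - 1e4)^2)
  expect_lt(mean(d > 4 * 300), 0.01)
  expect_length(t1$truth$planted_events, 0)
})

test_that("planted dispersals settle at the planted distance", {
  cfg <- track_config(hr_center = c(5e4, 5e4), n_fixes = 24 * 40,
                      events = list(list(type = "dispersal",
                                         start_fix = 32 * 24,
                                         distance = 5000,
                                         n_search = 24)),
                      seed = 5)
  tr <- simulate_track(cfg)
  ev <- tr$truth$planted_events[[1]]
  expect_equal(ev$type, "dispersal")
  late <- tr$relocs[(ev$end_fix + 1):nrow(tr$relocs), ]
  ctr <- c(mean(late$x), mean(late$y))
  d_new <- sqrt(sum((ctr - c(5e4, 5e4))^2))
  expect_gt(d_new, 2000)  # spatially disjoint from the natal range
  # post-settlement fixes cluster around the settlement site
  spread <- sqrt(max((late$x - ctr[1])^2 + (late$y - ctr[2])^2))
  expect_lt(spread, 1500)
})

test_that("planted excursions leave beyond the resident range and return", {
  cfg <- track_config(hr_center = c(0, 0), n_fixes = 24 * 38,
                      events = list(list(type = "excursion",
                                         start_fix = 33 * 24,
                                         n_loiter = 10)),
                      seed = 13)
  tr <- simulate_track(cfg)
  ev <- tr$truth$planted_events[[1]]
  rng <- ev$start_fix:ev$end_fix
  d <- sqrt(tr$relocs$x[rng]^2 + tr$relocs$y[rng]^2)
  r95 <- tr$truth$r95
  expect_gte(max(d), r95 + 500)             # far outside
  expect_gte(sum(d > r95 + 500), 2)         # the far rule
  runs <- rle(d > r95)
  expect_gte(max(runs$lengths[runs$values]), 4)  # the consecutive rule
  # afterwards the animal is back inside the resident range
  after <- min(ev$end_fix + 5, nrow(tr$relocs))
  d_after <- sqrt(tr$relocs$x[after]^2 + tr$relocs$y[after]^2)
  expect_lt(d_after, r95)
})

test_that("poor fixes are planted at the configured rate", {
  cfg <- track_config(n_fixes = 24 * 35, poor_fix_frac = 0.05, seed = 77)
  tr <- simulate_track(cfg)
  frac <- length(tr$truth$poor_fix_idx) / nrow(tr$relocs)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
  thr <- ifelse(tr$relocs$fix_dim == "2D", 5, 6)
  expect_true(all(tr$relocs$hdop[tr$truth$poor_fix_idx] >=
                    thr[tr$truth$poor_fix_idx]))
})

test_that("step simulation is uniform under a null model", {
  rs <- list(z = simulate_covariate_raster(80, 30, 6, seed = 41))
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  d <- simulate_ssf_steps(rs, c(z = 0), kern, n_strata = 2000, J = 4,
                          seed = 42)
  used_pos <- unlist(lapply(split(seq_len(nrow(d)), d$stratum),
                            function(i) which(d$case[i] == 1)))
  p <- chisq.test(table(factor(used_pos, levels = 1:5)))$p.value
  expect_gt(p, 0.001)
  expect_identical(d, simulate_ssf_steps(rs, c(z = 0), kern,
                                         n_strata = 2000, J = 4,
                                         seed = 42))
})

test_that("a binary covariate reproduces the logistic choice probability", {
  rs <- list(z = grid_raster(matrix(rep(c(0, 1), each = 40), 80, 80),
                             res = 30))
  kern <- list(shape = 2, scale = 200, mu = 0, kappa = 0.01)
  d <- simulate_ssf_steps(rs, c(z = 1), kern, n_strata = 4000, J = 1,
                          seed = 2)
  w <- vapply(split(seq_len(nrow(d)), d$stratum), function(i) {
    z <- d$z[i]
    if (length(unique(z)) == 2) z[d$case[i] == 1] else NA_real_
  }, 0)
  w <- w[!is.na(w)]
  p_hat <- mean(w)
  p_true <- exp(1) / (1 + exp(1))
  expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) /
                                            length(w)))
})

test_that("simulated selection is recovered by the conditional fit", {
  rasters <- list(
    a = simulate_covariate_raster(120, 30, 8, seed = 71),
    b = simulate_covariate_raster(120, 30, 8, seed = 72))
  kern <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  d <- simulate_ssf_steps(rasters, c(a = -0.5, b = 0.3), kern,
                          n_strata = 500, J = 50, seed = 73)
  fit <- clr_fit(as.matrix(d[c("a", "b")]), d$stratum, d$case)
  z <- (fit$beta[c("a", "b")] - c(-0.5, 0.3)) / fit$se[c("a", "b")]
  expect_true(all(abs(z) < 3))
  expect_lt(fit$beta[["a"]], 0)
  expect_gt(fit$beta[["b"]], 0)
})

test_that("truth ledgers serialize to JSON", {
  cfg <- track_config(n_fixes = 24 * 35, seed = 3,
                      events = list(list(type = "excursion",
                                         start_fix = 32 * 24)))
  tr <- simulate_track(cfg)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth_json(tr$truth, p)
  back <- jsonlite::read_json(p)
  expect_equal(length(back$planted_events),
               length(tr$truth$planted_events))
  expect_equal(back$planted_events[[1]]$type, "excursion")
})
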