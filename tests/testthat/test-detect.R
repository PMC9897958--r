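# a resident cluster plus an explicit far loop appended at given fixes
loop_track <- function(n_days = 36, out_at = 24 * 34, n_out = 5,
                       far = 3000, seed = 2) {
  tr <- make_fixture_track(n_days * 24, spread = 250, seed = seed)
  out <- out_at:(out_at + n_out - 1)
  tr$x[out] <- far + c(0, 150, 300, 150, 0, 100, 200)[seq_len(n_out)]
  tr$y[out] <- seq(0, 100, length.out = n_out)
  tr
}

test_that("a trajectory that never leaves its range yields no events", {
  cfg <- track_config(hr_center = c(0, 0), n_fixes = 24 * 36,
                      events = list(), seed = 4)
  tr <- simulate_track(cfg)
  scr <- screen_relocations(tr$relocs)
  expect_length(detect_ehrms(scr), 0)
})

test_that("the consecutive-fix rule rejects a three-fix exit", {
  tr3 <- screen_relocations(loop_track(n_out = 3))
  expect_length(detect_ehrms(tr3), 0)
  # five consecutive far fixes do qualify, as one excursion
  tr5 <- screen_relocations(loop_track(n_out = 5))
  ev <- detect_ehrms(tr5)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "excursion")
  # the detected range brackets the planted fixes (within one fix)
  expect_lte(abs(ev[[1]]$start_idx - 24 * 34), 1)
  expect_lte(abs(ev[[1]]$end_idx - (24 * 34 + 4)), 1)
  expect_gte(ev[[1]]$max_dist_m, 0)
})

test_that("detected events satisfy both defining rules", {
  cfg <- track_config(hr_center = c(0, 0), n_fixes = 24 * 40,
                      events = list(list(type = "excursion",
                                         start_fix = 33 * 24,
                                         n_loiter = 10)), seed = 19)
  scr <- screen_relocations(simulate_track(cfg)$relocs)
  evs <- detect_ehrms(scr)
  expect_length(evs, 1)
  e <- evs[[1]]
  rng <- e$start_idx:e$end_idx
  outside <- !hr_contains(e$pre_hr, scr$x[rng], scr$y[rng])
  far <- hr_distance_outside(e$pre_hr, scr$x[rng], scr$y[rng]) > 500
  expect_gte(sum(far), 2)
  runs <- rle(outside)
  expect_gte(max(runs$lengths[runs$values]), 4)
})

test_that("dispersals classify by settlement and truncation is unresolved", {
  cfg <- track_config(hr_center = c(5e4, 5e4), n_fixes = 24 * 44,
                      events = list(list(type = "dispersal",
                                         start_fix = 33 * 24,
                                         distance = 5000,
                                         n_search = 24)), seed = 23)
  scr <- screen_relocations(simulate_track(cfg)$relocs)
  evs <- detect_ehrms(scr)
  expect_gte(length(evs), 1)
  expect_equal(evs[[1]]$type, "dispersal")
  expect_gt(evs[[1]]$max_dist_m, 2000)
  # collar drop mid-movement: the track ends before any settlement window
  cfg2 <- track_config(hr_center = c(5e4, 5e4), n_fixes = 24 * 37,
                       events = list(list(type = "dispersal",
                                          start_fix = 34 * 24,
                                          distance = 5000,
                                          n_search = 48)), seed = 29)
  scr2 <- screen_relocations(simulate_track(cfg2)$relocs)
  evs2 <- detect_ehrms(scr2)
  types <- vapply(evs2, function(e) e$type, "")
  expect_true(all(types == "unresolved"))
})

test_that("stricter thresholds never yield more events", {
  scr <- screen_relocations(loop_track(n_out = 6, seed = 31))
  n_base <- length(detect_ehrms(scr))
  n_far <- length(detect_ehrms(scr, dist_threshold_m = 2000))
  n_cons <- length(detect_ehrms(scr, min_consecutive = 8))
  expect_lte(n_far, n_base)
  expect_lte(n_cons, n_base)
})

test_that("event summaries compute the documented statistics", {
  ev <- function(type, start, end, dist, season = "spring") {
    structure(list(animal_id = "A", type = type, season = season,
                   start_idx = start, end_idx = end, max_dist_m = dist),
              class = "ehrm_event")
  }
  s1 <- summarize_ehrms(list(ev("excursion", 10, 18, 900)))
  row <- s1$stats[s1$stats$type == "excursion", ]
  expect_equal(row$steps_mean, 8)
  expect_equal(row$duration_mean_h, 8)
  s2 <- summarize_ehrms(list(ev("excursion", 10, 14, 700),
                             ev("excursion", 40, 52, 1500, "summer")))
  row2 <- s2$stats
  expect_equal(row2$steps_mean, 8)
  expect_equal(row2$steps_se, 4)
  expect_equal(row2$steps_median, 8)
  expect_equal(c(row2$steps_min, row2$steps_max), c(4, 12))
  expect_equal(as.vector(s2$seasons[, "excursion"]), c(1, 1))
  expect_error(summarize_ehrms(list()), "no resolved")
})
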