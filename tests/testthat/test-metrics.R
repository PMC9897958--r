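test_that("uniform and checkerboard windows give the closed forms", {
  ls <- grid_raster(matrix(3L, 30, 30), res = 30)
  m <- moving_window_metrics(ls, 175, cells = data.frame(row = 15,
                                                         col = 15))
  expect_equal(unname(m[1, "for"]), 100)
  expect_equal(unname(m[1, "ED"]), 0)
  # the aggregation maximum assumes square packing, so a circular window
  # of one class sits just below 100; a square (fully truncated) window
  # attains it exactly
  expect_gt(unname(m[1, "AI"]), 99)
  sq <- moving_window_metrics(ls, 5000, cells = data.frame(row = 15,
                                                           col = 15))
  expect_equal(unname(sq[1, "AI"]), 100)
  expect_equal(unname(sq[1, "PRD"]), 1e6 / (900 * 900))
  expect_true(is.na(m[1, "IJI"]))  # a single class present

  cb <- grid_raster(outer(1:30, 1:30, function(i, j)
    ifelse((i + j) %% 2 == 0, 3L, 4L)), res = 30)
  mcb <- moving_window_metrics(cb, 175, cells = data.frame(row = 15,
                                                           col = 15))
  expect_equal(unname(mcb[1, "AI"]), 0)  # no like adjacencies
  expect_true(is.na(mcb[1, "IJI"]))      # two classes only
})

test_that("window metrics equal the enumeration oracle on random rasters", {
  set.seed(31)
  for (rep in 1:3) {
    vals <- matrix(sample.int(7L, 50 * 50, replace = TRUE,
                              prob = c(0.05, 0.1, 0.3, 0.3, 0.15, 0.07,
                                       0.03)), 50, 50)
    ls <- grid_raster(vals, res = 30)
    cells <- data.frame(row = sample(50, 12), col = sample(50, 12))
    cells <- rbind(cells, data.frame(row = c(1, 50), col = c(1, 27)))
    for (radius in c(175, 250)) {
      got <- moving_window_metrics(ls, radius, cells = cells)
      for (k in seq_len(nrow(cells))) {
        want <- oracle_window_metrics(vals, cells$row[k], cells$col[k],
                                      radius, 30)
        expect_equal(unname(got[k, ]), unname(want), tolerance = 1e-12)
      }
    }
  }
})

test_that("metric bands are invariant to group-preserving class relabels", {
  set.seed(8)
  vals <- matrix(sample.int(7L, 40 * 40, replace = TRUE), 40, 40)
  ls <- grid_raster(vals, res = 30)
  cells <- data.frame(row = c(5, 20, 36), col = c(7, 21, 33))
  m1 <- moving_window_metrics(ls, 250, cells = cells)
  # swap codes 1 <-> 2 (both ungrouped) and adapt the group map
  vals2 <- vals
  vals2[vals == 1L] <- 2L
  vals2[vals == 2L] <- 1L
  m2 <- moving_window_metrics(grid_raster(vals2, res = 30), 250,
                              cells = cells)
  expect_equal(m1, m2)
})

test_that("full-raster metrics agree with the per-cell interface", {
  set.seed(12)
  vals <- matrix(sample.int(7L, 25 * 25, replace = TRUE), 25, 25)
  ls <- grid_raster(vals, res = 30)
  bands <- moving_window_metrics(ls, 175)
  cells <- expand.grid(row = c(1, 13, 25), col = c(1, 13, 25))
  m <- moving_window_metrics(ls, 175, cells = cells)
  for (b in seq_along(bands))
    expect_equal(bands[[b]]$values[cbind(cells$row, cells$col)],
                 unname(m[, b]))
})

test_that("distance rasters are exact against brute force", {
  set.seed(5)
  vals <- matrix(sample(c(3L, 4L), 100, replace = TRUE, prob = c(0.1, 0.9)),
                 10, 10)
  vals[1, 1] <- 3L  # guarantee a target
  ls <- grid_raster(vals, res = 30)
  d <- distance_raster(ls, target_class = 3L)
  expect_equal(d$values, oracle_distance_raster(vals, 3L, 30))
  expect_true(all(d$values[vals == 3L] == 0))
  # unit offset: a lone target cell's east neighbour is one cell away
  v1 <- matrix(4L, 10, 10); v1[5, 5] <- 3L
  d1 <- distance_raster(grid_raster(v1, res = 30), target_class = 3L)
  expect_equal(d1$values[5, 6], 30)
  expect_error(distance_raster(grid_raster(v1, res = 30),
                               target_class = 7L), "empty target")
})

test_that("line-feature distances use densified segments", {
  ls <- grid_raster(matrix(1L, 20, 20), res = 30)
  # a vertical line at x = 300
  d <- distance_raster(ls, lines = list(cbind(c(300, 300), c(0, 600))))
  cc <- cell_center(ls, 10, 15)  # x = 435
  expect_lt(abs(raster_extract(d, cc$x, cc$y) - 135), 5.1)
  on_line <- cell_center(ls, 5, 10)  # x = 285, 15 m from the line
  expect_lte(raster_extract(d, on_line$x, on_line$y), 15 + 5)
})

test_that("edge density and aggregation respond oppositely to", {
  # fragmentation at fixed composition (two-class landscapes)
  blocky <- grid_raster(cbind(matrix(3L, 20, 10), matrix(4L, 20, 10)),
                        res = 30)
  checker <- grid_raster(outer(1:20, 1:20, function(i, j)
    ifelse((i + j) %% 2 == 0, 3L, 4L)), res = 30)
  ctr <- data.frame(row = 10, col = 10)
  mb <- moving_window_metrics(blocky, 250, cells = ctr)
  mc <- moving_window_metrics(checker, 250, cells = ctr)
  expect_gt(mc[1, "ED"], mb[1, "ED"])
  expect_lt(mc[1, "AI"], mb[1, "AI"])
})
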