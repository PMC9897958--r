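#' Simulate a multi-animal study with planted selection
#'
#' Generates a shared patch-mosaic landscape with synthetic streams and
#' roads, places animals' home ranges across it, and simulates each
#' animal's trajectory with planted excursions and (for some animals)
#' dispersals.  During event travel, steps are chosen among candidates by
#' `exp(beta ln D_IND)`, where `D_IND` is the squared Mahalanobis
#' dissimilarity (finest grain) of each candidate endpoint from the
#' animal's own pre-event home-range metric distribution — so the strength
#' of natal-habitat selection is known exactly.
#'
#' @param n_animals number of animals.
#' @param n_dispersers how many animals also disperse (default: all; each
#'   animal makes one earlier excursion as well).
#' @param beta_dind_disp,beta_dind_exc planted selection coefficients on
#'   `ln(D_IND)` during dispersal / excursion travel (0 = no selection).
#' @param extent_cells landscape side, cells (30 m cells).
#' @param n_fixes fixes per animal.
#' @param sim_grain grain radius (m) used for the planted dissimilarity.
#' @param J_sim candidate steps per travel step.
#' @param seed RNG seed.
#' @return list with `landscape`, `streams`, `roads`, `tracks` (list of
#'   relocation data.frames), `truth` (per animal), and the simulation
#'   metric raster.
#' @export
simulate_study <- function(n_animals = 10, n_dispersers = n_animals,
                           beta_dind_disp = -0.3, beta_dind_exc = 0,
                           extent_cells = 400, n_fixes = 24 * 54,
                           sim_grain = 175, J_sim = 20, seed = 1L) {
  # two-regime study area (forest-heavy west, row-crop east), emulating a
  # landscape where animals' natal contexts genuinely differ - this is what
  # separates the individual-specific from the pooled dissimilarity
  # reference
  lcA <- landscape_config(extent_cells = extent_cells, clumping = 0.5,
                          class_proportions = c(0.05, 0.075, 0.42, 0.19,
                                                0.20, 0.06, 0.005),
                          seed = seed)
  lcB <- landscape_config(extent_cells = extent_cells, clumping = 0.5,
                          class_proportions = c(0.05, 0.095, 0.10, 0.55,
                                                0.14, 0.06, 0.005),
                          seed = seed + 1L)
  lsA <- generate_landscape(lcA)
  lsB <- generate_landscape(lcB)
  v <- lsA$values
  east <- (floor(ncol(v) / 2) + 1):ncol(v)
  v[, east] <- lsB$values[, east]
  landscape <- grid_raster(v, xmin = lsA$xmin, ymin = lsA$ymin,
                           res = lsA$res)
  streams <- simulate_linear_features(landscape, n_lines = 2,
                                      seed = seed + 11L)
  roads <- simulate_linear_features(landscape, n_lines = 2, wiggle = 0.08,
                                    seed = seed + 23L)
  metr <- moving_window_metrics(landscape, sim_grain)
  ext_m <- extent_cells * landscape$res

  tracks <- list()
  truth <- list()
  withr_seed(seed + 37L, {
    # alternate home ranges between the regimes, placed deep enough inside
    # each that excursions stay within the natal regime
    side <- rep(c(0.22, 0.78), length.out = n_animals)
    centers <- cbind(ext_m * (side + runif(n_animals, -0.05, 0.05)),
                     runif(n_animals, 0.3 * ext_m, 0.7 * ext_m))
    disperser <- seq_len(n_animals) <= n_dispersers
  })
  metr_mat <- function(x, y) {
    m <- sapply(metr, function(b) raster_extract(b, x, y))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    m
  }
  for (a in seq_len(n_animals)) {
    id <- sprintf("A%02d", a)
    # pass 1: resident-only pre-period defines the natal reference
    cfg0 <- track_config(hr_center = centers[a, ], n_fixes = n_fixes,
                         events = list(), seed = seed + 100L + a)
    pre <- simulate_track(cfg0, id, extent = landscape)
    pre_xy <- pre$relocs[1:(30 * 24), ]
    ref <- build_reference(metr_mat(pre_xy$x, pre_xy$y), scope = "IND",
                           grain = sim_grain)
    # ln D_IND raster over the landscape, for the selection rule
    stacked <- sapply(metr, function(b) as.numeric(b$values))
    d2 <- mahalanobis_d2(stacked, ref)
    lnd <- grid_raster(matrix(log(pmax(d2, 1e-12)),
                              nrow(landscape$values)),
                       landscape$xmin, landscape$ymin, landscape$res)
    sel <- function(beta) if (beta == 0) NULL else
      list(beta = c(lnD = beta), rasters = list(lnD = lnd), J = J_sim)
    evs <- withr_seed(seed + 300L + a, {
      # two excursions per animal (the field norm is two or three a year)
      # and, for dispersers, a final dispersal with a multi-day search
      # before settlement
      exc <- function(start_day) {
        list(type = "excursion",
             start_fix = as.integer(start_day * 24) + sample.int(12, 1),
             selection = sel(beta_dind_exc),
             n_loiter = 16L + sample.int(12, 1))
      }
      evs <- list(exc(31), exc(34))
      if (disperser[a]) {
        evs[[3]] <- list(type = "dispersal",
                         start_fix = (38 + (a %% 2)) * 24 +
                           sample.int(12, 1),
                         distance = runif(1, 3500, 5500),
                         n_search = 60L + sample.int(12, 1),
                         selection = sel(beta_dind_disp))
      }
      evs
    })
    cfg <- track_config(hr_center = centers[a, ], n_fixes = n_fixes,
                        events = evs, seed = seed + 100L + a)
    tr <- simulate_track(cfg, id, extent = landscape)
    tracks[[id]] <- tr$relocs
    truth[[id]] <- tr$truth
  }
  list(landscape = landscape, streams = streams, roads = roads,
       tracks = tracks, truth = truth, sim_metrics = metr,
       sim_grain = sim_grain)
}

#' Run the full selection analysis on a set of trajectories
#'
#' Screens each trajectory, detects and classifies EHRMs, fits the pooled
#' movement kernel, builds used/available strata with attributed distance,
#' landscape-metric and dissimilarity covariates, and runs the three-tier
#' AICc model selection per subset (excursions by season, dispersals
#' pooled).
#'
#' @param tracks named list of relocation data.frames (one per animal).
#' @param landscape integer-class [grid_raster].
#' @param streams,roads lists of polyline coordinate matrices.
#' @param J available steps per used step.
#' @param grains dissimilarity grain radii, m.
#' @param seed RNG seed (random-step generation).
#' @param min_strata minimum strata for a subset to be modeled.
#' @param group composition-group mapping for the metrics.
#' @param detector_args list of overrides passed to [detect_ehrms()].
#' @return list with `events`, `kernel`, `designs` (per subset),
#'   `fits` (per subset: `tier1`, `tier2`, `tier3`), `references`,
#'   `summary`.
#' @export
run_nhpi_pipeline <- function(tracks, landscape, streams, roads, J = 50,
                              grains = c(175, 250, 350, 500), seed = 1L,
                              min_strata = 10, group = class_groups(),
                              detector_args = list()) {
  screened <- lapply(names(tracks), function(id)
    screen_relocations(tracks[[id]]))
  names(screened) <- names(tracks)
  events <- list()
  for (id in names(screened)) {
    evs <- do.call(detect_ehrms, c(list(screened[[id]]), detector_args))
    for (e in evs) {
      e$animal <- id
      if (e$type != "unresolved") events[[length(events) + 1]] <- e
    }
  }
  if (length(events) == 0) stop("no EHRMs detected")

  # pooled movement kernel over EHRM steps
  step_tabs <- lapply(events, function(e) {
    tr <- screened[[e$animal]]
    st <- track_steps(tr)
    st[st$from >= e$start_idx & st$to <= e$end_idx & !st$gap, ,
       drop = FALSE]
  })
  all_steps <- do.call(rbind, step_tabs)
  kernel <- fit_movement_kernel(all_steps$length, all_steps$turn)

  # covariate rasters
  dist_rasters <- list(
    dForest = distance_raster(landscape,
                              target_class = landcover_classes()["forest"]),
    dAg = distance_raster(landscape,
                          target_class = landcover_classes()["agriculture"]),
    dStream = distance_raster(landscape, lines = streams),
    dRoad = distance_raster(landscape, lines = roads))

  # strata
  strata <- list()
  meta <- list()
  sid <- 0L
  withr_seed(seed, {
    for (ei in seq_along(events)) {
      e <- events[[ei]]
      tr <- screened[[e$animal]]
      st <- track_steps(tr)
      use <- st[st$from >= e$start_idx & st$to <= e$end_idx & !st$gap &
                  st$length > 0, , drop = FALSE]
      for (k in seq_len(nrow(use))) {
        prev <- st$bearing[st$to == use$from[k] & !st$gap]
        prev <- if (length(prev)) prev[1] else NA_real_
        sid <- sid + 1L
        s <- generate_random_steps(use[k, ], prev, kernel, J = J,
                                   extent = landscape)
        s$stratum <- sid
        strata[[sid]] <- s
        meta[[sid]] <- data.frame(stratum = sid, event = ei,
                                  animal = e$animal, type = e$type,
                                  season = e$season)
      }
    }
  })
  if (length(strata) == 0) stop("no usable steps in any event")
  design <- do.call(rbind, strata)
  meta <- do.call(rbind, meta)
  design <- cbind(design, meta[match(design$stratum, meta$stratum),
                               c("event", "animal", "type", "season")])

  # distance covariates at endpoints
  dcov <- extract_covariates(design$x2, design$y2, dist_rasters)
  design <- cbind(design, dcov[names(dist_rasters)])

  # landscape metrics at all needed cells, per grain
  pre_pts <- lapply(events, function(e) {
    tr <- screened[[e$animal]]
    data.frame(x = tr$x[e$pre_idx], y = tr$y[e$pre_idx])
  })
  all_pts <- rbind(data.frame(x = design$x2, y = design$y2),
                   do.call(rbind, pre_pts))
  cells <- cell_of(landscape, all_pts$x, all_pts$y)
  key <- paste(cells$row, cells$col)
  ukey <- !duplicated(key) & !is.na(cells$row)
  ucells <- cells[ukey, , drop = FALSE]
  metric_lookup <- lapply(as.character(grains), function(g) {
    m <- moving_window_metrics(landscape, as.numeric(g),
                               cells = ucells, group = group)
    rownames(m) <- key[ukey]
    m
  })
  names(metric_lookup) <- as.character(grains)
  at_key <- function(g, keys) metric_lookup[[g]][keys, , drop = FALSE]

  n_design <- nrow(design)
  design_key <- key[seq_len(n_design)]
  pre_keys <- split(key[-seq_len(n_design)],
                    rep(seq_along(pre_pts),
                        vapply(pre_pts, nrow, 0L)))

  # references and dissimilarity covariates
  references <- list(ALL = list(), IND = list())
  for (g in as.character(grains)) {
    pooled <- do.call(rbind, lapply(seq_along(events), function(ei)
      at_key(g, pre_keys[[ei]])))
    references$ALL[[g]] <- build_reference(pooled, "ALL",
                                           grain = as.numeric(g))
    design[[paste0("D_ALL_", g)]] <-
      mahalanobis_d2(at_key(g, design_key), references$ALL[[g]])
    references$IND[[g]] <- lapply(seq_along(events), function(ei)
      build_reference(at_key(g, pre_keys[[ei]]), "IND",
                      grain = as.numeric(g)))
    dind <- rep(NA_real_, n_design)
    for (ei in seq_along(events)) {
      rows <- which(design$event == ei)
      dind[rows] <- mahalanobis_d2(at_key(g, design_key[rows]),
                                   references$IND[[g]][[ei]])
    }
    design[[paste0("D_IND_", g)]] <- dind
  }

  # subsets: excursions per season, dispersals pooled
  design$subset <- ifelse(design$type == "dispersal", "dispersal",
                          paste0("excursion_", design$season))
  fits <- list()
  designs <- list()
  for (sub in unique(design$subset)) {
    d <- design[design$subset == sub, , drop = FALSE]
    if (length(unique(d$stratum)) < min_strata) next
    designs[[sub]] <- d
    t1 <- tier1_select_forms(d, c("dForest", "dStream", "dAg", "dRoad"))
    t2 <- tier2_select_base(d, t1)
    t3 <- tier3_select_dissimilarity(d, t2$best, grains = grains)
    fits[[sub]] <- list(tier1 = t1, tier2 = t2, tier3 = t3)
  }
  list(events = events, kernel = kernel, designs = designs, fits = fits,
       references = references, screened = screened,
       dist_rasters = dist_rasters)
}
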