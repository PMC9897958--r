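#' Detector validation on seeded synthetic trajectories
#'
#' Simulates `n_tracks` trajectories (one to three planted events each),
#' screens them, runs [detect_ehrms()], and scores recall (planted events
#' matched by a detected event of overlapping time range), false positives
#' (detections matching no planted event), and label agreement.
#'
#' @param n_tracks number of trajectories.
#' @param days trajectory length, days.
#' @param seed base RNG seed.
#' @param detector_args overrides for [detect_ehrms()].
#' @return list with per-track data.frame `tracks` and totals `recall_pct`,
#'   `false_positives`, `labels_correct_pct`, `n_planted`.
#' @export
experiment_detector <- function(n_tracks = 20, days = 60, seed = 1L,
                                detector_args = list()) {
  rows <- list()
  for (i in seq_len(n_tracks)) {
    plan <- withr_seed(seed + 7L * i, {
      n_ev <- sample.int(3L, 1L)
      # at most one dispersal and only as the last event: a deer has no
      # 30-day pre-movement range so soon after resettling
      has_disp <- runif(1) < 0.4
      types <- c(rep("excursion", n_ev - has_disp),
                 if (has_disp) "dispersal")
      starts <- (31 + cumsum(c(0, rep(4, n_ev - 1)))) * 24 +
        sample.int(12, n_ev, replace = TRUE)
      keep <- starts < (days - 9) * 24
      Map(function(ty, st) list(type = ty, start_fix = st,
                                n_loiter = 8L + sample.int(8, 1)),
          types[keep], starts[keep])
    })
    cfg <- track_config(hr_center = c(5e4, 5e4), n_fixes = days * 24,
                        events = unname(plan), seed = seed + 1000L + i)
    tr <- simulate_track(cfg, sprintf("T%02d", i))
    scr <- screen_relocations(tr$relocs)
    det <- do.call(detect_ehrms, c(list(scr), detector_args))
    det <- Filter(function(e) e$type != "unresolved", det)
    planted <- tr$truth$planted_events
    planted <- Filter(function(p) !p$truncated, planted)
    matched <- rep(FALSE, length(det))
    for (p in seq_along(planted)) {
      pl <- planted[[p]]
      hit <- which(vapply(det, function(e) {
        scr$timestamp[e$start_idx] <= pl$t_end &&
          scr$timestamp[e$end_idx] >= pl$t_start
      }, TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        track = i, planted_type = pl$type,
        detected = length(hit) > 0,
        label_ok = length(hit) > 0 && det[[hit[1]]]$type == pl$type)
      matched[hit] <- TRUE
    }
    if (any(!matched))
      rows[[length(rows) + 1]] <- data.frame(
        track = i, planted_type = "none",
        detected = NA, label_ok = NA)[rep(1, sum(!matched)), ]
  }
  df <- do.call(rbind, rows)
  planted_rows <- df[df$planted_type != "none", , drop = FALSE]
  list(tracks = df,
       n_planted = nrow(planted_rows),
       recall_pct = 100 * mean(planted_rows$detected),
       false_positives = sum(df$planted_type == "none"),
       labels_correct_pct = 100 * mean(planted_rows$label_ok))
}

#' Coefficient recovery and CI coverage of the conditional-logistic fit
#'
#' Repeatedly simulates step-selection data from known coefficients over
#' two smooth covariate rasters and refits, recording estimates, standard
#' errors and 95% CI coverage.
#'
#' @param n_rep replicates.
#' @param true_beta named coefficients over the two covariates.
#' @param n_strata,J design size per replicate.
#' @param seed base RNG seed.
#' @return list with per-replicate data.frame `reps`, `coverage` per
#'   coefficient, and `max_abs_z` (largest |estimate - truth| / SE).
#' @export
experiment_clr_recovery <- function(n_rep = 200,
                                    true_beta = c(cov1 = -0.5, cov2 = 0.3),
                                    n_strata = 500, J = 50, seed = 1L) {
  kernel <- list(shape = 2, scale = 125, mu = 0, kappa = 0.5)
  rasters <- list(
    cov1 = simulate_covariate_raster(150, 30, 8, seed = seed + 1L),
    cov2 = simulate_covariate_raster(150, 30, 8, seed = seed + 2L))
  reps <- lapply(seq_len(n_rep), function(r) {
    design <- simulate_ssf_steps(rasters, true_beta, kernel,
                                 n_strata = n_strata, J = J,
                                 seed = seed + 100L + r)
    X <- as.matrix(design[names(true_beta)])
    fit <- clr_fit(X, design$stratum, design$case)
    data.frame(rep = r, term = names(true_beta),
               truth = unname(true_beta),
               est = unname(fit$beta[names(true_beta)]),
               se = unname(fit$se[names(true_beta)]))
  })
  df <- do.call(rbind, reps)
  df$z <- (df$est - df$truth) / df$se
  df$cover <- abs(df$z) <= 1.96
  list(reps = df,
       coverage = tapply(df$cover, df$term, mean),
       max_abs_z = max(abs(df$z)))
}

#' Brownian-motion variance recovery
#'
#' Simulates planar Brownian motion with GPS noise and re-estimates the
#' diffusion parameter by the leave-one-out likelihood.
#'
#' @param n_rep replicates.
#' @param sigma2m true Brownian motion variance, m^2/h.
#' @param n_fixes fixes per track.
#' @param location_error GPS error sd, m.
#' @param seed base RNG seed.
#' @return data.frame with per-replicate `sigma2m_hat` and `rel_err`.
#' @export
experiment_bbmm_recovery <- function(n_rep = 20, sigma2m = 2000,
                                     n_fixes = 500, location_error = 20,
                                     seed = 1L) {
  do.call(rbind, lapply(seq_len(n_rep), function(r) {
    withr_seed(seed + r, {
      x <- cumsum(rnorm(n_fixes, 0, sqrt(sigma2m)))
      y <- cumsum(rnorm(n_fixes, 0, sqrt(sigma2m)))
      xo <- x + rnorm(n_fixes, 0, location_error)
      yo <- y + rnorm(n_fixes, 0, location_error)
      est <- estimate_bm_variance(xo, yo, seq_len(n_fixes) - 1,
                                  location_error)
      data.frame(rep = r, sigma2m_hat = est$sigma2m,
                 rel_err = abs(est$sigma2m - sigma2m) / sigma2m)
    })
  }))
}

#' End-to-end natal-habitat selection recovery
#'
#' Simulates a population with dispersal-phase selection against
#' natal-habitat dissimilarity (coefficient `beta_dind_disp` on the ln
#' scale) and no excursion-phase selection, runs the full pipeline, and
#' records, per replicate: whether the dispersal tier-3 set includes the
#' D_IND model with the top Akaike weight, the D_IND coefficient and CI in
#' the dispersal model, and the excursion-subset D_IND CIs.
#'
#' @param n_rep replicates.
#' @param n_animals animals per replicate.
#' @param beta_dind_disp planted dispersal coefficient (ln scale).
#' @param J available steps per stratum.
#' @param seed base RNG seed.
#' @param quiet suppress per-replicate progress.
#' @return list with per-replicate data.frame `reps` and the joint success
#'   rate `success_pct` (D_IND model top-weighted with weight >= 0.8,
#'   dispersal CI excluding zero, all excursion CIs covering zero).
#' @export
experiment_nhpi_recovery <- function(n_rep = 20, n_animals = 10,
                                     beta_dind_disp = -0.3, J = 50,
                                     seed = 1L, quiet = TRUE) {
  reps <- lapply(seq_len(n_rep), function(r) {
    res <- tryCatch({
      study <- simulate_study(n_animals = n_animals,
                              beta_dind_disp = beta_dind_disp,
                              seed = seed + 1000L * r)
      run_nhpi_pipeline(study$tracks, study$landscape, study$streams,
                        study$roads, J = J, seed = seed + 1000L * r + 1L)
    }, error = function(e) e)
    fail <- function(note) data.frame(
      rep = r, ok = FALSE, top_w = NA, dind_term = NA, disp_beta = NA,
      disp_lo = NA, disp_hi = NA, exc_cover = NA, note = note)
    if (inherits(res, "error")) return(fail(conditionMessage(res)))
    disp <- res$fits$dispersal
    if (is.null(disp) || disp$tier3$d_ind_omitted)
      return(fail("no dispersal D_IND model"))
    t3 <- disp$tier3
    top_w <- t3$weights[["base_all_ind"]]
    fit <- t3$fits$base_all_ind
    dind_col <- grep("D_IND", names(fit$beta), value = TRUE)[1]
    ci <- clr_confint(fit)[dind_col, ]
    exc <- res$fits[grep("^excursion", names(res$fits))]
    exc_cover <- all(vapply(exc, function(f) {
      if (f$tier3$d_ind_omitted) return(TRUE)  # no D_IND effect retained
      ft <- f$tier3$fits$base_all_ind
      cn <- grep("D_IND", names(ft$beta), value = TRUE)[1]
      cc <- clr_confint(ft)[cn, ]
      cc[1] <= 0 && cc[2] >= 0
    }, TRUE))
    if (!quiet)
      message(sprintf("rep %d: w=%.2f %s CI=[%.3f, %.3f] exc_cover=%s", r,
                      top_w, dind_col, ci[1], ci[2], exc_cover))
    data.frame(rep = r, ok = TRUE, top_w = top_w, dind_term = dind_col,
               disp_beta = unname(fit$beta[dind_col]), disp_lo = ci[1],
               disp_hi = ci[2], exc_cover = exc_cover, note = "")
  })
  df <- do.call(rbind, reps)
  disp_ok <- df$ok & !is.na(df$top_w) & df$top_w >= 0.8 & df$disp_hi < 0
  list(reps = df,
       disp_recovered_pct = 100 * mean(df$ok & !is.na(df$disp_beta) &
                                         df$disp_beta < 0),
       disp_success_pct = 100 * mean(disp_ok),
       exc_cover_pct = 100 * mean(df$exc_cover, na.rm = TRUE),
       success_pct = 100 * mean(disp_ok & !is.na(df$exc_cover) &
                                  df$exc_cover))
}
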