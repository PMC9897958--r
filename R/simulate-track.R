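#' Configuration for a synthetic deer trajectory
#'
#' Resident movement is a discrete-time mean-reverting (Ornstein-Uhlenbeck
#' style) walk around a home-range centre: each coordinate follows
#' `x[t+1] = c + phi (x[t] - c) + eps`, with the innovation sd chosen so the
#' stationary spread equals `hr_sigma`.  Planted events interrupt residency
#' with a biased walk toward a waypoint: excursions loiter at the waypoint
#' and walk back; dispersals settle into residency around the waypoint.
#' During event travel, steps may be chosen among candidate steps by a
#' step-selection rule `P(step) ~ exp(beta' x)` over supplied covariate
#' rasters, which plants a known selection coefficient.
#'
#' @param hr_center length-2 centre coordinates, m.
#' @param hr_sigma stationary per-coordinate spread of residency, m.
#' @param phi hourly autocorrelation of the resident walk, in (0, 1).
#' @param n_fixes number of hourly fixes (>= 24 * 35).
#' @param start_time first timestamp (POSIXct or string, UTC).
#' @param events list of event plans: each a list with `type`
#'   (`"excursion"`/`"dispersal"`), `start_fix`, optional `distance` (m),
#'   `direction` (radians), `n_loiter` (excursion loiter fixes),
#'   `n_search` (dispersal pre-settlement search fixes), and optional
#'   `selection` (list with `beta` named over raster names, `rasters`).
#' @param step_shape,step_scale gamma step-length parameters of event
#'   steps, m.
#' @param kappa_turn von Mises concentration of candidate turns around the
#'   previous bearing (the movement kernel of event steps).
#' @param attract_travel,attract_local,attract_search weight of the
#'   waypoint attraction `exp(b cos(theta - theta_target))` in the
#'   step-choice exponent during travel, during excursion loitering, and
#'   during the wide-ranging pre-settlement search of a dispersal.
#' @param J_sim candidate steps per event step.
#' @param settle_sigma post-dispersal residency spread, m.
#' @param settle_phi post-dispersal residency autocorrelation.
#' @param poor_fix_frac fraction of fixes given HDOP above the screening
#'   threshold.
#' @param p3d probability a fix is three-dimensional.
#' @param seed integer RNG seed.
#' @return a `track_config` list.
#' @export
track_config <- function(hr_center = c(0, 0), hr_sigma = 300, phi = 0.85,
                         n_fixes = 24 * 45,
                         start_time = "2012-03-01 00:00:00",
                         events = list(), step_shape = 3, step_scale = 100,
                         kappa_turn = 0.5, attract_travel = 1.3,
                         attract_local = 0.3, attract_search = 0.5,
                         J_sim = 20, settle_sigma = 150,
                         settle_phi = 0.7, poor_fix_frac = 0.05, p3d = 0.7,
                         seed = 1L) {
  if (n_fixes < 24 * 35) stop("need n_fixes >= 24 * 35")
  starts <- vapply(events, function(e) e$start_fix, 0)
  if (length(starts) > 1 && any(diff(sort(starts)) < 24))
    stop("planted events must be at least a day apart")
  structure(list(hr_center = hr_center, hr_sigma = hr_sigma, phi = phi,
                 n_fixes = as.integer(n_fixes),
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 events = events, step_shape = step_shape,
                 step_scale = step_scale, kappa_turn = kappa_turn,
                 attract_travel = attract_travel,
                 attract_local = attract_local,
                 attract_search = attract_search, J_sim = J_sim,
                 settle_sigma = settle_sigma, settle_phi = settle_phi,
                 poor_fix_frac = poor_fix_frac, p3d = p3d,
                 seed = as.integer(seed)),
            class = "track_config")
}

#' Simulate a trajectory with planted extra-home-range movements
#'
#' @param config a [track_config].
#' @param animal_id id string for the output table.
#' @param extent optional [grid_raster]; all positions are clamped to lie
#'   inside it (an error is raised if a planted waypoint cannot fit).
#' @return list with `relocs` (relocation data.frame: `animal_id`,
#'   `timestamp`, `x`, `y`, `fix_dim`, `hdop`) and `truth` (a `sim_truth`
#'   list: `planted_events` with realized start/end fix indices and
#'   timestamps, `hr_center`, `hr_sigma`, `r95`, `poor_fix_idx`).
#' @export
simulate_track <- function(config, animal_id = "A1", extent = NULL) {
  stopifnot(inherits(config, "track_config"))
  n <- config$n_fixes
  r95 <- config$hr_sigma * sqrt(qchisq(0.95, 2))
  withr_seed(config$seed, {
    for (e in config$events) {
      if (is.null(e$distance))
        e$distance <- if (e$type == "dispersal") 5000 else r95 + 2500
      if (e$type == "dispersal" && e$distance < 2000)
        stop("dispersal distance must be >= 2 km")
    }
    evs <- config$events
    if (length(evs)) {
      ord <- order(vapply(evs, function(e) e$start_fix, 0))
      evs <- evs[ord]
    }
    xy <- matrix(NA_real_, n, 2)
    xy[1, ] <- config$hr_center
    center <- config$hr_center
    sig_eps <- config$hr_sigma * sqrt(1 - config$phi^2)
    set_sig <- config$settle_sigma * sqrt(1 - config$settle_phi^2)
    phase <- "resident"
    phi_cur <- config$phi
    sig_cur <- sig_eps
    ev_i <- 1L
    cur_ev <- NULL
    waypoint <- NULL
    realized <- list()
    clamp <- function(p) {
      if (is.null(extent)) return(p)
      m <- 2 * extent$res
      c(min(max(p[1], extent$xmin + m), raster_xmax(extent) - m),
        min(max(p[2], extent$ymin + m), raster_ymax(extent) - m))
    }
    pick_waypoint <- function(from, dist, dir) {
      for (a in seq_len(200)) {
        th <- if (!is.null(dir) && a == 1) dir else runif(1, -pi, pi)
        w <- from + dist * c(cos(th), sin(th))
        if (is.null(extent)) return(w)
        m <- 5 * extent$res
        if (w[1] > extent$xmin + m && w[1] < raster_xmax(extent) - m &&
            w[2] > extent$ymin + m && w[2] < raster_ymax(extent) - m)
          return(w)
      }
      stop("landscape too small to place the planted waypoint")
    }
    # one event step: a step-selection choice among J_sim candidates drawn
    # from the movement kernel (gamma lengths, von Mises turns about the
    # previous bearing), weighted by waypoint attraction plus any planted
    # habitat selection.  Keeping goal direction in the choice exponent
    # (not in the proposal) means availability resampled from a fitted
    # kernel remains a valid comparison set for these steps.
    event_step <- function(pos, prev_bearing, target, b_target, sel,
                           len_scale = 1) {
      J <- config$J_sim
      bear_t <- atan2(target[2] - pos[2], target[1] - pos[1])
      lens <- rgamma(J, shape = config$step_shape,
                     scale = config$step_scale * len_scale)
      bears <- prev_bearing + rvonmises(J, 0, config$kappa_turn)
      cand <- cbind(pos[1] + lens * cos(bears), pos[2] + lens * sin(bears))
      eta <- b_target * cos(bears - bear_t)
      if (!is.null(sel)) {
        for (v in names(sel$beta)) {
          z <- raster_extract(sel$rasters[[v]], cand[, 1], cand[, 2])
          z[!is.finite(z)] <- mean(z[is.finite(z)], na.rm = TRUE)
          eta <- eta + sel$beta[[v]] * z
        }
      }
      if (!is.null(extent)) {
        m <- 2 * extent$res
        off <- cand[, 1] < extent$xmin + m |
          cand[, 1] > raster_xmax(extent) - m |
          cand[, 2] < extent$ymin + m |
          cand[, 2] > raster_ymax(extent) - m
        eta[off] <- -Inf
        if (all(off)) return(clamp(cand[1, ]))
      }
      eta[is.na(eta)] <- -Inf
      pr <- exp(eta - max(eta))
      cand[sample.int(J, 1, prob = pr), ]
    }
    loiter_left <- 0L
    prev_bearing <- runif(1, -pi, pi)
    for (t in 2:n) {
      if (phase == "resident" && ev_i <= length(evs) &&
          t == evs[[ev_i]]$start_fix) {
        cur_ev <- evs[[ev_i]]
        if (is.null(cur_ev$distance))
          cur_ev$distance <- if (cur_ev$type == "dispersal") 5000
        else r95 + 2500
        waypoint <- pick_waypoint(center, cur_ev$distance,
                                  cur_ev$direction)
        phase <- "out"
        loiter_left <- if (is.null(cur_ev$n_loiter)) 6L else cur_ev$n_loiter
        cur_ev$realized_start <- t
        ev_i <- ev_i + 1L
      }
      if (phase == "resident") {
        xy[t, ] <- clamp(center + phi_cur * (xy[t - 1, ] - center) +
                           rnorm(2, 0, sig_cur))
      } else if (phase == "out") {
        xy[t, ] <- event_step(xy[t - 1, ], prev_bearing, waypoint,
                              config$attract_travel, cur_ev$selection)
        if (sqrt(sum((xy[t, ] - waypoint)^2)) < 2.5 * config$step_scale ||
            t - cur_ev$realized_start > 500) {
          if (cur_ev$type == "dispersal") {
            phase <- "search"
            loiter_left <- if (is.null(cur_ev$n_search)) 60L else
              cur_ev$n_search
          } else {
            phase <- "loiter"
          }
        }
      } else if (phase == "loiter") {
        xy[t, ] <- event_step(xy[t - 1, ], prev_bearing, waypoint,
                              config$attract_local, cur_ev$selection)
        loiter_left <- loiter_left - 1L
        if (loiter_left <= 0L) phase <- "back"
      } else if (phase == "search") {
        xy[t, ] <- event_step(xy[t - 1, ], prev_bearing, waypoint,
                              config$attract_search, cur_ev$selection)
        loiter_left <- loiter_left - 1L
        if (loiter_left <= 0L) {
          center <- waypoint
          phi_cur <- config$settle_phi
          sig_cur <- set_sig
          phase <- "resident"
          cur_ev$realized_end <- t
          realized[[length(realized) + 1]] <- cur_ev
          cur_ev <- NULL
        }
      } else if (phase == "back") {
        xy[t, ] <- event_step(xy[t - 1, ], prev_bearing, center,
                              config$attract_travel, cur_ev$selection)
        if (sqrt(sum((xy[t, ] - center)^2)) < r95) {
          phase <- "resident"
          cur_ev$realized_end <- t - 1L  # last fix before re-entry
          realized[[length(realized) + 1]] <- cur_ev
          cur_ev <- NULL
        }
      }
      d <- xy[t, ] - xy[t - 1, ]
      if (any(d != 0)) prev_bearing <- atan2(d[2], d[1])
    }
    if (!is.null(cur_ev)) {  # track ended mid-event
      cur_ev$realized_end <- n
      cur_ev$truncated <- TRUE
      realized[[length(realized) + 1]] <- cur_ev
    }
    ts <- config$start_time + 3600 * (0:(n - 1))
    fix_dim <- ifelse(runif(n) < config$p3d, "3D", "2D")
    hdop <- runif(n, 0.8, 3.9)
    poor <- which(runif(n) < config$poor_fix_frac)
    hdop[poor] <- ifelse(fix_dim[poor] == "2D", 5, 6) + runif(length(poor),
                                                             0.1, 4)
    relocs <- data.frame(animal_id = animal_id, timestamp = ts,
                         x = xy[, 1], y = xy[, 2], fix_dim = fix_dim,
                         hdop = hdop)
    truth <- structure(list(
      planted_events = lapply(realized, function(e)
        list(type = e$type, start_fix = e$realized_start,
             end_fix = e$realized_end,
             t_start = ts[e$realized_start], t_end = ts[e$realized_end],
             truncated = isTRUE(e$truncated))),
      hr_center = config$hr_center, hr_sigma = config$hr_sigma,
      r95 = r95, poor_fix_idx = poor), class = "sim_truth")
    list(relocs = relocs, truth = truth)
  })
}

#' Write a simulation truth ledger as JSON
#' @param truth a `sim_truth`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$planted_events <- lapply(out$planted_events, function(e) {
    e$t_start <- format(e$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    e$t_end <- format(e$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    e
  })
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
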