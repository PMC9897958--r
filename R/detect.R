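#' Detect extra-home-range movements (EHRMs) in a screened trajectory
#'
#' Slides a pre-movement home-range window (default 30 days) plus an
#' analysis window (the 2 days immediately following) along the trajectory,
#' advancing one day per placement.  For each placement a Brownian bridge UD
#' is fitted to the pre-window fixes and its 95% isopleth extracted; an EHRM
#' candidate exists when the analysis window holds at least `min_far` fixes
#' more than `dist_threshold_m` outside the isopleth *and* at least
#' `min_consecutive` consecutive fixes outside it.  Candidates are extended
#' forward and classified with [classify_ehrm()]; fixes already claimed by an
#' event are excluded from later pre-windows, and placements whose candidate
#' falls inside an existing event are skipped (overlap merging).
#'
#' @param traj screened `trajectory` for one animal (see
#'   [screen_relocations()]).
#' @param hr_window_days,analysis_window_days window lengths, days.
#' @param dist_threshold_m distance-outside threshold, m.
#' @param min_consecutive minimum consecutive outside fixes (the "more than
#'   3" rule, read as >= 4).
#' @param min_far minimum fixes beyond `dist_threshold_m` (>= 2).
#' @param advance_h window advancement per placement, hours.
#' @param completeness minimum fraction of expected hourly fixes in the
#'   pre-window; sparser placements are skipped.
#' @param level isopleth level.
#' @param location_error,res,quad_nodes,quad_tol BBMM settings (see
#'   [compute_bbmm_ud()]).
#' @param settle_window_h,settle_radius_m settlement rule passed to
#'   [classify_ehrm()].
#' @return list of `ehrm_event` objects (including `"unresolved"` ones,
#'   which downstream analyses exclude).
#' @export
detect_ehrms <- function(traj, hr_window_days = 30, analysis_window_days = 2,
                         dist_threshold_m = 500, min_consecutive = 4,
                         min_far = 2, advance_h = 24, completeness = 0.5,
                         level = 0.95, location_error = 20, res = 30,
                         quad_nodes = 10, quad_tol = Inf,
                         settle_window_h = 168, settle_radius_m = 1000) {
  n <- nrow(traj)
  hi <- hour_index(traj$timestamp)
  pre_h <- hr_window_days * 24
  ana_h <- analysis_window_days * 24
  if (max(hi) < pre_h + ana_h)
    stop("trajectory shorter than one window placement")
  covered <- rep(FALSE, n)
  events <- list()
  t0_min <- 0  # pre-windows restart after a dispersal settles
  t0s <- seq(0, max(hi) - pre_h - 1, by = advance_h)
  for (t0 in t0s) {
    if (t0 < t0_min) next
    pre <- which(hi >= t0 & hi < t0 + pre_h & !covered)
    if (length(pre) < completeness * pre_h) next
    ana <- which(hi >= t0 + pre_h & hi < t0 + pre_h + ana_h)
    ana <- ana[!covered[ana]]
    if (length(ana) == 0) next
    fit <- estimate_bm_variance(traj$x[pre], traj$y[pre],
                                traj$timestamp[pre], location_error)
    ud <- compute_bbmm_ud(traj$x[pre], traj$y[pre], traj$timestamp[pre],
                          fit$sigma2m, location_error, res = res,
                          quad_nodes = quad_nodes, quad_tol = quad_tol)
    hr <- extract_isopleth(ud, level)
    outside <- !hr_contains(hr, traj$x[ana], traj$y[ana])
    if (!any(outside)) next
    runs <- rle(outside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    cand <- which(runs$values & runs$lengths >= min_consecutive)
    ev <- NULL
    for (ci in cand) {
      start_idx <- ana[starts[ci]]
      if (covered[start_idx]) next
      ev_try <- classify_ehrm(traj, start_idx, hr,
                              settle_window_h = settle_window_h,
                              settle_radius_m = settle_radius_m)
      rng_try <- ev_try$start_idx:ev_try$end_idx
      # both defining rules must hold for this event's own fixes
      n_far <- sum(hr_distance_outside(hr, traj$x[rng_try],
                                       traj$y[rng_try]) > dist_threshold_m)
      if (n_far >= min_far) {
        ev <- ev_try
        break
      }
    }
    if (is.null(ev)) next
    ev$animal_id <- traj$animal_id[start_idx]
    ev$season <- assign_season(traj$timestamp[start_idx])
    ev$pre_idx <- pre
    ev$pre_window <- c(traj$timestamp[pre[1]], traj$timestamp[pre[length(pre)]])
    ev$pre_hr <- hr
    ev$sigma2m <- fit$sigma2m
    rng <- ev$start_idx:ev$end_idx
    ev$max_dist_m <- max(sqrt((traj$x[rng] - traj$x[ev$start_idx])^2 +
                              (traj$y[rng] - traj$y[ev$start_idx])^2))
    covered[rng] <- TRUE
    if (ev$type == "dispersal") t0_min <- hi[ev$end_idx]
    class(ev) <- "ehrm_event"
    events[[length(events) + 1]] <- ev
  }
  events
}

#' Classify an EHRM as excursion, dispersal, or unresolved
#'
#' Walking forward from the first outside fix: the event is an *excursion*
#' if the animal re-enters the pre-movement isopleth before settling (end =
#' last fix outside before re-entry), and a *dispersal* if, before any
#' re-entry, a `settle_window_h`-hour run of fixes lies entirely outside the
#' isopleth with maximum pairwise spread at most `2 * settle_radius_m` (end
#' = first fix of the settled run).  Events reaching the end of the data
#' with neither outcome are `"unresolved"`.
#'
#' @param traj trajectory data.frame.
#' @param start_idx index of the first EHRM fix.
#' @param pre_hr pre-movement `home_range`.
#' @param settle_window_h settlement window, hours.
#' @param settle_radius_m settlement radius, m (spread limit is twice this).
#' @return list with `type`, `start_idx`, `end_idx`.
#' @export
classify_ehrm <- function(traj, start_idx, pre_hr, settle_window_h = 168,
                          settle_radius_m = 1000) {
  n <- nrow(traj)
  hi <- hour_index(traj$timestamp)
  ii <- start_idx:n
  inside <- hr_contains(pre_hr, traj$x[ii], traj$y[ii])
  reentry <- which(inside)[1]  # position within ii, NA if never
  last_out <- if (is.na(reentry)) n else ii[reentry] - 1
  # settlement scan over fixes strictly before any re-entry
  j <- start_idx
  while (j <= last_out && hi[j] + settle_window_h - 1 <= hi[last_out]) {
    w <- which(hi >= hi[j] & hi < hi[j] + settle_window_h)
    w <- w[w >= start_idx]
    if (length(w) && max(w) <= last_out &&
        spread_le(traj$x[w], traj$y[w], 2 * settle_radius_m))
      return(list(type = "dispersal", start_idx = start_idx, end_idx = j))
    j <- j + 1
  }
  if (!is.na(reentry))
    return(list(type = "excursion", start_idx = start_idx,
                end_idx = last_out))
  list(type = "unresolved", start_idx = start_idx, end_idx = n)
}

# TRUE iff the maximum pairwise distance among points is <= lim
spread_le <- function(x, y, lim) {
  dx <- diff(range(x)); dy <- diff(range(y))
  if (max(dx, dy) > lim) return(FALSE)
  if (sqrt(dx^2 + dy^2) <= lim) return(TRUE)
  h <- chull(x, y)
  max(dist(cbind(x[h], y[h]))) <= lim
}

#' @export
print.ehrm_event <- function(x, ...) {
  cat(sprintf("ehrm_event: %s (%s), fixes %d-%d, max distance %.0f m\n",
              x$type, x$season, x$start_idx, x$end_idx, x$max_dist_m))
  invisible(x)
}

#' Descriptive summary of detected EHRMs
#'
#' Per movement type: event count, steps per event, duration, and maximum
#' straight-line displacement from the first event fix, plus counts per
#' season.
#'
#' @param events list of `ehrm_event` objects (unresolved events are
#'   dropped).
#' @param traj_list optional named list of trajectories (by animal id) used
#'   to recompute durations from timestamps; if omitted, fix-index spans are
#'   used as hours.
#' @return list with a per-type statistics data.frame (`stats`) and a
#'   season-by-type count table (`seasons`).
#' @export
summarize_ehrms <- function(events, traj_list = NULL) {
  events <- Filter(function(e) e$type != "unresolved", events)
  if (length(events) == 0) stop("no resolved events")
  df <- data.frame(
    animal_id = vapply(events, function(e) as.character(e$animal_id), ""),
    type = vapply(events, function(e) e$type, ""),
    season = vapply(events, function(e) e$season, ""),
    steps = vapply(events, function(e) {
      if (!is.null(traj_list)) {
        tr <- traj_list[[as.character(e$animal_id)]]
        as.numeric(tr$timestamp[e$end_idx] - tr$timestamp[e$start_idx],
                   units = "hours")
      } else e$end_idx - e$start_idx
    }, 0),
    max_dist_m = vapply(events, function(e) e$max_dist_m, 0))
  df$duration_h <- df$steps  # hourly schedule: one step per hour
  se <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  stats <- do.call(rbind, lapply(split(df, df$type), function(d) {
    data.frame(type = d$type[1], n_events = nrow(d),
               steps_mean = mean(d$steps), steps_se = se(d$steps),
               steps_min = min(d$steps), steps_max = max(d$steps),
               steps_median = median(d$steps),
               duration_mean_h = mean(d$duration_h),
               duration_se_h = se(d$duration_h),
               dist_min_m = min(d$max_dist_m),
               dist_max_m = max(d$max_dist_m),
               dist_median_m = median(d$max_dist_m))
  }))
  rownames(stats) <- NULL
  list(stats = stats, seasons = table(df$season, df$type), events = df)
}

#' Write an EHRM event ledger as CSV
#' @param events list of `ehrm_event` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ehrm_csv <- function(events, path) {
  df <- do.call(rbind, lapply(events, function(e) {
    data.frame(animal_id = as.character(e$animal_id), type = e$type,
               season = e$season, start_idx = e$start_idx,
               end_idx = e$end_idx, max_dist_m = e$max_dist_m)
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
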