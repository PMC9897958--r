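#' Read a relocation table from CSV
#'
#' Expected columns: `animal_id`, `timestamp` (ISO-8601, UTC), `x`, `y`
#' (projected meters), `fix_dim` (`"2D"`/`"3D"`), `hdop`.  Malformed rows
#' (bad timestamp, nonfinite coordinates, unknown fix dimension, nonpositive
#' HDOP) are dropped and reported with their line numbers.
#'
#' @param path CSV file path.
#' @return data.frame of relocations with attribute `"bad_rows"` (integer
#'   line numbers of dropped rows, header = line 1).
#' @export
read_relocations <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "x", "y", "fix_dim", "hdop")
  if (!all(need %in% names(raw)))
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "))
  ts <- as.POSIXct(rep(NA_real_, nrow(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (f in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
              "%Y-%m-%d %H:%M:%S")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw$timestamp[miss], f, tz = "UTC"))
  }
  bad <- is.na(ts) | !is.finite(raw$x) | !is.finite(raw$y) |
    !(raw$fix_dim %in% c("2D", "3D")) |
    !is.finite(raw$hdop) | raw$hdop <= 0
  out <- raw[!bad, , drop = FALSE]
  out$timestamp <- ts[!bad]
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bad_rows") <- which(bad) + 1L
  out
}

#' Write relocations to CSV
#' @param relocs relocation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relocations <- function(relocs, path) {
  out <- relocs
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screen relocations on GPS fix quality
#'
#' Censors imprecise fixes by horizontal dilution of precision, with
#' dimension-specific thresholds (defaults 5 for 2D and 6 for 3D fixes).
#' Under the default `"retain_low"` convention a fix is retained iff
#' `hdop < threshold` for its dimension; `"literal"` inverts the comparison
#' (removing `hdop < threshold`) for reproducing analyses that used that
#' reading.  Timestamps within 5 minutes of the hour are snapped to the
#' hour; other fixes are flagged off-schedule and dropped (regular 1-h steps
#' are required downstream).
#'
#' @param relocs relocation data.frame (see [read_relocations()]).
#' @param threshold_2d,threshold_3d HDOP thresholds (positive).
#' @param direction `"retain_low"` (default) or `"literal"`.
#' @param snap_tolerance_min snap window around the hour, minutes.
#' @return a `trajectory`: the screened data.frame, ordered in time, with a
#'   screening report in `attr(, "screening")` (counts removed per rule).
#' @export
screen_relocations <- function(relocs, threshold_2d = 5, threshold_3d = 6,
                               direction = c("retain_low", "literal"),
                               snap_tolerance_min = 5) {
  direction <- match.arg(direction)
  stopifnot(threshold_2d > 0, threshold_3d > 0)
  if (nrow(relocs) == 0) {
    out <- relocs
    attr(out, "screening") <- list(removed_2d = 0L, removed_3d = 0L,
                                   removed_off_schedule = 0L,
                                   removed_duplicate = 0L, n_in = 0L,
                                   n_out = 0L, direction = direction)
    class(out) <- c("trajectory", class(out))
    return(out)
  }
  if (any(!relocs$fix_dim %in% c("2D", "3D"))) stop("unknown fix_dim value")
  if (any(relocs$hdop <= 0)) stop("nonpositive hdop")
  thr <- ifelse(relocs$fix_dim == "2D", threshold_2d, threshold_3d)
  keep <- if (direction == "retain_low") relocs$hdop < thr else
    relocs$hdop >= thr
  removed_2d <- sum(!keep & relocs$fix_dim == "2D")
  removed_3d <- sum(!keep & relocs$fix_dim == "3D")
  out <- relocs[keep, , drop = FALSE]

  # regularize to the hourly schedule
  secs <- as.numeric(out$timestamp)
  off <- abs(secs - round(secs / 3600) * 3600)
  on_sched <- off <= snap_tolerance_min * 60
  removed_off <- sum(!on_sched)
  out <- out[on_sched, , drop = FALSE]
  out$timestamp <- as.POSIXct(round(as.numeric(out$timestamp) / 3600) * 3600,
                              origin = "1970-01-01", tz = "UTC")
  out <- out[order(out$animal_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out[, c("animal_id", "timestamp")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "screening") <- list(
    removed_2d = removed_2d, removed_3d = removed_3d,
    removed_off_schedule = removed_off, removed_duplicate = sum(dup),
    n_in = nrow(relocs), n_out = nrow(out), direction = direction)
  class(out) <- c("trajectory", class(out))
  out
}

#' Season of a timestamp
#'
#' Spring: 1 Mar-31 May; summer: 1 Jun-31 Aug; fall: 1 Sep-30 Nov; all other
#' dates (Dec-Feb) are winter.  The labels partition the calendar.
#'
#' @param timestamp POSIXct (any length).
#' @return character vector of `"spring"`, `"summer"`, `"fall"`, `"winter"`.
#' @export
assign_season <- function(timestamp) {
  m <- as.integer(format(timestamp, "%m", tz = "UTC"))
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[m]
}

# hourly fix index relative to the first fix (gaps show as skipped integers)
hour_index <- function(timestamp) {
  as.integer(round(as.numeric(timestamp - timestamp[1], units = "hours")))
}
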