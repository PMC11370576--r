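# Track tables: per-timepoint cell positions exported from tracking software
# (ICY / Imaris manual or spot tracking), one row per (fov, track, timepoint).
# Canonical columns: fov_id, track_id, t_s (seconds from movie start),
# x_um, y_um (planar position in micrometres).

TRACK_COLUMNS <- c("fov_id", "track_id", "t_s", "x_um", "y_um")

#' Read a cell-track table
#'
#' Reads a delimited text export of cell tracks with header
#' `fov_id,track_id,t_s,x_um,y_um` (an optional `z_um` column is read and
#' dropped with a warning: maximum-intensity-projection data carries no
#' usable axial information). If the file has a `frame` column instead of
#' `t_s`, a `frame_interval_s` must be supplied and timestamps are computed
#' as `frame * frame_interval_s`. Rows are sorted by time within each track;
#' duplicate timestamps within one track are an error.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @param frame_interval_s Seconds per frame, required when the file has a
#'   `frame` column and no `t_s` column.
#' @return A validated track table (`data.frame` with class `track_table`).
#' @export
read_tracks <- function(file, sep = ",", frame_interval_s = NULL) {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (!"t_s" %in% names(df)) {
    if (!"frame" %in% names(df)) {
      stop("track table needs a 't_s' column, or a 'frame' column plus ",
           "'frame_interval_s'")
    }
    if (is.null(frame_interval_s)) {
      stop("track table has frame indices but no timestamps: supply ",
           "'frame_interval_s' to convert frames to seconds")
    }
    stopifnot(is.numeric(frame_interval_s), frame_interval_s > 0)
    df$t_s <- df$frame * frame_interval_s
    df$frame <- NULL
  }
  if ("z_um" %in% names(df)) {
    warning("dropping 'z_um' column: track analysis is planar (2-D)")
    df$z_um <- NULL
  }
  as_track_table(df)
}

#' Validate a data frame of track points
#'
#' Checks the track-table contract: required columns, finite coordinates,
#' finite non-negative times, and no duplicate timestamps within a track,
#' then sorts points by time within each (fov_id, track_id).
#'
#' @param df A data frame with columns `fov_id,track_id,t_s,x_um,y_um`.
#' @return `df`, sorted, with class `track_table` prepended.
#' @export
as_track_table <- function(df) {
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("track table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[TRACK_COLUMNS]
  for (col in c("t_s", "x_um", "y_um")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("column '", col, "' must be finite numeric")
    }
  }
  if (any(df$t_s < 0)) stop("timestamps must be non-negative")
  df <- df[order(df$fov_id, df$track_id, df$t_s), , drop = FALSE]
  rownames(df) <- NULL
  key <- paste(df$fov_id, df$track_id, sep = "\r")
  dup <- stats::ave(df$t_s, key, FUN = function(t) anyDuplicated(t) > 0)
  if (any(dup > 0)) {
    bad <- unique(key[dup > 0])[1]
    stop("duplicate timestamps within track ", gsub("\r", "/", bad))
  }
  class(df) <- unique(c("track_table", class(df)))
  df
}

#' Write a track table
#'
#' @param tracks A track table.
#' @param file Output path.
#' @param sep Field separator.
#' @export
write_tracks <- function(tracks, file, sep = ",") {
  tracks <- as_track_table(as.data.frame(tracks))
  utils::write.table(tracks, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# points of one track, ordered by t; internal helper
.one_track <- function(track) {
  track <- as.data.frame(track)
  stopifnot(all(c("t_s", "x_um", "y_um") %in% names(track)),
            nrow(track) >= 1)
  track[order(track$t_s), c("t_s", "x_um", "y_um"), drop = FALSE]
}

#' Track duration
#'
#' Time span of a track: last minus first timestamp, in seconds. A
#' single-point track has duration 0.
#'
#' @param track Data frame of one track's points (`t_s,x_um,y_um`).
#' @return Duration in seconds.
#' @export
track_duration <- function(track) {
  p <- .one_track(track)
  max(p$t_s) - min(p$t_s)
}

#' Total displacement (path length)
#'
#' Sum of Euclidean step lengths over consecutive points, in micrometres.
#' 0 for a single-point track.
#'
#' @inheritParams track_duration
#' @return Path length in micrometres.
#' @export
total_displacement <- function(track) {
  p <- .one_track(track)
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p$x_um)^2 + diff(p$y_um)^2))
}

#' Net displacement
#'
#' Straight-line Euclidean distance between the first and last point of a
#' track, in micrometres.
#'
#' @inheritParams track_duration
#' @return Net displacement in micrometres.
#' @export
net_displacement <- function(track) {
  p <- .one_track(track)
  n <- nrow(p)
  sqrt((p$x_um[n] - p$x_um[1])^2 + (p$y_um[n] - p$y_um[1])^2)
}

#' Track Speed Mean
#'
#' Mean speed of a track, defined as path length divided by track duration
#' (micrometres per second). This duration-weighted definition equals the
#' unweighted mean of per-step speeds when frames are evenly spaced and is
#' robust to dropped frames; it is applied identically to real and
#' synthetic tables.
#'
#' @inheritParams track_duration
#' @return Mean speed in um/s.
#' @export
track_speed_mean <- function(track) {
  p <- .one_track(track)
  if (nrow(p) < 2) {
    stop("track speed mean is undefined for a single-point track")
  }
  total_displacement(p) / track_duration(p)
}

#' Compute all motility metrics for one track
#'
#' @inheritParams track_duration
#' @return A one-row data frame with `duration_s`, `speed_mean_um_per_s`,
#'   `net_um`, `total_um`.
#' @export
compute_metrics <- function(track) {
  p <- .one_track(track)
  if (nrow(p) < 2) {
    stop("metrics are undefined for a single-point track")
  }
  data.frame(
    duration_s = track_duration(p),
    speed_mean_um_per_s = track_speed_mean(p),
    net_um = net_displacement(p),
    total_um = total_displacement(p)
  )
}

#' Per-track metrics for a whole track table
#'
#' Computes duration, mean speed and net/total displacement for every track
#' in a table. Single-point tracks cannot carry motility metrics; they are
#' excluded and their count reported via a message (set `quiet = TRUE` to
#' suppress).
#'
#' @param tracks A track table (see [read_tracks()]).
#' @param quiet Suppress the excluded-track message.
#' @return Data frame with one row per track:
#'   `fov_id,track_id,n_points,duration_s,speed_mean_um_per_s,net_um,total_um`.
#' @export
track_metrics <- function(tracks, quiet = FALSE) {
  tracks <- as_track_table(as.data.frame(tracks))
  key <- paste(tracks$fov_id, tracks$track_id, sep = "\r")
  parts <- split(tracks, factor(key, levels = unique(key)))
  n_pts <- vapply(parts, nrow, integer(1))
  n_single <- sum(n_pts < 2)
  if (n_single > 0 && !quiet) {
    message(n_single, " single-point track(s) excluded from metrics")
  }
  parts <- parts[n_pts >= 2]
  if (!length(parts)) {
    return(data.frame(fov_id = character(), track_id = character(),
                      n_points = integer(), duration_s = numeric(),
                      speed_mean_um_per_s = numeric(), net_um = numeric(),
                      total_um = numeric()))
  }
  rows <- lapply(parts, function(p) {
    cbind(data.frame(fov_id = p$fov_id[1], track_id = p$track_id[1],
                     n_points = nrow(p)),
          compute_metrics(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
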