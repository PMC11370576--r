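# Rule-based leukocyte behavior classification from Track Duration and
# Track Speed Mean, per field of view (FOV).

BEHAVIOR_CLASSES <- c("adherent", "crawling", "patrolling", "tethering")

#' Classifier thresholds
#'
#' Duration/speed cut-offs of the four-class behavior rule set. The
#' defaults follow the intravital neutrophil analysis of 20-minute movies:
#' a Track Speed Mean cut of 0.03 um/s separating immobile from motile
#' cells, a 150-second short-duration cut below which a track is a brief
#' capture-and-release (tethering) event, and a 600-second long-duration
#' cut (half the movie) above which a motile track counts as persistent
#' crawling. For a 1-hour movie the long cut would typically be 1800 s.
#'
#' @param speed_cut_um_per_s Speed at or below which a (non-tethering)
#'   track is adherent. Default 0.03 um/s.
#' @param short_duration_s Duration below which a track is tethering.
#'   Default 150 s.
#' @param long_duration_s Duration at or above which a motile track is
#'   crawling. Default 600 s.
#' @return A list of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(speed_cut_um_per_s = 0.03,
                                  short_duration_s = 150,
                                  long_duration_s = 600) {
  stopifnot(is.numeric(speed_cut_um_per_s), speed_cut_um_per_s > 0,
            is.numeric(short_duration_s), short_duration_s > 0,
            is.numeric(long_duration_s), long_duration_s > short_duration_s)
  structure(list(speed_cut_um_per_s = speed_cut_um_per_s,
                 short_duration_s = short_duration_s,
                 long_duration_s = long_duration_s),
            class = "classifier_thresholds")
}

#' Classify track behavior from duration and mean speed
#'
#' Assigns each track exactly one of four behavior classes by an ordered
#' decision tree:
#' \enumerate{
#'   \item duration < `short_duration_s` (strict) -> `tethering`;
#'   \item else speed <= `speed_cut_um_per_s` -> `adherent`;
#'   \item else duration >= `long_duration_s` -> `crawling`;
#'   \item else -> `patrolling`.
#' }
#' Boundary conventions: a track of exactly 150 s is NOT tethering
#' ("under 150 seconds" is read as strict); exactly 600 s IS crawling
#' (duration ties go to the more persistent class); a speed of exactly
#' 0.03 um/s is adherent (the cut is "<=").  The tree is total: every
#' finite (duration, speed) pair gets exactly one class.
#'
#' @param duration_s Track duration(s), seconds (vectorized).
#' @param speed_mean_um_per_s Track Speed Mean(s), um/s (vectorized).
#' @param thresholds A [classifier_thresholds()] object.
#' @return Factor with levels `adherent, crawling, patrolling, tethering`.
#' @export
classify_behavior <- function(duration_s, speed_mean_um_per_s,
                              thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"),
            length(duration_s) == length(speed_mean_um_per_s),
            all(is.finite(duration_s)), all(is.finite(speed_mean_um_per_s)),
            all(duration_s >= 0), all(speed_mean_um_per_s >= 0))
  cls <- ifelse(duration_s < thresholds$short_duration_s, "tethering",
         ifelse(speed_mean_um_per_s <= thresholds$speed_cut_um_per_s, "adherent",
         ifelse(duration_s >= thresholds$long_duration_s, "crawling",
                "patrolling")))
  factor(cls, levels = BEHAVIOR_CLASSES)
}

#' Classify every track of a track table
#'
#' Computes per-track metrics with [track_metrics()] and appends the
#' behavior class of each track.
#'
#' @param tracks A track table.
#' @param thresholds A [classifier_thresholds()] object.
#' @param quiet Passed to [track_metrics()].
#' @return The metrics table with an extra `behavior` factor column.
#' @export
classify_tracks <- function(tracks, thresholds = classifier_thresholds(),
                            quiet = FALSE) {
  m <- track_metrics(tracks, quiet = quiet)
  m$behavior <- classify_behavior(m$duration_s, m$speed_mean_um_per_s,
                                  thresholds)
  m
}

#' Summarize behavior frequencies per field of view
#'
#' Counts tracks of each behavior class within one FOV and converts counts
#' to frequencies (fractions of classified tracks, summing to 1).
#'
#' @param classified A classified metrics table ([classify_tracks()]
#'   output), or a raw track table (classified on the fly). All rows must
#'   share one `fov_id`; use [summarize_fovs()] for multi-FOV tables.
#' @param thresholds Used only when `classified` lacks a `behavior` column.
#' @return One-row data frame: `fov_id`, `n_tracks`, `n_<class>` counts and
#'   `freq_<class>` frequencies for the four classes.
#' @export
summarize_fov <- function(classified, thresholds = classifier_thresholds()) {
  if (!"behavior" %in% names(classified)) {
    classified <- classify_tracks(classified, thresholds, quiet = TRUE)
  }
  if (length(unique(classified$fov_id)) > 1) {
    stop("summarize_fov expects a single fov_id; got ",
         length(unique(classified$fov_id)), " (use summarize_fovs)")
  }
  if (nrow(classified) == 0) {
    stop("no classifiable track in FOV: empty summary")
  }
  counts <- table(factor(classified$behavior, levels = BEHAVIOR_CLASSES))
  n <- sum(counts)
  out <- data.frame(fov_id = classified$fov_id[1], n_tracks = n)
  for (cl in BEHAVIOR_CLASSES) out[[paste0("n_", cl)]] <- as.integer(counts[[cl]])
  for (cl in BEHAVIOR_CLASSES) out[[paste0("freq_", cl)]] <- counts[[cl]] / n
  out
}

#' Summarize behavior frequencies for every FOV of a table
#'
#' @inheritParams summarize_fov
#' @return One row per FOV, columns as in [summarize_fov()].
#' @export
summarize_fovs <- function(classified, thresholds = classifier_thresholds()) {
  if (!"behavior" %in% names(classified)) {
    classified <- classify_tracks(classified, thresholds, quiet = TRUE)
  }
  parts <- split(classified, factor(classified$fov_id,
                                    levels = unique(classified$fov_id)))
  out <- do.call(rbind, lapply(parts, summarize_fov))
  rownames(out) <- NULL
  out
}
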