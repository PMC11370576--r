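# Seeded synthetic intravital movies: correlated random-walk tracks drawn
# from four motility modes, with ground-truth behavior labels, standing in
# for tracked microscopy data so the metric and classification stages can
# be validated end to end.

#' Motility-mode parameters
#'
#' Describes how tracks of one behavior mode are generated: mean per-step
#' speed and spread, heading persistence, track lifetime range and whether
#' the cell enters at the field border or appears in the interior.
#'
#' @param mode One of `adherent, crawling, patrolling, tethering`.
#' @param speed_um_per_s Mean step speed (um/s), >= 0.
#' @param speed_sd Standard deviation of step speed (um/s).
#' @param persistence Turning-angle concentration in \[0, 1\]:
#'   0 = uniform headings (pure random walk), 1 = straight line.
#' @param duration_range_s Length-2 numeric, min/max track lifetime (s).
#' @param entry `"interior"` (uniform start position) or `"boundary"`
#'   (start on a field edge, heading inward).
#' @param border `"reflect"` (bounce off edges) or `"exit"` (terminate on
#'   border contact once past the minimum lifetime, emulating FOV exit).
#' @return List of class `motility_mode_params`.
#' @export
motility_mode_params <- function(mode, speed_um_per_s, speed_sd,
                                 persistence, duration_range_s,
                                 entry = c("interior", "boundary"),
                                 border = c("reflect", "exit")) {
  mode <- match.arg(mode, BEHAVIOR_CLASSES)
  entry <- match.arg(entry)
  border <- match.arg(border)
  stopifnot(speed_um_per_s >= 0, speed_sd >= 0,
            persistence >= 0, persistence <= 1,
            length(duration_range_s) == 2,
            duration_range_s[1] > 0,
            duration_range_s[1] <= duration_range_s[2])
  structure(list(mode = mode, speed_um_per_s = speed_um_per_s,
                 speed_sd = speed_sd, persistence = persistence,
                 duration_range_s = duration_range_s, entry = entry,
                 border = border),
            class = "motility_mode_params")
}

#' Default motility-mode presets
#'
#' Well-separated parameter sets for the four behavior modes of a
#' 20-minute neutrophil movie: adherent cells drift at 0.005 um/s for most
#' of the movie (1000-1200 s), crawling cells move at 0.12 um/s for
#' 700-1100 s, patrolling cells transit at 0.15 um/s for 200-500 s, and
#' tethering cells appear at the border for only 60-120 s. Speeds sit well
#' to either side of the 0.03 um/s classifier cut and durations clear of
#' the 150/600 s cuts, so generated labels are recoverable by the
#' classifier.
#'
#' @return Named list of [motility_mode_params()], one per class.
#' @export
default_mode_presets <- function() {
  list(
    adherent = motility_mode_params("adherent", 0.005, 0.00125, 0.2,
                                    c(1000, 1200), "interior", "reflect"),
    crawling = motility_mode_params("crawling", 0.12, 0.03, 0.8,
                                    c(700, 1100), "interior", "reflect"),
    patrolling = motility_mode_params("patrolling", 0.15, 0.0375, 0.9,
                                      c(200, 500), "boundary", "exit"),
    tethering = motility_mode_params("tethering", 0.15, 0.0375, 0.9,
                                     c(60, 120), "boundary", "exit")
  )
}

#' Movie scenario
#'
#' A synthetic field-of-view recording: duration, extent, per-mode track
#' counts, frame interval and seed. Defaults describe a 20-minute movie in
#' a 400 x 400 um field sampled every 10 s.
#'
#' @param label Scenario label (e.g. an experimental arm name).
#' @param duration_s Movie duration, seconds (default 1200 = 20 min; use
#'   3600 for a 1-hour macrophage movie).
#' @param width_um,height_um Field-of-view extent, micrometres.
#' @param counts Named integer vector of track counts per mode; names must
#'   be behavior classes.
#' @param frame_interval_s Seconds between frames (default 10).
#' @param fov_id Field identifier used in output tables.
#' @param seed Integer seed; one top-level seed spawns independent
#'   per-track substreams.
#' @return List of class `movie_scenario`.
#' @export
movie_scenario <- function(label = "movie",
                           duration_s = 1200,
                           width_um = 400, height_um = 400,
                           counts = c(adherent = 10, crawling = 10,
                                      patrolling = 10, tethering = 10),
                           frame_interval_s = 10,
                           fov_id = label,
                           seed = 1L) {
  stopifnot(duration_s > 0, width_um > 0, height_um > 0,
            frame_interval_s > 0, all(counts >= 0),
            all(names(counts) %in% BEHAVIOR_CLASSES))
  structure(list(label = label, duration_s = duration_s,
                 width_um = width_um, height_um = height_um,
                 counts = counts, frame_interval_s = frame_interval_s,
                 fov_id = fov_id, seed = as.integer(seed)),
            class = "movie_scenario")
}

# wrapped turning angle: persistence 0 -> uniform on (-pi, pi],
# persistence 1 -> no turning; in between, normal with sd (1 - p) * pi
# wrapped into (-pi, pi].
.turn_angles <- function(n, persistence) {
  if (persistence <= 0) return(stats::runif(n, -pi, pi))
  if (persistence >= 1) return(rep(0, n))
  a <- stats::rnorm(n, 0, (1 - persistence) * pi)
  (a + pi) %% (2 * pi) - pi
}

# gamma step lengths with given mean/sd (degenerate sd -> constant)
.step_lengths <- function(n, mean_len, sd_len) {
  if (mean_len <= 0) return(rep(0, n))
  if (sd_len <= 0) return(rep(mean_len, n))
  shape <- (mean_len / sd_len)^2
  stats::rgamma(n, shape = shape, rate = shape / mean_len)
}

#' Simulate one track of a motility mode
#'
#' Generates a correlated random walk: step lengths drawn from a gamma
#' distribution with mean `speed * frame_interval`, headings turning by a
#' wrapped angle whose spread shrinks with `persistence`. The lifetime is
#' drawn uniformly from `duration_range_s` (snapped to the frame grid) and
#' the start time placed uniformly so the track fits inside the movie.
#' Reflecting modes bounce off field borders; exiting modes terminate on
#' border contact once past their minimum lifetime.
#'
#' @param params A [motility_mode_params()] object.
#' @param scenario A [movie_scenario()] object.
#' @param track_id Identifier for the generated track.
#' @param seed Optional integer seed for this track's substream.
#' @return Track table of the generated points with the true mode stored
#'   in attribute `true_mode`.
#' @export
simulate_track <- function(params, scenario, track_id = "t1", seed = NULL) {
  stopifnot(inherits(params, "motility_mode_params"),
            inherits(scenario, "movie_scenario"))
  dt <- scenario$frame_interval_s
  if (params$duration_range_s[1] > scenario$duration_s) {
    stop("infeasible parameters: duration_range_s exceeds movie duration")
  }
  if (!is.null(seed)) set.seed(seed)
  dur <- stats::runif(1, params$duration_range_s[1],
                      min(params$duration_range_s[2], scenario$duration_s))
  n_steps <- max(1L, as.integer(round(dur / dt)))
  n_slots <- floor((scenario$duration_s - n_steps * dt) / dt)
  t0 <- if (n_slots > 0) dt * (sample.int(n_slots + 1L, 1L) - 1L) else 0
  w <- scenario$width_um; h <- scenario$height_um
  if (params$entry == "boundary") {
    edge <- sample.int(4L, 1L)
    u <- stats::runif(1)
    pos <- switch(edge, c(u * w, 0), c(u * w, h), c(0, u * h), c(w, u * h))
    # heading toward the field centre, jittered
    heading <- atan2(h / 2 - pos[2], w / 2 - pos[1]) + stats::runif(1, -0.5, 0.5)
  } else {
    pos <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
    heading <- stats::runif(1, -pi, pi)
  }
  lens <- .step_lengths(n_steps, params$speed_um_per_s * dt,
                        params$speed_sd * dt)
  turns <- .turn_angles(n_steps, params$persistence)
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  xs[1] <- pos[1]; ys[1] <- pos[2]
  n_kept <- n_steps + 1L
  for (i in seq_len(n_steps)) {
    heading <- heading + turns[i]
    x <- xs[i] + lens[i] * cos(heading)
    y <- ys[i] + lens[i] * sin(heading)
    out_of_field <- x < 0 || x > w || y < 0 || y > h
    if (out_of_field && params$border == "exit" &&
        i * dt >= params$duration_range_s[1]) {
      # clip the exit point to the border and stop the track there
      xs[i + 1L] <- min(max(x, 0), w)
      ys[i + 1L] <- min(max(y, 0), h)
      n_kept <- i + 1L
      break
    }
    # mirror reflection (repeated for corner overshoots)
    while (x < 0 || x > w) x <- if (x < 0) -x else 2 * w - x
    while (y < 0 || y > h) y <- if (y < 0) -y else 2 * h - y
    xs[i + 1L] <- x
    ys[i + 1L] <- y
  }
  out <- data.frame(fov_id = scenario$fov_id, track_id = track_id,
                    t_s = t0 + dt * (seq_len(n_kept) - 1L),
                    x_um = xs[seq_len(n_kept)], y_um = ys[seq_len(n_kept)])
  attr(out, "true_mode") <- params$mode
  out
}

#' Simulate a whole movie with ground-truth labels
#'
#' Generates the scenario's requested number of tracks per motility mode.
#' The scenario seed is used once to draw an independent substream seed per
#' track, so adding tracks does not perturb earlier ones.
#'
#' @param scenario A [movie_scenario()] object.
#' @param modes Named list of [motility_mode_params()] covering every mode
#'   with a nonzero count (default [default_mode_presets()]).
#' @return List with `tracks` (a track table) and `labels`
#'   (`fov_id,track_id,true_mode`).
#' @export
simulate_movie <- function(scenario, modes = default_mode_presets()) {
  stopifnot(inherits(scenario, "movie_scenario"))
  counts <- scenario$counts[scenario$counts > 0]
  missing_modes <- setdiff(names(counts), names(modes))
  if (length(missing_modes)) {
    stop("no mode parameters for: ", paste(missing_modes, collapse = ", "))
  }
  n_total <- sum(counts)
  set.seed(scenario$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_total, replace = TRUE)
  track_dfs <- vector("list", n_total)
  labels <- vector("list", n_total)
  k <- 0L
  for (mode in names(counts)) {
    for (i in seq_len(counts[[mode]])) {
      k <- k + 1L
      id <- sprintf("%s_%03d", mode, i)
      track_dfs[[k]] <- simulate_track(modes[[mode]], scenario,
                                       track_id = id, seed = sub_seeds[k])
      labels[[k]] <- data.frame(fov_id = scenario$fov_id, track_id = id,
                                true_mode = mode)
    }
  }
  tracks <- as_track_table(do.call(rbind, track_dfs))
  list(tracks = tracks, labels = do.call(rbind, labels))
}
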