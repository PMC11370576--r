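# Independent oracles, deliberately coded without reference to the
# package internals they check.

# Brute-force behavior lookup: evaluates the four published rule
# predicates directly, with the documented tie-breaks (150 s strict for
# tethering, 600 s tie to crawling, speed cut inclusive for adherent).
oracle_behavior <- function(duration_s, speed_um_per_s,
                            speed_cut = 0.03, short_s = 150, long_s = 600) {
  stopifnot(length(duration_s) == 1, length(speed_um_per_s) == 1)
  is_tethering <- duration_s < short_s
  is_adherent <- !is_tethering & speed_um_per_s <= speed_cut
  is_crawling <- !is_tethering & speed_um_per_s > speed_cut & duration_s >= long_s
  # boundary tie-break: exactly 150 s is not tethering, so a motile track
  # of 150 s falls to patrolling ("> 150 but < 600" with the strict lower
  # bound absorbed by the tethering rule)
  is_patrolling <- !is_tethering & speed_um_per_s > speed_cut &
    duration_s < long_s
  # the documented precedence makes the predicates exhaustive & exclusive
  picks <- c(tethering = is_tethering, adherent = is_adherent,
             crawling = is_crawling, patrolling = is_patrolling)
  names(picks)[which(picks)[1]]
}

# Hand-coded one-way ANOVA from the classical sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0; ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  k <- length(unique(groups)); n <- length(values)
  msb <- ss_between / (k - 1)
  msw <- ss_within / (n - k)
  f <- msb / msw
  list(f = f, df1 = k - 1, df2 = n - k,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Random jagged test track (not a correlated walk; raw uniform points).
random_track <- function(n = NULL, fov = "f", id = "t") {
  if (is.null(n)) n <- sample(2:40, 1)
  data.frame(fov_id = fov, track_id = id,
             t_s = sort(sample.int(10000, n)),
             x_um = runif(n, 0, 400), y_um = runif(n, 0, 400))
}

# Apply a rigid rotation + translation to a track's coordinates.
transform_track <- function(track, angle = 0, dx = 0, dy = 0, dt = 0) {
  x <- track$x_um * cos(angle) - track$y_um * sin(angle) + dx
  y <- track$x_um * sin(angle) + track$y_um * cos(angle) + dy
  data.frame(fov_id = track$fov_id, track_id = track$track_id,
             t_s = track$t_s + dt, x_um = x, y_um = y)
}

# Single-cell trace table wrapper around bare (t, ratio) samples.
as_cell_trace <- function(t_s, ratio, batch = "b1", dish = "d1",
                          cell = "c1", condition = "vehicle") {
  as_trace_table(data.frame(batch_id = batch, dish_id = dish, cell_id = cell,
                            condition = condition, t_s = t_s, ratio = ratio))
}
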