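test_that("metrics match hand-computed values on simple geometries", {
  tri <- data.frame(fov_id = "f", track_id = "a",
                    t_s = c(0, 10, 20),
                    x_um = c(0, 3, 3), y_um = c(0, 0, 4))
  expect_equal(track_duration(tri), 20)
  expect_equal(total_displacement(tri), 7)      # 3 + 4
  expect_equal(net_displacement(tri), 5)        # 3-4-5 triangle
  expect_equal(track_speed_mean(tri), 0.35)
  m <- compute_metrics(tri)
  expect_equal(unlist(m),
               c(duration_s = 20, speed_mean_um_per_s = 0.35,
                 net_um = 5, total_um = 7))

  # duration counts time span only; speed is path / duration
  slow <- data.frame(fov_id = "f", track_id = "b", t_s = c(0, 10, 20),
                     x_um = c(0, 0.3, 0.6), y_um = 0)
  expect_equal(track_speed_mean(slow), 0.03)
  leap <- data.frame(fov_id = "f", track_id = "c", t_s = c(0, 10),
                     x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(track_speed_mean(leap), 0.5)

  # degenerate cases
  single <- data.frame(fov_id = "f", track_id = "d", t_s = 37,
                       x_um = 1, y_um = 2)
  expect_equal(track_duration(single), 0)
  expect_equal(total_displacement(single), 0)
  expect_equal(net_displacement(single), 0)
  expect_error(track_speed_mean(single), "single-point")
  loop <- data.frame(fov_id = "f", track_id = "e", t_s = c(30, 60, 90),
                     x_um = c(1, 5, 1), y_um = c(1, 5, 1))
  expect_equal(track_duration(loop), 60)
  expect_equal(net_displacement(loop), 0)
  still <- data.frame(fov_id = "f", track_id = "g", t_s = c(0, 5, 10),
                      x_um = 2, y_um = 2)
  expect_equal(track_speed_mean(still), 0)
})

test_that("metrics are invariant under rigid motion and time shift, and scale linearly", {
  set.seed(42)
  for (i in 1:25) {
    tr <- random_track()
    m0 <- compute_metrics(tr)
    moved <- transform_track(tr, angle = runif(1, -pi, pi),
                             dx = runif(1, -50, 50), dy = runif(1, -50, 50),
                             dt = 100)
    expect_equal(compute_metrics(moved), m0, tolerance = 1e-9)
    expect_gte(m0$total_um, m0$net_um)  # triangle inequality
    doubled <- tr
    doubled$x_um <- 2 * tr$x_um
    doubled$y_um <- 2 * tr$y_um
    m2 <- compute_metrics(doubled)
    expect_equal(m2$total_um, 2 * m0$total_um)
    expect_equal(m2$net_um, 2 * m0$net_um)
    expect_equal(m2$speed_mean_um_per_s, 2 * m0$speed_mean_um_per_s)
    expect_equal(m2$duration_s, m0$duration_s)
  }
})

test_that("speed mean equals the duration-weighted mean of step speeds", {
  set.seed(7)
  for (i in 1:10) {
    tr <- random_track()
    dt <- diff(tr$t_s)
    step_speed <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) / dt
    expect_equal(track_speed_mean(tr),
                 stats::weighted.mean(step_speed, dt), tolerance = 1e-12)
  }
})

test_that("track table reader round-trips, sorts, converts frames and rejects bad input", {
  tr <- rbind(random_track(8, id = "t1"), random_track(5, id = "t2"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks(as_track_table(tr), f)
  back <- read_tracks(f)
  expect_s3_class(back, "track_table")
  expect_equal(back$x_um, as_track_table(tr)$x_um)

  # unsorted rows are sorted by time within track
  shuffled <- tr[sample(nrow(tr)), ]
  utils::write.table(shuffled, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_false(is.unsorted(subset(read_tracks(f), track_id == "t1")$t_s))

  # frame-index input requires a frame interval
  frames <- data.frame(fov_id = "f", track_id = "t", frame = 0:4,
                       x_um = 0:4, y_um = 0)
  utils::write.table(frames, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_error(read_tracks(f), "frame_interval_s")
  expect_equal(read_tracks(f, frame_interval_s = 10)$t_s, c(0, 10, 20, 30, 40))

  # z column is dropped with a warning
  with_z <- cbind(random_track(4), z_um = 1)
  utils::write.table(with_z, f, sep = ",", row.names = FALSE, quote = FALSE)
  expect_warning(res <- read_tracks(f), "z_um")
  expect_false("z_um" %in% names(res))

  # duplicate timestamps within one track are an error
  dup <- random_track(4)
  dup$t_s[2] <- dup$t_s[1]
  expect_error(as_track_table(dup), "duplicate timestamps")
  neg <- random_track(3)
  neg$t_s[1] <- -1
  expect_error(as_track_table(neg), "non-negative")
})

test_that("track_metrics excludes and reports single-point tracks", {
  tr <- rbind(random_track(6, id = "long"),
              data.frame(fov_id = "f", track_id = "stub", t_s = 3,
                         x_um = 1, y_um = 1))
  expect_message(m <- track_metrics(as_track_table(tr)),
                 "1 single-point track")
  expect_equal(m$track_id, "long")
  expect_silent(track_metrics(as_track_table(tr), quiet = TRUE))
})
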