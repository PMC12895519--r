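test_that("transverse velocity samples match closed-form tracks", {
  # straight track along x: all |dy/dt| = 0
  tx <- straight_tracks(0)
  expect_equal(as.numeric(y_velocity_samples(tx)), rep(0, 19))
  # constant (0, 10) um/s motion: all samples 10
  ty <- straight_tracks(pi / 2, speed = 10)
  expect_equal(as.numeric(y_velocity_samples(ty)), rep(10, 19),
               tolerance = 1e-12)
  # signed variant keeps direction
  tdown <- straight_tracks(-pi / 2, speed = 10)
  expect_equal(as.numeric(y_velocity_samples(tdown, signed = TRUE)),
               rep(-10, 19), tolerance = 1e-12)
})

test_that("isotropic straight swimmers have mean |v_y| = 2v/pi", {
  # analytic oracle: E|v sin(theta)| over uniform theta = 2v/pi
  set.seed(5)
  tracks <- straight_tracks(runif(4000, -pi, pi), speed = 44, n_frames = 3)
  s <- y_velocity_samples(tracks)
  expect_equal(mean(s), 2 * 44 / pi, tolerance = 0.03)
})

test_that("per-track samples survive mirroring and resampling density", {
  set.seed(8)
  tr <- straight_tracks(runif(20, -pi, pi))
  mirrored <- tr
  mirrored$POSITION_Y <- -mirrored$POSITION_Y
  expect_equal(as.numeric(y_velocity_samples(track_table(mirrored))),
               as.numeric(y_velocity_samples(tr)))
  # doubling sampling density of a noiseless straight track leaves the
  # velocity samples unchanged
  t1 <- straight_tracks(0.7, n_frames = 10, dt = 0.05)
  t2 <- straight_tracks(0.7, n_frames = 19, dt = 0.025)
  expect_equal(unique(round(as.numeric(y_velocity_samples(t1)), 9)),
               unique(round(as.numeric(y_velocity_samples(t2)), 9)))
})

test_that("inconsistent frame timing and short tracks are handled explicitly", {
  df <- data.frame(TRACK_ID = 1, FRAME = 0:2,
                   POSITION_T = c(0, 0.05, 0.2),  # inconsistent with 50 ms
                   POSITION_X = 1:3, POSITION_Y = 1:3)
  expect_error(y_velocity_samples(track_table(df)), "inconsistent")
  one_frame <- data.frame(TRACK_ID = c(1, 2, 2), FRAME = c(0, 0, 1),
                          POSITION_T = c(0, 0, 0.05),
                          POSITION_X = c(0, 0, 1), POSITION_Y = c(0, 0, 1))
  s <- y_velocity_samples(track_table(one_frame))
  expect_equal(attr(s, "n_skipped"), 1L)
  expect_length(as.numeric(s), 1L)
})

test_that("distribution summary matches a sort-based quantile oracle", {
  const <- rep(3.5, 25)
  sm <- velocity_distribution_summary(const)
  expect_equal(sm$mean, 3.5)
  expect_equal(unname(sm$quantiles), rep(3.5, 5))
  set.seed(12)
  x <- rexp(101, 1 / 8)
  sm2 <- velocity_distribution_summary(x)
  # sort-based oracle (linear interpolation of order statistics)
  xs <- sort(x)
  oracle <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(unname(sm2$quantiles),
               vapply(c(.05, .25, .5, .75, .95), oracle, numeric(1)),
               tolerance = 1e-12)
  expect_equal(sm2$mean, mean(x))
  expect_error(velocity_distribution_summary(1:5), "at least 10")
})

test_that("alignment index is 1 for flow-aligned and 2/pi for isotropic tracks", {
  expect_equal(alignment_index(straight_tracks(c(0, pi))), 1)
  set.seed(9)
  iso <- straight_tracks(runif(4000, -pi, pi), n_frames = 3)
  expect_equal(alignment_index(iso), 2 / pi, tolerance = 0.03)
})

test_that("track tables round-trip through delimited text with validation", {
  set.seed(3)
  tr <- straight_tracks(c(0.2, 1.4, -2.3), n_frames = 5)
  tr$EXTRA_COL <- seq_len(nrow(tr))  # unknown columns preserved
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracks(track_table(tr), path)
  back <- read_tracks(path)
  expect_equal(as.data.frame(back), as.data.frame(track_table(tr)),
               tolerance = 1e-12)
  expect_true("EXTRA_COL" %in% names(back))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TRACK_ID\tFRAME\tPOSITION_T\tPOSITION_X\tPOSITION_Y",
               "1\t0\t0\t1\t2", "1\t1\t0.05\t3"), bad)
  expect_error(read_tracks(bad), "line 3")
  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TRACK_ID\tFRAME\tPOSITION_T\tPOSITION_X", "1\t0\t0\t1"),
             missing_col)
  expect_error(read_tracks(missing_col), "POSITION_Y")
})

test_that("ABM track ensembles: transverse speed reflects swimming, alignment responds to advection", {
  # p0 modulation is imposed on reversals only, so the transverse speed
  # statistic stays pinned to the isotropic swimming value 2v/pi across
  # the fitted p0 schedule; alignment with the flow axis grows once the
  # window-averaged advection becomes comparable to the swimming speed
  vels <- c(0.5, 5)
  p0s <- c(0.5, 0.1)
  stats <- vapply(seq_along(vels), function(k) {
    cfg <- abm_config(velocity_m_d = vels[k], p0 = p0s[k], n_agents = 500,
                      duration = 16, burn_in = 8, seed = 40 + k,
                      record_tracks = TRUE)
    tt <- make_track_fixtures(cfg, attractant = NULL, localization_sd = 0,
                              n_frames = 100, seed = 140 + k)
    s <- y_velocity_samples(tt)
    c(mean(s), alignment_index(tt))
  }, numeric(2))
  expect_equal(stats[1, ], rep(2 * 44 / pi, 2), tolerance = 0.08)
  # strong advection (mean flow above the swimming speed) aligns tracks
  cfg_fast <- abm_config(velocity_m_d = 40, p0 = 0.1, n_agents = 500,
                         duration = 10, burn_in = 4, seed = 77,
                         record_tracks = TRUE)
  tt_fast <- make_track_fixtures(cfg_fast, attractant = NULL,
                                 localization_sd = 0, n_frames = 100,
                                 seed = 177)
  expect_gt(alignment_index(tt_fast), max(stats[2, ]) + 0.05)
  # and leaves the transverse swimming statistic untouched
  expect_equal(mean(y_velocity_samples(tt_fast)), 2 * 44 / pi,
               tolerance = 0.08)
})
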