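params25 <- pipeline_params(fps = 25)

test_that("tracks below the 30-s floor produce no segments", {
  # 29 s continuous at 25 fps
  tab <- toy_table(0:724, x = (0:724) * 0.004, y = rep(0, 725))
  expect_length(filter_and_segment(tab, params25), 0L)
  # exactly 30 s is kept
  tab30 <- toy_table(0:749, x = (0:749) * 0.004, y = rep(0, 750))
  expect_length(filter_and_segment(tab30, params25), 1L)
})

test_that("a long hole splits a track into discardable pieces", {
  # 60 s total with a 6-s hole at t = 27 s: two 27-s pieces, both dropped
  frames <- c(0:674, 825:1499)
  tab <- toy_table(frames, x = frames * 0.004, y = rep(0, length(frames)))
  expect_length(filter_and_segment(tab, params25), 0L)
})

test_that("a short hole is retained inside one segment for interpolation", {
  # 60 s with a 2-s hole: one full-span segment with flagged missing frames
  frames <- c(0:699, 750:1499)
  tab <- toy_table(frames, x = frames * 0.004, y = rep(0, length(frames)))
  segs <- filter_and_segment(tab, params25)
  expect_length(segs, 1L)
  expect_identical(nrow(segs[[1]]), 1500L)
  expect_identical(sum(!segs[[1]]$observed), 50L)
  expect_true(all(is.na(segs[[1]]$x_mm[!segs[[1]]$observed])))
})

test_that("gap interpolation is linear and the no-hole case is the identity", {
  seg <- toy_segment(x = c(0, NA, 0), y = c(0, NA, 2))
  seg$observed <- c(TRUE, FALSE, TRUE)
  out <- interpolate_gaps(seg, params25)
  expect_equal(out$x_mm, c(0, 0, 0))
  expect_equal(out$y_mm, c(0, 1, 2))
  expect_identical(out$observed, c(TRUE, FALSE, TRUE))

  seg2 <- toy_segment(x = c(0, NA, NA, NA, 4), y = rep(0, 5))
  seg2$observed <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(interpolate_gaps(seg2, params25)$x_mm, 0:4)

  intact <- toy_segment(x = 1:10, y = 1:10)
  expect_identical(interpolate_gaps(intact, params25), intact)
})

test_that("holes at or beyond max_gap_s cannot reach interpolation", {
  seg <- toy_segment(x = c(0, rep(NA, 125), 126), y = rep(0, 127))
  seg$observed <- c(TRUE, rep(FALSE, 125), TRUE)
  expect_error(interpolate_gaps(seg, params25), "contract")
})

test_that("rolling mean preserves constants and straight interiors, kills 1-s wobble", {
  n <- 1000
  const <- toy_segment(x = rep(2, n), y = rep(-1, n))
  sm <- rolling_mean_smooth(const, params25)
  expect_equal(sm$x_mm, rep(2, n))
  expect_equal(sm$y_mm, rep(-1, n))

  line <- toy_segment(x = (1:n) * 0.004, y = rep(0, n))
  sml <- rolling_mean_smooth(line, params25)
  interior <- 26:(n - 25)
  expect_equal(sml$x_mm[interior], line$x_mm[interior], tolerance = 1e-12)

  # sinusoid, period 25 frames (1 s), window 50: amplitude suppressed to <= 5%
  wob <- toy_segment(x = (1:n) * 0.004, y = 0.2 * sin(2 * pi * (1:n) / 25))
  smw <- rolling_mean_smooth(wob, params25)
  expect_lt(max(abs(smw$y_mm[interior])), 0.05 * 0.2)
})

test_that("a too-short segment is returned unsmoothed with a warning", {
  short <- toy_segment(x = 1:10, y = rep(0, 10))
  expect_warning(out <- rolling_mean_smooth(short, params25), "window")
  expect_identical(out$x_mm, short$x_mm)
})

test_that("curvature is zero on lines, constant on circles, split across a sharp corner", {
  p0 <- pipeline_params(fps = 25, stillness_floor_mm = 0)
  line <- toy_segment(x = (1:100) * 0.01, y = rep(0, 100))
  expect_equal(compute_curvature(line, p0)$kappa, rep(0, 97))

  # circular arc with angular step delta per frame -> kappa == delta everywhere
  delta <- 0.02
  th <- (1:200) * delta
  circ <- toy_segment(x = 2 * cos(th), y = 2 * sin(th))
  expect_equal(compute_curvature(circ, p0)$kappa, rep(delta, 197),
               tolerance = 1e-9)

  # 90-degree corner in one frame: centered-displacement heading splits the
  # right angle over the two frames flanking the vertex
  xs <- c(seq(-5, 0, by = 1), rep(0, 5))
  ys <- c(rep(0, 6), seq(1, 5, by = 1))
  corner <- toy_segment(x = xs, y = ys)
  k <- compute_curvature(corner, p0)$kappa
  expect_equal(max(k), pi / 4, tolerance = 1e-9)
  expect_equal(sum(k), pi / 2, tolerance = 1e-9)
})

test_that("sub-floor displacements yield zero curvature", {
  jitter <- toy_segment(x = c(0, 1e-5, 0, 1e-5, 0, 1e-5, 0),
                        y = c(0, 1e-5, 1e-5, 0, 0, 1e-5, 0))
  k <- compute_curvature(jitter, pipeline_params(fps = 25))$kappa
  expect_equal(k, rep(0, length(k)))
})

test_that("event detection finds runs, merges near neighbors, records peaks", {
  sep25 <- pipeline_params(fps = 25)  # merge window 1 s = 25 frames

  expect_identical(nrow(detect_reorientations(toy_curvature(rep(0, 100)),
                                              sep25)), 0L)

  one <- toy_curvature(c(rep(0, 20), rep(0.4, 5), rep(0, 20)))
  ev <- detect_reorientations(one, sep25)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$end_frame - ev$start_frame + 1L, 5L)
  expect_equal(ev$peak_curvature, 0.4)

  # two runs 10 frames apart (0.4 s < 1 s) merge; 60 frames apart do not
  near <- toy_curvature(c(rep(0, 10), rep(0.3, 4), rep(0, 10), rep(0.5, 4),
                          rep(0, 10)))
  mev <- detect_reorientations(near, sep25)
  expect_identical(nrow(mev), 1L)
  expect_equal(mev$peak_curvature, 0.5)

  far <- toy_curvature(c(rep(0, 10), rep(0.3, 4), rep(0, 60), rep(0.5, 4),
                         rep(0, 10)))
  expect_identical(nrow(detect_reorientations(far, sep25)), 2L)
})

test_that("reorientation rate is events per track minute", {
  seg <- toy_segment(x = (1:7500) * 0.004, y = rep(0, 7500))  # 5 min
  ev0 <- data.frame(worm_id = integer(0), start_frame = integer(0),
                    end_frame = integer(0), peak_curvature = numeric(0))
  expect_equal(reorientation_rate(ev0, seg)$reorientations_per_minute, 0)
  ev10 <- data.frame(worm_id = 1L, start_frame = seq(100, 1000, length.out = 10),
                     end_frame = seq(105, 1005, length.out = 10),
                     peak_curvature = 0.5)
  expect_equal(reorientation_rate(ev10, seg)$reorientations_per_minute, 2)
})

test_that("locomotion features recover constant speed and stationarity", {
  run <- toy_segment(x = (0:999) * (0.2 / 25), y = rep(0, 1000))
  f <- locomotion_features(run, heading_reference = rep(0, 1000))
  expect_equal(f$speed_10th, 0.2, tolerance = 1e-9)
  expect_equal(f$speed_50th, 0.2, tolerance = 1e-9)
  expect_equal(f$forward_fraction, 1)
  expect_equal(f$backward_fraction, 0)

  still <- toy_segment(x = rep(1, 500), y = rep(1, 500))
  fs <- locomotion_features(still)
  expect_equal(fs$speed_50th, 0)
  expect_equal(fs$paused_fraction, 1)

  # reversed run against the reference orientation
  rev <- toy_segment(x = rev((0:999) * (0.2 / 25)), y = rep(0, 1000))
  fr <- locomotion_features(rev, heading_reference = rep(0, 1000))
  expect_equal(fr$backward_fraction, 1)
})

test_that("median speed on simulated tracks matches the configured run speed", {
  cfg <- foraging_config(n_worms = 5, state = "global", seed = 17, gap_rate = 0)
  sim <- simulate_foraging_tracks(cfg)
  res <- analyze_trajectories(sim$tracks)
  expect_lt(max(abs(res$summary$speed_50th - cfg$run_speed)),
            0.05 * cfg$run_speed)
})

test_that("noiseless planted events are recovered one-to-one", {
  cfg <- foraging_config(n_worms = 5, reorientation_rate = 2, seed = 31,
                         heading_noise = 0, wobble_amplitude = 0, gap_rate = 0)
  sim <- simulate_foraging_tracks(cfg)
  res <- analyze_trajectories(sim$tracks)
  # score isolated events inside the scoreable region: the curvature series
  # excludes just over a second at each track end (partial smoothing windows),
  # and two near-reversals of opposite sign within one smoothing window cancel
  # each other on the smoothed path -- a known limit of rolling-mean smoothing
  margin <- 30
  pl <- sim$truth$planted_events
  pl <- pl[pl$start_frame > margin & pl$end_frame < 300 * 25 - margin, ]
  iso <- vapply(seq_len(nrow(pl)), function(i) {
    same <- pl[pl$worm_id == pl$worm_id[i], ]
    all(abs(same$start_frame - pl$start_frame[i]) %in% c(0) |
          abs(same$start_frame - pl$start_frame[i]) > 50)
  }, logical(1))
  # sensitivity over isolated events; precision against the full truth
  expect_equal(event_match_stats(pl[iso, ], res$events, 25)$sensitivity, 1)
  expect_equal(event_match_stats(sim$truth$planted_events,
                                 res$events, 25)$precision, 1)
})

test_that("recovered mean rate is within Poisson sampling error of the truth", {
  cfg <- foraging_config(n_worms = 20, state = "global", seed = 19)
  sim <- simulate_foraging_tracks(cfg)
  res <- analyze_trajectories(sim$tracks)
  total_min <- sum(res$summary$track_minutes)
  se <- sqrt(1 / total_min)
  expect_lt(abs(mean(res$summary$reorientations_per_minute) - 1), 3 * se)
})

test_that("row order of the input table does not change any output", {
  cfg <- foraging_config(n_worms = 3, duration_s = 90, state = "local",
                         seed = 23)
  sim <- simulate_foraging_tracks(cfg)
  res1 <- analyze_trajectories(sim$tracks)
  shuffled <- sim$tracks[with_seed_shuffle(nrow(sim$tracks)), ]
  attr(shuffled, "fps") <- attr(sim$tracks, "fps")
  res2 <- analyze_trajectories(shuffled)
  expect_equal(res1$events, res2$events, ignore_attr = TRUE)
  expect_equal(res1$summary, res2$summary, ignore_attr = TRUE)
})

test_that("interpolated frames never create supra-threshold curvature on a straight track", {
  frames <- setdiff(0:1499, c(300:349, 900:979))  # 2-s and 3.2-s holes
  tab <- toy_table(frames, x = frames * 0.004, y = frames * 0.002)
  res <- analyze_trajectories(tab)
  expect_identical(nrow(res$events), 0L)
})
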