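test_that("growth curve handles constant, doubling and orphan cases", {
  one <- data.frame(cell_id = "a", parent_id = NA_character_,
                    time_h = (0:9) * 0.5, gfp = 100)
  g <- growth_curve(one)
  expect_equal(g$n_cells, rep(1L, 10))

  # synchronous doubling each frame from one cell
  rows <- list()
  for (f in 0:3) {
    n <- 2^f
    rows[[f + 1]] <- data.frame(
      cell_id = sprintf("f%d_%d", f, seq_len(n)),
      parent_id = if (f == 0) NA_character_ else
        sprintf("f%d_%d", f - 1, rep(seq_len(n / 2), each = 2)),
      time_h = f * 0.5, gfp = 100)
  }
  g2 <- growth_curve(do.call(rbind, rows))
  expect_equal(g2$n_cells, c(1L, 2L, 4L, 8L))

  orphan <- rbind(one,
                  data.frame(cell_id = "x", parent_id = "ghost",
                             time_h = 2, gfp = 100))
  expect_warning(g3 <- growth_curve(orphan), "orphan")
  expect_equal(g3$n_cells[g3$time_h == 2], 2L)
})

test_that("noiseless ramp gives a frame-exact onset with r2 = 1", {
  v <- ramp_trace(onset_h = 24, slope_per_frame = 3, noise_sd = 0)
  t <- (seq_along(v) - 1) * 0.5
  det <- detect_onset(t, v)
  expect_true(det$detected)
  expect_equal(det$onset, 24)
  expect_equal(det$r2, 1, tolerance = 1e-12)
  # rise over the 5-point window: 3 a.u./frame * 4 frames = 12 > 8
  expect_equal(det$slope * 2, 12, tolerance = 1e-10)
})

test_that("flat and too-short traces return the sentinel", {
  set.seed(3)
  t <- (0:95) * 0.5
  flat <- 100 + rnorm(96, 0, 1)
  det <- detect_onset(t, flat)
  expect_false(det$detected)
  expect_equal(det$onset, 1)

  short <- detect_onset((0:5) * 0.5, rep(100, 6))
  expect_false(short$detected)
  expect_equal(short$reason, "too short")
})

test_that("gaps in the frame sequence break regression windows", {
  v <- ramp_trace(onset_h = 24, slope_per_frame = 3, noise_sd = 0)
  t <- (seq_along(v) - 1) * 0.5
  drop <- t < 25 | t > 26.5  # remove 4 frames just after onset
  det <- detect_onset(t[drop], v[drop])
  expect_true(det$detected)
  expect_gt(det$onset, 26.5)  # first full window after the gap
})

test_that("raising thresholds never yields an earlier onset", {
  set.seed(9)
  t <- (0:95) * 0.5
  for (k in 1:10) {
    v <- ramp_trace(onset_h = 20 + 2 * k, slope_per_frame = 6,
                    noise_sd = 1, seed = k)
    o1 <- detect_onset(t, v, onset_params(slope_threshold = 8))
    o2 <- detect_onset(t, v, onset_params(slope_threshold = 16))
    o3 <- detect_onset(t, v, onset_params(r2_threshold = 0.995))
    if (o2$detected) expect_gte(o2$onset, o1$onset)
    if (o3$detected) expect_gte(o3$onset, o1$onset)
  }
})

test_that("moving qq threshold on a single frame equals the snapshot fit", {
  sim <- well_separated_snapshot(n = 2000, f = 0.05, seed = 60)
  norm <- normalize_background(sim$cells)
  frame <- data.frame(cell_id = norm$cell_id, time_h = 12, gfp = norm$gfp)
  mov <- moving_qq_threshold(frame, "gfp")
  snap <- qq_fit(norm$gfp, ids = norm$cell_id)
  expect_equal(mov$summary$fraction, snap$subpop_fraction)
  expect_setequal(mov$members$cell_id, snap$subpop_ids)
})

test_that("subpopulation size rises only after the activation window opens", {
  sim <- simulate_timelapse(timelapse_params(
    n_initial_cells = 20, activation_prob = 0.3,
    activation_window_h = c(25, 35), carryover_fraction = 0, seed = 13))
  mov <- moving_qq_threshold(sim$traces, "gfp")
  s <- mov$summary
  early <- s$fraction[s$time_h < 24 & !is.na(s$fraction)]
  late <- s$fraction[s$time_h > 40 & !is.na(s$fraction)]
  # early cross-sections hold few cells, so allow one spurious cell
  expect_lt(median(early), 0.05)
  expect_gt(median(late), 0.15)
})

test_that("carry-over filtering removes pre-activated lineages only", {
  none <- simulate_timelapse(timelapse_params(
    n_initial_cells = 20, carryover_fraction = 0, activation_prob = 0,
    seed = 17))
  kept <- filter_carryover(none$traces, "gfp")
  expect_equal(length(attr(kept, "removed_ids")), 0)

  some <- simulate_timelapse(timelapse_params(
    n_initial_cells = 40, carryover_fraction = 0.05, activation_prob = 0,
    seed = 19))
  filt <- filter_carryover(some$traces, "gfp")
  carry <- some$truth$cell_id[some$truth$carryover]
  expect_gt(length(carry), 0)
  expect_gte(mean(carry %in% attr(filt, "removed_ids")), 0.9)

  # a cell first appearing after the window is never removed
  late_ids <- names(which(tapply(some$traces$time_h,
                                 some$traces$cell_id, min) > 10))
  expect_false(any(late_ids %in% attr(filt, "removed_ids")))
})

test_that("carry-over and minimum-length filters commute", {
  sim <- simulate_timelapse(timelapse_params(
    n_initial_cells = 20, carryover_fraction = 0.1, activation_prob = 0.2,
    seed = 23))
  p <- onset_params()
  a <- filter_min_points(filter_carryover(sim$traces, "gfp", p),
                         p$min_trace_points)
  b <- filter_carryover(filter_min_points(sim$traces, p$min_trace_points),
                        "gfp", p)
  attr(a, "removed_ids") <- NULL; attr(b, "removed_ids") <- NULL
  expect_equal(a, b)
})

test_that("the data-driven slope threshold separates noise from ramps", {
  set.seed(29)
  t <- (0:95) * 0.5
  noise_rises <- unlist(lapply(1:30, function(k)
    pool_window_rises(data.frame(cell_id = "c", time_h = t,
                                 gfp = 100 + rnorm(96, 0, 1)), "gfp")))
  thr <- slope_null_threshold(noise_rises)
  expect_identical(thr$source, "data")
  expect_gte(mean(noise_rises < thr$threshold), 0.98)

  # with ramping traces in the pool, the threshold stays below true rises
  ramps <- do.call(rbind, lapply(1:20, function(k)
    data.frame(cell_id = sprintf("r%d", k), time_h = t,
               gfp = ramp_trace(onset_h = 30, slope_per_frame = 10,
                                noise_sd = 1, seed = k))))
  mixed <- c(noise_rises, pool_window_rises(ramps, "gfp"))
  thr2 <- slope_null_threshold(mixed)
  expect_lt(thr2$threshold, 10 * 4)  # true window rise is 40 a.u.

  fallback <- slope_null_threshold(numeric(0))
  expect_identical(fallback$source, "fallback")
  expect_equal(fallback$threshold, 8)
})

test_that("paired onsets carry sentinels and recover the designed lag", {
  sim <- simulate_timelapse(timelapse_params(
    n_initial_cells = 20, activation_prob = 0.5, carryover_fraction = 0,
    channel_delay_mu = 4, channel_delay_sd = 0, seed = 31))
  act <- sim$truth$cell_id[sim$truth$activated]
  po <- pair_onsets(sim$traces, cell_ids = act)
  expect_equal(po$median_lag_h, 2, tolerance = 0.51)  # 4 frames = 2 h

  # a flat cell shows the sentinel in both channels
  quiet <- sim$truth$cell_id[!sim$truth$activated & sim$truth$terminal][1]
  po2 <- pair_onsets(sim$traces, cell_ids = quiet)
  expect_equal(po2$onsets$onset_gfp, 1)
  expect_false(po2$onsets$detected_gfp)
})

test_that("end-to-end pipeline recovers the designed activated fraction", {
  sim <- simulate_timelapse(timelapse_params(
    n_initial_cells = 30, activation_prob = 0.05,
    carryover_fraction = 0, seed = 37))
  res <- timelapse_analysis(sim$traces)
  final <- tail(stats::na.omit(res$moving$gfp$summary$fraction), 1)
  expect_lt(abs(final - 0.05), 0.02)
})
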