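test_that("snapshot generator respects degenerate and sampled fractions", {
  all_low <- simulate_snapshot(snapshot_params(n_cells = 100,
                                               sub_fraction = 0, seed = 1))
  expect_false(any(all_low$truth$high))
  all_high <- simulate_snapshot(snapshot_params(n_cells = 100,
                                                sub_fraction = 1, seed = 1))
  expect_true(all(all_high$truth$high))

  sim <- simulate_snapshot(snapshot_params(n_cells = 10000,
                                           sub_fraction = 0.05, seed = 42))
  realized <- mean(sim$truth$high)
  # binomial sampling bound: 3 * sqrt(p (1 - p) / n)
  expect_lt(abs(realized - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("snapshot output is deterministic given the seed and carries images", {
  a <- simulate_snapshot(snapshot_params(seed = 7))
  b <- simulate_snapshot(snapshot_params(seed = 7))
  expect_identical(a, b)
  expect_equal(sort(unique(a$cells$image_id)), sprintf("img%02d", 1:8))
  # per-image background is constant within an image
  per_img <- tapply(a$cells$bg_gfp, a$cells$image_id,
                    function(x) length(unique(x)))
  expect_true(all(per_img == 1))
})

test_that("snapshot params are validated", {
  expect_error(snapshot_params(n_cells = 3), "n_cells")
  expect_error(snapshot_params(sub_fraction = 1.2), "sub_fraction")
  expect_error(snapshot_params(main_sigma = 0), "sigmas")
})

test_that("paired generator realizes the designed overlap", {
  identical_sets <- simulate_paired_snapshot(
    paired_params(overlap_design = 1, seed = 1))
  expect_identical(identical_sets$truth$high_gfp,
                   identical_sets$truth$high_mcherry)

  disjoint <- simulate_paired_snapshot(
    paired_params(overlap_design = 0, seed = 1))
  expect_false(any(disjoint$truth$high_gfp & disjoint$truth$high_mcherry))

  p <- paired_params(
    gfp = snapshot_params(n_cells = 10000, channel = "gfp"),
    mcherry = snapshot_params(n_cells = 10000, channel = "mcherry"),
    overlap_design = 0.8, seed = 3)
  sim <- simulate_paired_snapshot(p)
  h1 <- sim$truth$high_gfp; h2 <- sim$truth$high_mcherry
  jacc <- sum(h1 & h2) / sum(h1 | h2)
  expect_lt(abs(jacc - 0.8), 0.05)
})

test_that("timelapse population doubles per division and lineage is a tree", {
  sim <- simulate_timelapse(timelapse_params(n_initial_cells = 10,
                                             n_divisions = 4, seed = 11))
  g <- growth_curve(sim$traces)
  expect_equal(g$n_cells[1], 10)
  final <- tail(g$n_cells, 1)
  expect_lt(abs(final - 160) / 160, 0.2)

  # every non-root cell has exactly one parent present in the data
  first <- sim$traces[!duplicated(sim$traces$cell_id), ]
  non_root <- first[!is.na(first$parent_id), ]
  expect_true(all(non_root$parent_id %in% sim$traces$cell_id))
  # times strictly increase along every trace
  ok <- tapply(sim$traces$time_h, sim$traces$cell_id,
               function(t) all(diff(t) > 0))
  expect_true(all(ok))
})

test_that("timelapse traces ramp exactly from the truth onset when noiseless", {
  sim <- simulate_timelapse(timelapse_params(
    n_initial_cells = 4, activation_prob = 1, noise_sd = 0,
    ramp_slope_sd = 0, carryover_fraction = 0, channel_delay_sd = 0,
    seed = 2))
  act <- sim$truth[sim$truth$activated, ]
  expect_gt(nrow(act), 0)
  cell <- act[1, ]
  tr <- sim$traces[sim$traces$cell_id == cell$cell_id, ]
  after <- tr$time_h >= cell$onset_gfp_h
  expect_true(any(after))
  # slope in a.u. per frame (frames are 0.5 h apart)
  d <- diff(tr$gfp[after]) / diff(tr$time_h[after]) * 0.5
  expect_equal(d, rep(cell$slope_gfp, length(d)), tolerance = 1e-10)
  before <- tr$gfp[!after]
  expect_true(all(before == 100))
})

test_that("activation_prob = 0 yields no in-movie onsets", {
  sim <- simulate_timelapse(timelapse_params(activation_prob = 0,
                                             carryover_fraction = 0,
                                             seed = 5))
  expect_false(any(sim$truth$activated))
  expect_true(all(is.na(sim$truth$onset_gfp_h)))
})

test_that("count generator matches its design", {
  # equal size factors, no DE: column medians are close
  sim <- simulate_counts(counts_params(n_genes = 2000, seed = 1))
  med <- apply(sim$counts, 2, median)
  expect_lt(diff(range(med)) / median(med), 0.15)

  # dispersion -> 0 limit: per-gene variance tracks the mean (Poisson)
  pois <- simulate_counts(counts_params(n_genes = 3000, dispersion = 0,
                                        gene_spread_sdlog = 0, seed = 2))
  expect_lt(abs(var(as.vector(pois$counts)) /
                  mean(pois$counts) - 1), 0.1)

  # designed 2x size factor recovered by median-of-ratios
  sf <- simulate_counts(counts_params(
    n_genes = 1000, n_samples = 4, size_factors = c(1, 1, 2, 2),
    group = c("A", "A", "B", "B"), seed = 3))
  est <- pseudoreference_normalize(sf$counts)$size_factors
  expect_lt(abs(est[3] / est[1] - 2) / 2, 0.1)
})
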