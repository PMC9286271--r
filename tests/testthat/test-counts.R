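test_that("pseudoreference factors match the hand-computed example", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- pseudoreference_normalize(m)$size_factors
  expect_equal(unname(sf), c(sqrt(2) / 2, sqrt(2)), tolerance = 1e-12)
})

test_that("pseudoreference agrees with a brute-force oracle", {
  set.seed(101)
  for (k in 1:100) {
    m <- matrix(rpois(5 * 4, lambda = sample(5:200, 1)), 5, 4)
    if (!any(apply(m, 1, function(r) all(r > 0)))) next
    got <- unname(pseudoreference_normalize(m)$size_factors)
    want <- brute_force_size_factors(m)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("size factors are equivariant to scaling one sample", {
  set.seed(5)
  m <- matrix(rpois(200, 50), 50, 4)
  base <- pseudoreference_normalize(m)$size_factors
  m2 <- m; m2[, 2] <- m2[, 2] * 4
  scaled <- pseudoreference_normalize(m2)$size_factors
  # its own factor scales by c^(1 - 1/n); all factors shift by the
  # pseudoreference's c^(1/n)
  expect_equal(scaled[2] / base[2] / (scaled[1] / base[1]), 4,
               tolerance = 1e-12)
  # identical samples get factor 1
  ident <- cbind(a = c(3, 7, 11), b = c(3, 7, 11))
  expect_equal(unname(pseudoreference_normalize(ident)$size_factors),
               c(1, 1))
})

test_that("pseudoreference matches DESeq2's estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  # odd gene count: DESeq2 takes the median in log space, which differs
  # from the plain ratio median only when the median averages two genes
  m <- matrix(rnbinom(606, mu = 100, size = 10), 101, 6)
  ours <- unname(pseudoreference_normalize(m)$size_factors)
  ref <- unname(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("all-zero-containing matrices are rejected", {
  m <- cbind(c(0, 5), c(3, 0))
  expect_error(pseudoreference_normalize(m), "nonzero")
})

test_that("log2p1 transform handles zeros and rejects negatives", {
  expect_equal(log2p1(c(0, 1, 3)), c(0, 1, 2))
  expect_error(log2p1(-1), "non-negative")
})

test_that("region fold changes hit designed effects and closed forms", {
  m <- cbind(a1 = c(8, 100), a2 = c(8, 100),
             b1 = c(2, 100), b2 = c(2, 100))
  rownames(m) <- c("g1", "g2")
  fc <- region_log2fc(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fc$genes$log2fc, c(2, 0))

  sim <- simulate_counts(counts_params(
    n_genes = 400, de_gene_idx = 1:40, log2fc = 1.5, seed = 55))
  norm <- pseudoreference_normalize(sim$counts)
  grp <- sim$truth$group
  fc2 <- region_log2fc(norm, colnames(sim$counts)[grp == "B"],
                       colnames(sim$counts)[grp == "A"])
  expect_lt(abs(mean(fc2$genes$log2fc[1:40]) - 1.5), 0.2)

  # zero denominator falls back to log-space difference and is flagged
  z <- cbind(a = c(4, 10), b = c(0, 10))
  rownames(z) <- c("gz", "go")
  fcz <- region_log2fc(z, "a", "b")
  expect_true(fcz$genes$flagged[1])
  expect_equal(fcz$genes$log2fc[1], log2(5) - 0)
})

test_that("bootstrap t-test is deterministic, calibrated at the edges", {
  set.seed(61)
  a <- matrix(rnorm(40), 10, 4)
  b <- a  # identical groups
  r1 <- bootstrap_ttest(a, b, n_boot = 200, seed = 3)
  r2 <- bootstrap_ttest(a, b, n_boot = 200, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p_value >= 0.5))

  # a huge shift reaches the resolution floor 2/(n_boot+1)
  shift <- matrix(rnorm(16, 100), 4, 4)
  null <- matrix(rnorm(16), 4, 4)
  r3 <- bootstrap_ttest(shift, null, n_boot = 500, seed = 4)
  expect_true(all(r3$p_value <= 2 / 501))

  # degenerate variance falls back to permutation and is flagged
  cst <- matrix(1, 3, 4)
  r4 <- bootstrap_ttest(cst, cst, n_boot = 100, seed = 5)
  expect_true(all(r4$flagged))
  expect_true(all(r4$p_value == 1))
})

test_that("95th-percentile comparison detects a designed tail shift", {
  set.seed(71)
  delta <- 50
  induced <- lapply(1:4, function(i) rlnorm(2000, 3, 0.5) + delta)
  control <- lapply(1:4, function(i) rlnorm(2000, 3, 0.5))
  res <- percentile95_compare(induced, control)
  expect_lt(abs(res$mean_difference - delta) / delta, 0.15)
  expect_lt(res$p_value, 0.01)

  # identical paired distributions: no signal
  same <- lapply(1:3, function(i) rnorm(500, 10))
  res2 <- percentile95_compare(same, same)
  expect_equal(res2$mean_difference, 0)
  expect_true(res2$degenerate)

  expect_error(percentile95_compare(list(rnorm(10)), list(rnorm(10))),
               ">= 2")
})
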