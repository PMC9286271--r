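#' @keywords internal
#' @import stats
#' @importFrom graphics lines
"_PACKAGE"

## Parameter constructors ----------------------------------------------------

#' Parameters for a synthetic snapshot population
#'
#' Describes a stationary-phase snapshot of ~1000 segmented cells spread over
#' a handful of microscope images: a dominant main population of cells with
#' low, right-skewed fluorescence just above the image background, plus a
#' small high-expressing (transfer-competent) subpopulation.
#'
#' Intensities are generated as `background(image) + population draw`, so the
#' analysis pipeline (not the generator) performs background subtraction.
#' `main_mu`/`main_sigma` and `sub_mu`/`sub_sigma` are the mean and standard
#' deviation of the above-background intensity in arbitrary camera units; with
#' `family = "lognormal"` they parameterize a lognormal via moment matching.
#'
#' @param n_cells Total number of cells across all images (>= 4).
#' @param n_images Number of microscope images the cells are split over.
#' @param background_mean,background_sd Per-image background intensity
#'   distribution (a.u.); each image draws one background level.
#' @param main_mu,main_sigma Mean and sd of the main-population intensity
#'   above background (a.u.).
#' @param sub_fraction Expected proportion of high-expressing cells in `[0,1]`.
#' @param sub_mu,sub_sigma Mean and sd of the subpopulation intensity above
#'   background (a.u.).
#' @param family Distribution family for the above-background draws:
#'   `"lognormal"` (default; fluorescence distributions are strongly
#'   right-tailed) or `"normal"`.
#' @param channel Channel name used for the intensity column (e.g. `"gfp"`).
#' @param seed Integer seed; fixing it makes the output byte-identical.
#' @return An object of class `snapshot_params`.
#' @export
snapshot_params <- function(n_cells = 1000, n_images = 8,
                            background_mean = 100, background_sd = 5,
                            main_mu = 20, main_sigma = 8,
                            sub_fraction = 0.05,
                            sub_mu = 200, sub_sigma = 40,
                            family = c("lognormal", "normal"),
                            channel = "gfp", seed = NULL) {
  family <- match.arg(family)
  p <- list(n_cells = n_cells, n_images = n_images,
            background_mean = background_mean, background_sd = background_sd,
            main_mu = main_mu, main_sigma = main_sigma,
            sub_fraction = sub_fraction, sub_mu = sub_mu,
            sub_sigma = sub_sigma, family = family, channel = channel,
            seed = seed)
  validate_snapshot_params(p)
  structure(p, class = "snapshot_params")
}

validate_snapshot_params <- function(p) {
  stopifnot(
    "n_cells must be >= 4" = p$n_cells >= 4,
    "n_images must be >= 1" = p$n_images >= 1,
    "sub_fraction must be in [0,1]" =
      p$sub_fraction >= 0 && p$sub_fraction <= 1,
    "sigmas must be > 0" = p$main_sigma > 0 && p$sub_sigma > 0,
    "background_mean must be > 0" = p$background_mean > 0
  )
  invisible(p)
}

#' Parameters for a paired two-channel snapshot
#'
#' Two reporters measured in the same cells. `overlap_design` is the target
#' Jaccard overlap `|both high| / |high in either|` of the two true high
#' sets; the generator realizes it by construction, so the recovered overlap
#' of a perfect classifier equals the design up to rounding.
#'
#' @param gfp,mcherry `snapshot_params` for each channel; `n_cells` and
#'   `n_images` must agree.
#' @param overlap_design Target Jaccard overlap of the true high sets, in
#'   `[0,1]`.
#' @param seed Integer seed.
#' @return An object of class `paired_params`.
#' @export
paired_params <- function(gfp = snapshot_params(channel = "gfp"),
                          mcherry = snapshot_params(channel = "mcherry"),
                          overlap_design = 0.5, seed = NULL) {
  stopifnot(
    "overlap_design must be in [0,1]" =
      overlap_design >= 0 && overlap_design <= 1,
    "channel params must agree on n_cells" = gfp$n_cells == mcherry$n_cells,
    "channel params must agree on n_images" = gfp$n_images == mcherry$n_images,
    "channel names must differ" = !identical(gfp$channel, mcherry$channel)
  )
  structure(list(gfp = gfp, mcherry = mcherry,
                 overlap_design = overlap_design, seed = seed),
            class = "paired_params")
}

#' Parameters for a synthetic time-lapse experiment
#'
#' Emulates surface-grown microcolonies imaged every `frame_interval` minutes
#' for ~48 h: roughly `n_divisions` synchronous-with-jitter divisions during
#' exponential growth, then stationary phase during which individual cells
#' stochastically activate and their fluorescence ramps up linearly.
#' A configurable fraction of founder cells is already activated at t = 0
#' (carry-over from the preceding stationary-phase preculture); carried-over
#' cells do not divide (activated cells arrest division in this system).
#'
#' @param n_initial_cells Founder cells at frame 0.
#' @param frame_interval Imaging interval in minutes.
#' @param n_frames Number of frames (96 frames at 30 min is 48 h).
#' @param n_divisions Divisions before stationary phase.
#' @param stationary_h Time (hours) at which growth stops.
#' @param division_jitter_frames Uniform jitter (frames) on division times.
#' @param activation_window_h Two-element `[start, end]` window (hours) in
#'   which activation onsets are drawn uniformly.
#' @param activation_prob Probability that a terminal-generation cell
#'   activates.
#' @param baseline Baseline fluorescence (camera greyscale a.u.).
#' @param ramp_slope_mu,ramp_slope_sd Per-frame fluorescence ramp slope of
#'   activated cells (a.u./frame), truncated at 0.
#' @param noise_sd Additive per-frame measurement noise sd (a.u.).
#' @param carryover_fraction Fraction of founder cells pre-activated at t=0.
#' @param channel_delay_mu,channel_delay_sd Delay (frames, Gaussian truncated
#'   at 0) of the second channel's onset after the first.
#' @param n_positions Number of imaging positions founders are spread over.
#' @param channels Names of the two fluorescence channels.
#' @param seed Integer seed.
#' @return An object of class `timelapse_params`.
#' @export
timelapse_params <- function(n_initial_cells = 10, frame_interval = 30,
                             n_frames = 96, n_divisions = 4,
                             stationary_h = 20, division_jitter_frames = 1,
                             activation_window_h = c(20, 30),
                             activation_prob = 0.05,
                             baseline = 100,
                             ramp_slope_mu = 10, ramp_slope_sd = 2,
                             noise_sd = 1,
                             carryover_fraction = 0.02,
                             channel_delay_mu = 0, channel_delay_sd = 0,
                             n_positions = 8,
                             channels = c("gfp", "mcherry"), seed = NULL) {
  stopifnot(
    "frame_interval must be > 0" = frame_interval > 0,
    "carryover_fraction must be in [0,1]" =
      carryover_fraction >= 0 && carryover_fraction <= 1,
    "activation_prob must be in [0,1]" =
      activation_prob >= 0 && activation_prob <= 1,
    "activation_window_h must be [start, end]" =
      length(activation_window_h) == 2 &&
      activation_window_h[1] <= activation_window_h[2],
    "need two channel names" = length(channels) == 2,
    "n_initial_cells must be >= 1" = n_initial_cells >= 1
  )
  structure(list(n_initial_cells = n_initial_cells,
                 frame_interval = frame_interval, n_frames = n_frames,
                 n_divisions = n_divisions, stationary_h = stationary_h,
                 division_jitter_frames = division_jitter_frames,
                 activation_window_h = activation_window_h,
                 activation_prob = activation_prob, baseline = baseline,
                 ramp_slope_mu = ramp_slope_mu, ramp_slope_sd = ramp_slope_sd,
                 noise_sd = noise_sd, carryover_fraction = carryover_fraction,
                 channel_delay_mu = channel_delay_mu,
                 channel_delay_sd = channel_delay_sd,
                 n_positions = n_positions, channels = channels, seed = seed),
            class = "timelapse_params")
}

#' Parameters for a synthetic gene-by-sample count matrix
#'
#' Negative-binomial counts with known per-sample size factors and designed
#' log2 fold changes on a chosen gene set between two sample groups.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param baseline_mean Median gene-level expected count before scaling.
#' @param gene_spread_sdlog Lognormal sd of per-gene base means.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @param size_factors True per-sample size factors (> 0).
#' @param group Group label per sample (two levels; fold changes apply to the
#'   second level).
#' @param de_gene_idx Indices of differentially expressed genes.
#' @param log2fc Designed log2 fold change per DE gene (recycled).
#' @param seed Integer seed.
#' @return An object of class `counts_params`.
#' @export
counts_params <- function(n_genes = 500, n_samples = 8,
                          baseline_mean = 100, gene_spread_sdlog = 1,
                          dispersion = 0.05,
                          size_factors = rep(1, n_samples),
                          group = rep(c("A", "B"), each = n_samples / 2),
                          de_gene_idx = integer(), log2fc = numeric(),
                          seed = NULL) {
  stopifnot(
    "size factors must be > 0" = all(size_factors > 0),
    "one size factor per sample" = length(size_factors) == n_samples,
    "one group label per sample" = length(group) == n_samples,
    "dispersion must be >= 0" = dispersion >= 0,
    "de_gene_idx within range" =
      all(de_gene_idx >= 1 & de_gene_idx <= n_genes)
  )
  if (length(de_gene_idx) > 0 && length(log2fc) == 0)
    stop("log2fc required when de_gene_idx is given")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 baseline_mean = baseline_mean,
                 gene_spread_sdlog = gene_spread_sdlog,
                 dispersion = dispersion, size_factors = size_factors,
                 group = group, de_gene_idx = de_gene_idx,
                 log2fc = rep_len(log2fc, length(de_gene_idx)), seed = seed),
            class = "counts_params")
}

## Generators ----------------------------------------------------------------

rpop <- function(n, mu, sigma, family) {
  if (n == 0) return(numeric(0))
  if (family == "lognormal") {
    sdlog <- sqrt(log1p((sigma / mu)^2))
    rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    rnorm(n, mu, sigma)
  }
}

#' Simulate a snapshot cell table with known subpopulation labels
#'
#' @param params A [snapshot_params()] object.
#' @return A list with class `snapshot_sim`:
#'   * `cells`: data.frame `cell_id`, `image_id`, `<channel>` raw intensity,
#'     `bg_<channel>` per-image background.
#'   * `truth`: data.frame `cell_id`, `high` (logical ground-truth label).
#'   * `params`: the input parameters.
#' @examples
#' sim <- simulate_snapshot(snapshot_params(n_cells = 200, seed = 1))
#' head(sim$cells)
#' mean(sim$truth$high)
#' @export
simulate_snapshot <- function(params) {
  validate_snapshot_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_cells
  image <- rep_len(seq_len(params$n_images), n)
  bg <- abs(rnorm(params$n_images, params$background_mean,
                  params$background_sd))
  high <- runif(n) < params$sub_fraction
  draw <- numeric(n)
  draw[!high] <- rpop(sum(!high), params$main_mu, params$main_sigma,
                      params$family)
  draw[high] <- rpop(sum(high), params$sub_mu, params$sub_sigma,
                     params$family)
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    image_id = sprintf("img%02d", image),
    stringsAsFactors = FALSE
  )
  cells[[params$channel]] <- bg[image] + draw
  cells[[paste0("bg_", params$channel)]] <- bg[image]
  truth <- data.frame(cell_id = cells$cell_id, high = high,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, truth = truth, params = params),
            class = "snapshot_sim")
}

#' Simulate a paired two-channel snapshot with designed overlap
#'
#' High-state labels for the two channels are placed so that the Jaccard
#' overlap of the two true high sets equals `overlap_design` up to rounding.
#'
#' @param params A [paired_params()] object.
#' @return A list with class `paired_sim`: `cells` (both channels and both
#'   per-image backgrounds), `truth` (`cell_id`, `high_gfp`, `high_mcherry`
#'   using the configured channel names), `params`.
#' @export
simulate_paired_snapshot <- function(params) {
  stopifnot(inherits(params, "paired_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p1 <- params$gfp; p2 <- params$mcherry
  n <- p1$n_cells
  s1 <- round(p1$sub_fraction * n)
  s2 <- round(p2$sub_fraction * n)
  J <- params$overlap_design
  b <- round(J * (s1 + s2) / (1 + J))
  b <- max(b, s1 + s2 - n)
  b <- min(b, s1, s2)
  perm <- sample.int(n)
  both <- perm[seq_len(b)]
  only1 <- perm[seq_len(s1 - b) + b]
  only2 <- perm[seq_len(s2 - b) + s1]
  high1 <- logical(n); high1[c(both, only1)] <- TRUE
  high2 <- logical(n); high2[c(both, only2)] <- TRUE

  image <- rep_len(seq_len(p1$n_images), n)
  cells <- data.frame(
    cell_id = sprintf("c%05d", seq_len(n)),
    image_id = sprintf("img%02d", image),
    stringsAsFactors = FALSE
  )
  for (ch in list(list(p = p1, high = high1), list(p = p2, high = high2))) {
    p <- ch$p
    bg <- abs(rnorm(p$n_images, p$background_mean, p$background_sd))
    draw <- numeric(n)
    draw[!ch$high] <- rpop(sum(!ch$high), p$main_mu, p$main_sigma, p$family)
    draw[ch$high] <- rpop(sum(ch$high), p$sub_mu, p$sub_sigma, p$family)
    cells[[p$channel]] <- bg[image] + draw
    cells[[paste0("bg_", p$channel)]] <- bg[image]
  }
  truth <- data.frame(cell_id = cells$cell_id, stringsAsFactors = FALSE)
  truth[[paste0("high_", p1$channel)]] <- high1
  truth[[paste0("high_", p2$channel)]] <- high2
  structure(list(cells = cells, truth = truth, params = params),
            class = "paired_sim")
}

#' Simulate a tracked time-lapse experiment with known activation onsets
#'
#' Founder cells divide `n_divisions` times at jittered, evenly spaced times
#' until `stationary_h`; terminal-generation cells then activate with
#' probability `activation_prob` at a uniform time in `activation_window_h`,
#' after which their fluorescence ramps linearly (slope in a.u./frame) on top
#' of baseline noise. The second channel's onset lags by a truncated-Gaussian
#' number of frames. Carried-over cells are activated before t = 0 and do
#' not divide.
#'
#' @param params A [timelapse_params()] object.
#' @return A list with class `timelapse_sim`:
#'   * `traces`: long data.frame `cell_id`, `parent_id`, `position`,
#'     `time_h`, one column per channel.
#'   * `truth`: per-cell `cell_id`, `terminal`, `carryover`, `activated`,
#'     `onset_<ch1>_h`, `onset_<ch2>_h` (NA where not activated or
#'     pre-movie), slopes per channel.
#'   * `params`.
#' @export
simulate_timelapse <- function(params) {
  stopifnot(inherits(params, "timelapse_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  dt_h <- params$frame_interval / 60
  times <- (seq_len(params$n_frames) - 1) * dt_h
  ch1 <- params$channels[1]; ch2 <- params$channels[2]

  n0 <- params$n_initial_cells
  n_carry <- round(params$carryover_fraction * n0)
  carry0 <- seq_len(n0) <= n_carry   # founders are exchangeable

  div_every_h <- params$stationary_h / max(params$n_divisions, 1)
  jit <- params$division_jitter_frames * dt_h

  ## Build the lineage tree breadth-first.
  cells <- list()
  nid <- 0L
  new_cell <- function(parent, pos, birth_h, gen, carry) {
    nid <<- nid + 1L
    list(id = sprintf("t%05d", nid), parent = parent, pos = pos,
         birth = birth_h, gen = gen, carry = carry)
  }
  queue <- lapply(seq_len(n0), function(i)
    new_cell(NA_character_, ((i - 1L) %% params$n_positions) + 1L, 0, 0L,
             carry0[i]))
  out <- list()
  while (length(queue) > 0) {
    cell <- queue[[1]]; queue <- queue[-1]
    divides <- !cell$carry && cell$gen < params$n_divisions
    if (divides) {
      div_h <- (cell$gen + 1) * div_every_h + runif(1, -jit, jit)
      div_h <- min(max(div_h, cell$birth + dt_h), params$stationary_h)
      cell$death <- div_h
      for (k in 1:2)
        queue[[length(queue) + 1L]] <-
          new_cell(cell$id, cell$pos, div_h, cell$gen + 1L, FALSE)
    } else {
      cell$death <- Inf
    }
    out[[length(out) + 1L]] <- cell
  }

  ## Per-cell activation truth (terminal cells only).
  n_cells <- length(out)
  truth <- data.frame(
    cell_id = vapply(out, `[[`, "", "id"),
    parent_id = vapply(out, `[[`, "", "parent"),
    position = vapply(out, function(c) sprintf("pos%02d", c$pos), ""),
    terminal = vapply(out, function(c) is.infinite(c$death), TRUE),
    carryover = vapply(out, `[[`, TRUE, "carry"),
    stringsAsFactors = FALSE
  )
  act <- truth$terminal & !truth$carryover &
    runif(n_cells) < params$activation_prob
  truth$activated <- act | truth$carryover

  onset1 <- rep(NA_real_, n_cells)
  onset1[act] <- snap_to_grid(
    runif(sum(act), params$activation_window_h[1],
          params$activation_window_h[2]), dt_h)
  onset1[truth$carryover] <- -5  # ramped up in the preculture
  delay <- pmax(0, round(rnorm(n_cells, params$channel_delay_mu,
                               params$channel_delay_sd))) * dt_h
  onset2 <- onset1 + ifelse(is.na(onset1), 0, delay)
  slope1 <- pmax(rnorm(n_cells, params$ramp_slope_mu, params$ramp_slope_sd),
                 0.1 * params$ramp_slope_mu)
  slope2 <- pmax(rnorm(n_cells, params$ramp_slope_mu, params$ramp_slope_sd),
                 0.1 * params$ramp_slope_mu)
  truth[[paste0("onset_", ch1, "_h")]] <- onset1
  truth[[paste0("onset_", ch2, "_h")]] <- onset2
  truth[[paste0("slope_", ch1)]] <- ifelse(truth$activated, slope1, NA_real_)
  truth[[paste0("slope_", ch2)]] <- ifelse(truth$activated, slope2, NA_real_)

  ## Emit observations.
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cell <- out[[i]]
    sel <- times >= cell$birth - 1e-9 & times < cell$death - 1e-9
    tt <- times[sel]
    if (length(tt) == 0) next
    mk_channel <- function(onset, slope) {
      v <- rep(params$baseline, length(tt))
      if (truth$activated[i] && !is.na(onset)) {
        up <- tt >= onset - 1e-9
        v[up] <- v[up] + (tt[up] - onset) / dt_h * slope
      }
      v + rnorm(length(tt), 0, params$noise_sd)
    }
    df <- data.frame(cell_id = cell$id, parent_id = cell$parent,
                     position = sprintf("pos%02d", cell$pos), time_h = tt,
                     stringsAsFactors = FALSE)
    df[[ch1]] <- mk_channel(onset1[i], slope1[i])
    df[[ch2]] <- mk_channel(onset2[i], slope2[i])
    rows[[i]] <- df
  }
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  structure(list(traces = traces, truth = truth, params = params),
            class = "timelapse_sim")
}

snap_to_grid <- function(t_h, dt_h) round(t_h / dt_h) * dt_h

#' Simulate a count matrix with known size factors and fold changes
#'
#' @param params A [counts_params()] object.
#' @return A list with class `counts_sim`: `counts` (integer matrix, genes x
#'   samples), `truth` (list: `size_factors`, `group`, `de_gene_idx`,
#'   `log2fc`, `base_means`), `params`.
#' @export
simulate_counts <- function(params) {
  stopifnot(inherits(params, "counts_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g <- params$n_genes; s <- params$n_samples
  base <- params$baseline_mean *
    rlnorm(g, -params$gene_spread_sdlog^2 / 2, params$gene_spread_sdlog)
  lfc <- rep(0, g)
  lfc[params$de_gene_idx] <- params$log2fc
  grp2 <- params$group == unique(params$group)[2]
  mu <- outer(base, params$size_factors) *
    2^outer(lfc, as.numeric(grp2))
  counts <- matrix(0L, g, s)
  if (params$dispersion > 0) {
    counts[] <- rnbinom(g * s, mu = mu, size = 1 / params$dispersion)
  } else {
    counts[] <- rpois(g * s, mu)
  }
  dimnames(counts) <- list(sprintf("g%04d", seq_len(g)),
                           sprintf("s%d", seq_len(s)))
  structure(list(counts = counts,
                 truth = list(size_factors = params$size_factors,
                              group = params$group,
                              de_gene_idx = params$de_gene_idx,
                              log2fc = params$log2fc, base_means = base),
                 params = params),
            class = "counts_sim")
}
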