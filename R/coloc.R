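## Two-reporter colocalization: per-channel qq thresholds on the same cells,
## quadrant classification, and the overlap proportion of the two detected
## subpopulations.

#' Scale fluorescence to percent of the channel maximum
#'
#' Maps each raw value F to `(F - I) / (Fmax - I) * 100`, where I is the
#' background and Fmax the channel maximum, so paired-channel scatter plots
#' share a 0-100 axis.
#'
#' @param values Raw intensities.
#' @param background Background intensity I (scalar or per-value).
#' @param fmax Channel maximum; default `max(values)`.
#' @return Values on the percent scale; the maximum maps to 100.
#' @export
scale_to_max <- function(values, background, fmax = max(values)) {
  if (any(fmax <= background)) stop("channel maximum must exceed background")
  (values - background) / (fmax - background) * 100
}

#' Classify cells into expression quadrants
#'
#' Each cell is assigned to exactly one of four quadrants according to
#' whether it is high in each channel. Membership is given either as the
#' detected subpopulation id sets (from [qq_fit()] per channel) or as scalar
#' intensity thresholds compared with strict `>`, so a cell exactly on a
#' threshold falls on the low side.
#'
#' @param cells Paired-channel data frame with `cell_id` and both channel
#'   columns.
#' @param channels Length-2 channel column names.
#' @param high_ids Optional list of two id vectors (high cells per channel).
#' @param thresholds Optional numeric length-2 scalar thresholds (used when
#'   `high_ids` is NULL).
#' @return A named integer vector `both_high`, `<ch1>_only`, `<ch2>_only`,
#'   `both_low`; the counts sum to `nrow(cells)`.
#' @export
classify_quadrants <- function(cells, channels = c("gfp", "mcherry"),
                               high_ids = NULL, thresholds = NULL) {
  stopifnot(length(channels) == 2,
            all(channels %in% names(cells)))
  if (anyDuplicated(cells$cell_id) > 0) {
    stop("cell ids must be unique across the paired table")
  }
  if (!is.null(high_ids)) {
    stopifnot(length(high_ids) == 2)
    h1 <- cells$cell_id %in% high_ids[[1]]
    h2 <- cells$cell_id %in% high_ids[[2]]
  } else if (!is.null(thresholds)) {
    stopifnot(length(thresholds) == 2)
    h1 <- cells[[channels[1]]] > thresholds[1]
    h2 <- cells[[channels[2]]] > thresholds[2]
  } else {
    stop("provide high_ids or thresholds")
  }
  counts <- c(sum(h1 & h2), sum(h1 & !h2), sum(!h1 & h2), sum(!h1 & !h2))
  names(counts) <- c("both_high", paste0(channels[1], "_only"),
                     paste0(channels[2], "_only"), "both_low")
  counts
}

#' Overlap percentage of two detected subpopulations
#'
#' Default mode `"union"` reports `100 * both / (both + only1 + only2)`
#' (the Jaccard overlap of the two high sets). Conditional modes report the
#' overlap given one channel's subpopulation. The union overlap can never
#' exceed either conditional overlap.
#'
#' @param counts Quadrant counts from [classify_quadrants()] (order:
#'   both_high, channel-1 only, channel-2 only, both_low).
#' @param mode `"union"`, `"given-gfp"` (conditional on channel 1) or
#'   `"given-mcherry"` (conditional on channel 2).
#' @return Overlap percent in `[0, 100]`, or `NA` when no cell is high in
#'   the relevant denominator.
#' @export
overlap_percent <- function(counts, mode = c("union", "given-gfp",
                                             "given-mcherry")) {
  mode <- match.arg(mode)
  both <- counts[[1]]; o1 <- counts[[2]]; o2 <- counts[[3]]
  denom <- switch(mode,
                  "union" = both + o1 + o2,
                  "given-gfp" = both + o1,
                  "given-mcherry" = both + o2)
  if (denom == 0) return(NA_real_)
  100 * both / denom
}

#' Full two-channel colocalization analysis of one sample
#'
#' Normalizes both channels by image background, runs [qq_fit()] per channel
#' on the same cells, classifies quadrants from the two detected
#' subpopulations and computes the overlap.
#'
#' @param cells Raw paired cell table (`cell_id`, `image_id`, two channel
#'   columns with `bg_` companions).
#' @param channels Length-2 channel names.
#' @param mode Overlap mode passed to [overlap_percent()].
#' @param ... Passed to [qq_fit()].
#' @return A list of class `coloc_result`: `fits` (per-channel `qq_result`),
#'   `quadrants`, `overlap_percent`, `mode`, per-channel subpopulation
#'   fractions.
#' @export
coloc_analysis <- function(cells, channels = c("gfp", "mcherry"),
                           mode = "union", ...) {
  norm <- normalize_background(cells, channels)
  fits <- lapply(channels, function(ch)
    qq_fit(norm[[ch]], ids = norm$cell_id, ...))
  names(fits) <- channels
  quad <- classify_quadrants(norm, channels,
                             high_ids = lapply(fits, `[[`, "subpop_ids"))
  structure(list(fits = fits, quadrants = quad,
                 overlap_percent = overlap_percent(quad, mode), mode = mode,
                 subpop_fractions =
                   vapply(fits, `[[`, 0, "subpop_fraction")),
            class = "coloc_result")
}

#' Summarize overlap across biological replicates
#'
#' @param overlaps Numeric vector of per-replicate overlap percentages.
#' @return A list `mean`, `sd`, `n` (sd is `NA` with a single replicate).
#' @export
replicate_overlap_summary <- function(overlaps) {
  overlaps <- overlaps[!is.na(overlaps)]
  list(mean = mean(overlaps),
       sd = if (length(overlaps) > 1) sd(overlaps) else NA_real_,
       n = length(overlaps))
}
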