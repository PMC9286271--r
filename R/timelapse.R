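## Time-lapse analysis: growth curves, per-frame moving qq thresholds,
## carry-over and trace-length filtering, onset detection by sliding linear
## regression, and cross-channel onset pairing.

#' Onset-detection and filtering parameters
#'
#' @param window Number of consecutive time points per regression window
#'   (>= 2, default 5).
#' @param slope_threshold Minimum fluorescence rise (a.u.) over one window
#'   for a "real" increase (default 8). With `slope_mode = "window-rise"`
#'   the fitted slope times the window time-span is compared to this value;
#'   with `"per-frame"` the per-frame slope itself is compared.
#' @param r2_threshold Minimum coefficient of determination (default 0.98).
#' @param sentinel Value reported when no qualifying increase exists
#'   (default 1, stored alongside a logical `detected` flag).
#' @param min_trace_points Minimum trace length for onset analysis
#'   (default 10).
#' @param carryover_window_h Time window (hours) in which pre-activated
#'   carried-over cells are identified and removed (default `c(0, 10)`).
#' @param min_consecutive Number of consecutive qualifying windows required
#'   to call an onset (default 2; replaces interactive confirmation of
#'   single-window slopes).
#' @param slope_mode `"window-rise"` (default) or `"per-frame"`.
#' @return An object of class `onset_params`.
#' @export
onset_params <- function(window = 5, slope_threshold = 8,
                         r2_threshold = 0.98, sentinel = 1,
                         min_trace_points = 10,
                         carryover_window_h = c(0, 10),
                         min_consecutive = 2,
                         slope_mode = c("window-rise", "per-frame")) {
  slope_mode <- match.arg(slope_mode)
  stopifnot("window must be >= 2" = window >= 2,
            "slope_threshold must be > 0" = slope_threshold > 0,
            "r2_threshold must be in (0,1)" =
              r2_threshold > 0 && r2_threshold < 1,
            "min_consecutive must be >= 1" = min_consecutive >= 1)
  structure(list(window = window, slope_threshold = slope_threshold,
                 r2_threshold = r2_threshold, sentinel = sentinel,
                 min_trace_points = min_trace_points,
                 carryover_window_h = carryover_window_h,
                 min_consecutive = min_consecutive, slope_mode = slope_mode),
            class = "onset_params")
}

#' Population growth curve from tracked traces
#'
#' Counts live cells at each frame time. Cells are counted from their first
#' observed frame; a cell whose `parent_id` is set but absent from the data
#' (an orphan appearing mid-movie) triggers a warning and is still counted.
#'
#' @param traces Long trace table (`cell_id`, `parent_id`, `time_h`, ...).
#' @return Data frame `time_h`, `n_cells`, sorted by time.
#' @export
growth_curve <- function(traces) {
  known <- unique(traces$cell_id)
  parents <- traces$parent_id[!duplicated(traces$cell_id)]
  first_t <- tapply(traces$time_h, traces$cell_id, min)
  orphan <- !is.na(parents) & !(parents %in% known) &
    first_t[unique(traces$cell_id)] > min(traces$time_h)
  if (any(orphan)) {
    warning(sprintf("%d orphan cell(s) with unknown parent; counted from %s",
                    sum(orphan), "first appearance"))
  }
  tab <- table(traces$time_h)
  data.frame(time_h = as.numeric(names(tab)), n_cells = as.integer(tab),
             row.names = NULL)
}

#' Moving qq threshold over time
#'
#' Applies [qq_fit()] to the cross-section of all live-cell values at each
#' frame, giving the detected subpopulation size and fraction as a function
#' of time. Frames with fewer than `min_cells` live cells, or a degenerate
#' cross-section, yield `NA` and are listed in the `skipped` attribute.
#'
#' @param traces Long trace table.
#' @param channel Channel column name.
#' @param min_cells Minimum live cells per frame (default 4).
#' @param ... Passed to [qq_fit()].
#' @return A list of class `moving_qq`: `summary` (data frame `time_h`, `n`,
#'   `n_subpop`, `fraction`), `members` (data frame `time_h`, `cell_id` of
#'   per-frame subpopulation members).
#' @export
moving_qq_threshold <- function(traces, channel, min_cells = 4, ...) {
  times <- sort(unique(traces$time_h))
  summ <- data.frame(time_h = times, n = NA_integer_,
                     n_subpop = NA_integer_, fraction = NA_real_)
  members <- list()
  skipped <- character()
  for (i in seq_along(times)) {
    sel <- traces$time_h == times[i]
    v <- traces[[channel]][sel]
    ids <- traces$cell_id[sel]
    summ$n[i] <- length(v)
    if (length(v) < min_cells) {
      skipped <- c(skipped, sprintf("t=%g: %d cells", times[i], length(v)))
      next
    }
    fit <- tryCatch(suppressWarnings(qq_fit(v, ids = ids, ...)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      skipped <- c(skipped, sprintf("t=%g: degenerate", times[i]))
      next
    }
    summ$n_subpop[i] <- length(fit$subpop_ids)
    summ$fraction[i] <- fit$subpop_fraction
    if (length(fit$subpop_ids) > 0) {
      members[[length(members) + 1]] <-
        data.frame(time_h = times[i], cell_id = fit$subpop_ids,
                   stringsAsFactors = FALSE)
    }
  }
  members <- if (length(members) > 0) do.call(rbind, members) else
    data.frame(time_h = numeric(), cell_id = character())
  structure(list(summary = summ, members = members, channel = channel,
                 skipped = skipped),
            class = "moving_qq")
}

#' Remove carried-over pre-activated cells
#'
#' Cells already activated in the preceding stationary-phase preculture are
#' bright from the first frames. For each requested channel, a qq threshold
#' is derived from the pooled observations inside `carryover_window_h`
#' (0-10 h, exponential phase); a cell classified above it in at least
#' `min_hits` frames of the window is removed with its whole trace (a
#' pre-activated cell is bright throughout the window, whereas single-frame
#' excursions are fit noise). Cells first appearing after the window are
#' never removed.
#'
#' @param traces Long trace table.
#' @param channels Channel column name(s); with several, a cell flagged in
#'   any channel is removed (combined rule).
#' @param params An [onset_params()] object (supplies the window).
#' @param min_hits Minimum classified frames within the window (default 3).
#' @param ... Passed to [qq_fit()].
#' @return Filtered traces, with attribute `removed_ids`.
#' @export
filter_carryover <- function(traces, channels,
                             params = onset_params(), min_hits = 3, ...) {
  win <- params$carryover_window_h
  sel <- traces$time_h >= win[1] & traces$time_h <= win[2]
  removed <- character()
  if (any(sel)) {
    for (ch in channels) {
      v <- traces[[ch]][sel]
      obs_id <- traces$cell_id[sel]
      fit <- tryCatch(qq_fit(v, ids = seq_along(v), ...),
                      error = function(e) NULL)
      if (is.null(fit)) next
      hits <- table(obs_id[fit$subpop_ids])
      removed <- union(removed, names(hits)[hits >= min_hits])
    }
  }
  out <- traces[!(traces$cell_id %in% removed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_ids") <- removed
  out
}

#' Keep traces with at least a minimum number of time points
#'
#' @param traces Long trace table.
#' @param min_points Minimum observations per cell (default from
#'   [onset_params()]).
#' @return Filtered traces.
#' @export
filter_min_points <- function(traces, min_points = 10) {
  n_per <- table(traces$cell_id)
  keep <- names(n_per)[n_per >= min_points]
  out <- traces[traces$cell_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Rolling OLS over windows of `w` consecutive, evenly spaced points.
## Returns per window-start: slope (a.u. per hour), r2, valid (even spacing).
roll_ols <- function(time_h, values, w) {
  n <- length(values)
  if (n < w) {
    return(data.frame(start = integer(), t0 = numeric(), slope = numeric(),
                      rise = numeric(), r2 = numeric()))
  }
  dt <- diff(time_h)
  step <- min(dt)
  n_win <- n - w + 1
  starts <- seq_len(n_win)
  # window is valid when all its gaps equal the frame interval
  ok <- vapply(starts, function(i)
    all(abs(dt[i:(i + w - 2)] - step) < step * 1e-6), TRUE)
  x <- time_h; y <- values
  slope <- r2 <- rep(NA_real_, n_win)
  for (i in starts[ok]) {
    xi <- x[i:(i + w - 1)]; yi <- y[i:(i + w - 1)]
    xc <- xi - mean(xi); yc <- yi - mean(yi)
    sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
    slope[i] <- sxy / sxx
    r2[i] <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  }
  data.frame(start = starts, t0 = time_h[starts], slope = slope,
             rise = slope * (time_h[starts + w - 1] - time_h[starts]),
             r2 = r2, valid = ok)
}

#' Detect the fluorescence onset of one trace
#'
#' Slides an ordinary least-squares regression over every window of
#' `params$window` consecutive observed frames (gaps break windows). A
#' window qualifies when its fluorescence rise exceeds
#' `params$slope_threshold` and its r-squared exceeds
#' `params$r2_threshold`; the onset is the time of the first point of the
#' first run of at least `params$min_consecutive` qualifying windows. When
#' no window qualifies the sentinel value is returned with
#' `detected = FALSE`.
#'
#' @param time_h Observation times (hours), strictly increasing.
#' @param values Fluorescence values (camera greyscale a.u.).
#' @param params An [onset_params()] object.
#' @return A list `onset` (hours, or the sentinel), `detected`, `slope` and
#'   `r2` of the first qualifying window (NA if none), `reason`.
#' @export
detect_onset <- function(time_h, values, params = onset_params()) {
  stopifnot("times must be strictly increasing" = all(diff(time_h) > 0))
  no <- function(reason) list(onset = params$sentinel, detected = FALSE,
                              slope = NA_real_, r2 = NA_real_,
                              reason = reason)
  if (length(values) < max(params$window, params$min_trace_points)) {
    return(no("too short"))
  }
  win <- roll_ols(time_h, values, params$window)
  crit <- if (params$slope_mode == "window-rise") win$rise else win$slope
  qual <- win$valid & !is.na(win$r2) & crit > params$slope_threshold &
    win$r2 > params$r2_threshold
  qual[is.na(qual)] <- FALSE
  if (!any(qual)) return(no("no qualifying window"))
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  good <- which(r$values & r$lengths >= params$min_consecutive)
  if (length(good) == 0) return(no("no sustained increase"))
  first <- ends[good[1]] - r$lengths[good[1]] + 1
  list(onset = win$t0[first], detected = TRUE, slope = win$slope[first],
       r2 = win$r2[first], reason = "ok")
}

#' Data-driven threshold from the pooled window-slope distribution
#'
#' Pools the per-window fluorescence rises of many traces and places the
#' threshold between spurious drift and real increase at an upper quantile
#' of the central bulk (outliers beyond 1.5 IQR trimmed first, so genuine
#' ramps do not inflate the null). With fewer than `min_windows` windows the
#' fixed default is returned with `source = "fallback"`.
#'
#' @param rises Numeric vector of window rises (a.u. per window), e.g.
#'   pooled `rise` columns from traces.
#' @param probs Quantile of the trimmed bulk (default 0.99).
#' @param fallback Fixed threshold when data are insufficient (default 8).
#' @param min_windows Minimum pooled windows (default 100).
#' @return A list `threshold`, `quantile`, `source`, `n`.
#' @export
slope_null_threshold <- function(rises, probs = 0.99, fallback = 8,
                                 min_windows = 100) {
  rises <- rises[is.finite(rises)]
  if (length(rises) < min_windows) {
    return(list(threshold = fallback, quantile = probs, source = "fallback",
                n = length(rises)))
  }
  qs <- quantile(rises, c(0.25, 0.75), names = FALSE)
  fence <- qs[2] + 1.5 * (qs[2] - qs[1])
  bulk <- rises[rises <= fence]
  list(threshold = quantile(bulk, probs, names = FALSE), quantile = probs,
       source = "data", n = length(rises))
}

#' Pool window rises from many traces
#'
#' @param traces Long trace table.
#' @param channel Channel column.
#' @param window Window length in frames.
#' @return Numeric vector of valid window rises.
#' @export
pool_window_rises <- function(traces, channel, window = 5) {
  unlist(lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$time_h), ]
    w <- roll_ols(tr$time_h, tr[[channel]], window)
    w$rise[w$valid]
  }), use.names = FALSE)
}

#' Pair fluorescence onsets across two channels
#'
#' Runs [detect_onset()] per channel for every requested cell and combines
#' the results into one table, with the sentinel where a channel shows no
#' increase, plus the median signed lag (second channel minus first) over
#' cells detected in both.
#'
#' @param traces Long trace table (filtered).
#' @param channels Length-2 channel names.
#' @param cell_ids Cells to analyze (default: all cells in `traces`).
#' @param params An [onset_params()] object.
#' @return A list of class `onset_table`: `onsets` (data frame `cell_id`,
#'   `onset_<ch>`, `detected_<ch>`, `slope_<ch>`, `r2_<ch>` per channel),
#'   `median_lag_h`, `n_both`.
#' @export
pair_onsets <- function(traces, channels = c("gfp", "mcherry"),
                        cell_ids = NULL, params = onset_params()) {
  stopifnot(length(channels) == 2)
  if (is.null(cell_ids)) cell_ids <- unique(traces$cell_id)
  per_cell <- split(traces, traces$cell_id)
  rows <- lapply(cell_ids, function(id) {
    tr <- per_cell[[id]]
    row <- list(cell_id = id)
    for (ch in channels) {
      det <- if (is.null(tr)) {
        list(onset = params$sentinel, detected = FALSE, slope = NA_real_,
             r2 = NA_real_)
      } else {
        tr <- tr[order(tr$time_h), ]
        detect_onset(tr$time_h, tr[[ch]], params)
      }
      row[[paste0("onset_", ch)]] <- det$onset
      row[[paste0("detected_", ch)]] <- det$detected
      row[[paste0("slope_", ch)]] <- det$slope
      row[[paste0("r2_", ch)]] <- det$r2
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  onsets <- do.call(rbind, rows)
  both <- onsets[[paste0("detected_", channels[1])]] &
    onsets[[paste0("detected_", channels[2])]]
  lag <- onsets[[paste0("onset_", channels[2])]][both] -
    onsets[[paste0("onset_", channels[1])]][both]
  structure(list(onsets = onsets,
                 median_lag_h = if (any(both)) median(lag) else NA_real_,
                 n_both = sum(both), channels = channels),
            class = "onset_table")
}

#' End-to-end time-lapse pipeline
#'
#' Carry-over filtering, minimum-length filtering, moving qq thresholds per
#' channel, union of the per-channel tc cell sets, and paired onset
#' detection — the full trace analysis in one call.
#'
#' @param traces Long trace table.
#' @param channels Length-2 channel names.
#' @param params An [onset_params()] object.
#' @param ... Passed to [qq_fit()] for the moving thresholds.
#' @return A list of class `timelapse_result`: `growth`, per-channel
#'   `moving` summaries, `tc_ids` (union across channels), `onsets`
#'   (an `onset_table`), `removed_carryover`.
#' @export
timelapse_analysis <- function(traces, channels = c("gfp", "mcherry"),
                               params = onset_params(), ...) {
  growth <- growth_curve(traces)
  filtered <- filter_carryover(traces, channels, params, ...)
  removed <- attr(filtered, "removed_ids")
  filtered <- filter_min_points(filtered, params$min_trace_points)
  moving <- lapply(channels, function(ch)
    moving_qq_threshold(filtered, ch, ...))
  names(moving) <- channels
  tc_ids <- sort(unique(unlist(lapply(moving, function(m)
    unique(m$members$cell_id)))))
  onsets <- pair_onsets(filtered, channels, cell_ids = tc_ids,
                        params = params)
  structure(list(growth = growth, moving = moving, tc_ids = tc_ids,
                 onsets = onsets, removed_carryover = removed),
            class = "timelapse_result")
}
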