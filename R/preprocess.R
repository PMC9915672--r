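#' Compute dF/Fstd for a fluorescence trace
#'
#' `dF/Fstd = (F - mean(Fbaseline)) / sd(Fbaseline)`: the trace normalized to
#' the mean and standard deviation of its pre-stimulus baseline. The result
#' is invariant to positive affine transforms of the raw fluorescence.
#'
#' @param trace Numeric vector of raw fluorescence (a.u.).
#' @param baseline_idx Indices of the baseline frames (>= 2 frames).
#' @return Numeric vector of dF/Fstd, same length as `trace`.
#' @export
compute_dff <- function(trace, baseline_idx) {
  stopifnot(length(baseline_idx) >= 2, all(baseline_idx %in% seq_along(trace)))
  b <- trace[baseline_idx]
  s <- stats::sd(b)
  if (!is.finite(s) || s == 0) {
    stop("degenerate trace: baseline standard deviation is zero", call. = FALSE)
  }
  (trace - mean(b)) / s
}

#' Mean response over a one-second window
#'
#' @param trace Numeric vector (a dF/Fstd trace).
#' @param window A window spec: list with `start_s` (seconds from stimulus
#'   onset) and `duration_s` (1 s).
#' @param frame_rate Frames per second.
#' @param onset_frame 1-based index of the stimulus-onset frame.
#' @return Scalar mean over the window's frames.
#' @export
window_response <- function(trace, window, frame_rate, onset_frame) {
  idx <- .window_frames(window, frame_rate, onset_frame)
  if (min(idx) < 1 || max(idx) > length(trace)) {
    stop("window out of trace range", call. = FALSE)
  }
  mean(trace[idx])
}

.window_frames <- function(window, frame_rate, onset_frame) {
  start <- onset_frame + round(window$start_s * frame_rate)
  start:(start + round(window$duration_s * frame_rate) - 1L)
}

.window_spec <- function(start_s, duration_s = 1) {
  stopifnot(start_s >= 0, start_s + duration_s <= 5 + 1e-9)
  list(start_s = start_s, duration_s = duration_s)
}

# Candidate window starts: every frame offset in [0, 4] s after onset so the
# 1-s window ends by 5 s.
.candidate_starts <- function(frame_rate) (0:round(4 * frame_rate)) / frame_rate

# Per-trial window means for a trials x frames matrix.
.trial_window_means <- function(mat, idx) rowMeans(mat[, idx, drop = FALSE])

#' Optimal response window for one neuron and stimulus condition
#'
#' Slides a one-second window over the frame grid in \[0, 4\] s after stimulus
#' onset and returns the start maximizing the sensitivity index d' between
#' the per-trial window means and the per-trial one-second pre-stimulus
#' baseline means: `d' = |mu_win - mu_base| / sqrt((var_win + var_base)/2)`.
#' Ties are broken to the earliest start.
#'
#' @param dff Matrix of dF/Fstd traces, trials x frames (>= 2 trials).
#' @param frame_rate Frames per second.
#' @param onset_frame 1-based stimulus-onset frame; at least `frame_rate`
#'   baseline frames must precede it and at least 5 s must follow.
#' @return A window spec (list with `start_s`, `duration_s`, `dprime`).
#' @export
optimal_window <- function(dff, frame_rate, onset_frame) {
  stopifnot(is.matrix(dff), nrow(dff) >= 2)
  nf <- round(frame_rate)
  stopifnot(onset_frame > nf, ncol(dff) >= onset_frame + 5 * nf - 1)
  base <- .trial_window_means(dff, (onset_frame - nf):(onset_frame - 1L))
  starts <- .candidate_starts(frame_rate)
  dp <- vapply(starts, function(s) {
    w <- .trial_window_means(dff, .window_frames(.window_spec(s), frame_rate, onset_frame))
    pooled <- (stats::var(w) + stats::var(base)) / 2
    if (pooled == 0) {
      if (mean(w) == mean(base)) 0 else Inf
    } else {
      abs(mean(w) - mean(base)) / sqrt(pooled)
    }
  }, numeric(1))
  if (!any(is.finite(dp) | is.infinite(dp)) || all(is.na(dp))) {
    stop("degenerate traces: d' undefined for every window", call. = FALSE)
  }
  best <- which.max(dp)                      # which.max takes the earliest tie
  c(.window_spec(starts[best]), dprime = dp[best])
}

#' Fixed response window for a whole recording
#'
#' Selects the one-second window (shared by all neurons and conditions of the
#' recording) that maximizes the number of responsive neurons. For each
#' candidate start, each neuron and each sound x laser condition, the
#' per-trial window means are compared with the per-trial pre-stimulus
#' baseline means by a paired t-test; p-values are Bonferroni-corrected
#' across the conditions, and a neuron counts as responsive if any corrected
#' p < `alpha`. Ties are broken to the earliest start.
#'
#' @param traces A `"trace_set"` (see [generate_traces()]).
#' @param alpha Significance level on the corrected p-values.
#' @return A window spec (list with `start_s`, `duration_s`,
#'   `n_responsive`).
#' @export
fixed_window <- function(traces, alpha = 0.01) {
  stopifnot(inherits(traces, "trace_set"))
  fr <- traces$frame_rate
  onset <- traces$onset_frame
  nf <- round(fr)
  dff <- .dff_array(traces)
  n <- dim(dff)[1]
  cond <- paste(traces$trials$level, traces$trials$laser)
  conds <- unique(cond)
  n_cond <- length(conds)
  n_trials <- sum(cond == conds[1])
  if (n_trials < 2) stop("insufficient data: need >= 2 trials per condition", call. = FALSE)

  base <- apply(dff[, , (onset - nf):(onset - 1L), drop = FALSE], c(1, 2), mean)
  starts <- .candidate_starts(fr)
  counts <- vapply(starts, function(s) {
    idx <- .window_frames(.window_spec(s), fr, onset)
    w <- apply(dff[, , idx, drop = FALSE], c(1, 2), mean)
    d <- w - base
    responsive <- logical(n)
    for (cc in conds) {
      dc <- d[, cond == cc, drop = FALSE]
      m <- rowMeans(dc)
      sdd <- apply(dc, 1, stats::sd)
      tt <- m / (sdd / sqrt(n_trials))
      p <- 2 * stats::pt(-abs(tt), df = n_trials - 1)
      p[sdd == 0] <- ifelse(m[sdd == 0] == 0, 1, 0)
      responsive <- responsive | (pmin(p * n_cond, 1) < alpha)
    }
    sum(responsive)
  }, numeric(1))
  best <- which.max(counts)
  c(.window_spec(starts[best]), n_responsive = counts[best])
}

# dF/Fstd for every neuron x trial trace, baseline = 1 s pre-onset.
.dff_array <- function(traces) {
  nf <- round(traces$frame_rate)
  bidx <- (traces$onset_frame - nf):(traces$onset_frame - 1L)
  F <- traces$F
  mb <- apply(F[, , bidx, drop = FALSE], c(1, 2), mean)
  sb <- apply(F[, , bidx, drop = FALSE], c(1, 2), stats::sd)
  if (any(sb == 0)) stop("degenerate trace: baseline standard deviation is zero", call. = FALSE)
  (F - as.vector(mb)) / as.vector(sb)
}

#' Windowed response table from a trace set
#'
#' Converts frame-level traces to the scalar trial responses used by the rest
#' of the pipeline: dF/Fstd averaged over either each neuron-and-condition's
#' optimal window or the recording's single fixed window.
#'
#' @param traces A `"trace_set"`.
#' @param mode `"optimal"` (per neuron and condition) or `"fixed"` (one
#'   window for the whole recording).
#' @param alpha Passed to [fixed_window()] when `mode = "fixed"`.
#' @return A response table (data frame `neuron`, `level`, `laser`, `trial`,
#'   `response`) with a `"window_mode"` attribute.
#' @export
window_table <- function(traces, mode = c("optimal", "fixed"), alpha = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(traces, "trace_set"))
  fr <- traces$frame_rate
  onset <- traces$onset_frame
  dff <- .dff_array(traces)
  n <- dim(dff)[1]
  trials <- traces$trials
  cond <- paste(trials$level, trials$laser)
  out <- vector("list", n)
  if (mode == "fixed") {
    win <- fixed_window(traces, alpha = alpha)
    idx <- .window_frames(win, fr, onset)
    w <- apply(dff[, , idx, drop = FALSE], c(1, 2), mean)
    for (i in seq_len(n)) {
      out[[i]] <- data.frame(neuron = i, trials[, c("level", "laser", "trial")],
                             response = w[i, ], row.names = NULL)
    }
  } else {
    for (i in seq_len(n)) {
      resp <- numeric(nrow(trials))
      for (cc in unique(cond)) {
        rows <- which(cond == cc)
        win <- optimal_window(dff[i, rows, , drop = TRUE], fr, onset)
        idx <- .window_frames(win, fr, onset)
        resp[rows] <- rowMeans(dff[i, rows, idx, drop = TRUE])
      }
      out[[i]] <- data.frame(neuron = i, trials[, c("level", "laser", "trial")],
                             response = resp, row.names = NULL)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "window_mode") <- mode
  tab
}

#' Identify optogenetically tagged interneurons from two-channel signals
#'
#' The static red marker channel is contaminated by bleedthrough from the
#' activity-dependent green channel. A single ordinary-least-squares slope of
#' red on green (pooled over cells and frames) estimates the bleedthrough
#' coefficient; the corrected red signal is `red - slope * green`, and a cell
#' is tagged when its mean corrected red fluorescence, z-scored to the
#' background, exceeds `threshold` (2 by convention).
#'
#' @param green,red Matrices cells x frames of channel signals (a.u.).
#' @param background_sd Background red-channel sd used for z-scoring (> 0).
#' @param background_mean Background red-channel mean (default 0).
#' @param threshold z-score threshold for tagging.
#' @return A list with `bleedthrough_coef`, per-cell `z`, and logical
#'   `tagged`.
#' @export
identify_tagged_cells <- function(green, red, background_sd,
                                  background_mean = 0, threshold = 2) {
  stopifnot(is.matrix(green), is.matrix(red), all(dim(green) == dim(red)),
            background_sd > 0)
  g <- as.vector(green)
  vg <- stats::var(g)
  if (vg == 0) {
    warning("constant green channel; bleedthrough slope set to 0")
    slope <- 0
  } else {
    slope <- stats::cov(g, as.vector(red)) / vg
  }
  corrected <- red - slope * green
  z <- (rowMeans(corrected) - background_mean) / background_sd
  list(bleedthrough_coef = slope, z = z, tagged = z > threshold)
}
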