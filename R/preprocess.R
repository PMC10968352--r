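# Detrending, probability-based bad-channel detection, re-referencing and
# epoch extraction.

#' Remove the least-squares linear trend
#'
#' Subtracts each channel's best-fitting straight line (intercept plus
#' slope times time), leaving zero mean and zero linear trend. Idempotent.
#'
#' @param x A numeric vector, a channels x time matrix, or an
#'   `eeg_recording`.
#' @return Same type as the input.
#' @export
#' @examples
#' detrend(3 + 0.5 * (0:99))          # a pure ramp detrends to zero
detrend <- function(x) UseMethod("detrend")

#' @export
detrend.default <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2          # centered time, orthogonal to 1
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

#' @export
detrend.matrix <- function(x) {
  n <- ncol(x)
  t <- seq_len(n) - (n + 1) / 2
  slope <- as.vector(x %*% t) / sum(t * t)
  x - rowMeans(x) - outer(slope, t)
}

#' @export
detrend.eeg_recording <- function(x) {
  x$samples <- detrend.matrix(x$samples)
  x
}

#' Probability-based bad-channel detection
#'
#' Scores each channel by the negative mean log-likelihood of its samples
#' under a kernel density fit to that channel's amplitude distribution,
#' z-scores the measure across channels, and flags channels with |z|
#' beyond `z_thresh`. The pass is repeated `n_iter` times on the surviving
#' channels so that a gross outlier cannot mask a milder one.
#' Zero-variance (flat) channels are always flagged.
#'
#' @param rec An `eeg_recording`. Channels already in `rec$bad_channels`
#'   are excluded from scoring.
#' @param z_thresh Absolute z-score threshold (default 3).
#' @param n_iter Number of detection passes (default 2).
#' @param max_samples Per-channel subsample size used for the density fit.
#' @return Character vector of newly flagged channel labels.
#' @export
detect_bad_channels <- function(rec, z_thresh = 3, n_iter = 2,
                                max_samples = 4096) {
  flagged <- character(0)
  alive <- setdiff(rec$channels, rec$bad_channels)
  if (length(alive) < 4)
    stop("need at least 4 unflagged channels, have ", length(alive))
  for (iter in seq_len(n_iter)) {
    if (length(alive) < 4) {
      warning("fewer than 4 channels survive; stopping detection at pass ",
              iter)
      break
    }
    thin <- lapply(match(alive, rec$channels),
                   function(i) thin_to(rec$samples[i, ], max_samples))
    v <- vapply(thin, stats::var, numeric(1))
    flat <- alive[v == 0]
    live <- alive[v > 0]
    scores <- vapply(thin[v > 0], function(x) {
      kd <- stats::density(x, n = 512)
      f <- stats::approx(kd$x, kd$y, xout = x, rule = 2)$y
      -mean(log(pmax(f, 1e-300)))
    }, numeric(1))
    bad <- character(0)
    if (length(live) >= 2 && stats::sd(scores) > 0) {
      z <- (scores - mean(scores)) / stats::sd(scores)
      bad <- live[abs(z) > z_thresh]
    }
    new_flags <- c(flat, bad)
    flagged <- union(flagged, new_flags)
    alive <- setdiff(alive, new_flags)
    if (!length(new_flags)) break     # nothing more to find
  }
  flagged
}

#' Re-reference a subset of channels to a new reference electrode
#'
#' Subtracts the reference channel's signal from each channel of `subset`
#' (by default the six posterior sensors), leaving all other channels
#' untouched, and updates the recording's reference tag. The operation is
#' not idempotent: applying it twice subtracts the reference twice.
#'
#' @param rec An `eeg_recording`.
#' @param new_ref Reference channel label, `"AF3"` or `"F3"` in the
#'   standard workflow. Must not be flagged bad, and must not belong to
#'   `subset`.
#' @param subset Channels to re-reference; defaults to the posterior set
#'   T7, P7, O1, O2, P8, T8.
#' @return The re-referenced `eeg_recording`.
#' @export
rereference <- function(rec, new_ref,
                        subset = c("T7", "P7", "O1", "O2", "P8", "T8")) {
  if (!new_ref %in% rec$channels)
    stop("reference channel ", new_ref, " not present in recording")
  if (new_ref %in% rec$bad_channels)
    stop("cannot re-reference to bad channel ", new_ref)
  if (new_ref %in% subset)
    stop("reference channel must not belong to the re-referenced subset")
  subset <- intersect(subset, rec$channels)
  ref_sig <- rec$samples[match(new_ref, rec$channels), ]
  rows <- match(subset, rec$channels)
  rec$samples[rows, ] <- sweep(rec$samples[rows, , drop = FALSE], 2, ref_sig)
  rec$reference <- new_ref
  rec
}

#' Extract the 10-second epochs preceding each SWB report
#'
#' For every report at time `t` whose window `[t - duration, t)` lies
#' inside the run, returns the corresponding channels x samples epoch
#' (sample indices `round((t - duration) * fs)` to `round(t * fs) - 1`,
#' half-open). Reports too early or too late for a full window are skipped
#' with a warning, never zero-padded.
#'
#' @param rec An `eeg_recording`.
#' @param reports Data frame with columns `time_s` and `swb` (extra
#'   columns are ignored).
#' @param duration Window length in seconds (default 10).
#' @return List of epochs (class `"eeg_epoch"`).
#' @export
extract_epochs <- function(rec, reports, duration = 10) {
  n <- ncol(rec$samples)
  out <- vector("list", nrow(reports))
  kept <- 0L
  for (r in seq_len(nrow(reports))) {
    t_rep <- reports$time_s[r]
    i0 <- round((t_rep - duration) * rec$fs)
    i1 <- round(t_rep * rec$fs)
    if (i0 < 0 || i1 > n) {
      warning("report at t = ", t_rep,
              " s: window does not fit in the run; epoch skipped")
      next
    }
    kept <- kept + 1L
    out[[kept]] <- new_epoch(
      rec$samples[, (i0 + 1L):i1, drop = FALSE], rec$fs, rec$channels,
      swb = reports$swb[r], t_report = t_rep,
      bad_channels = rec$bad_channels,
      participant_id = rec$participant_id, run_id = rec$run_id)
  }
  out[seq_len(kept)]
}
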