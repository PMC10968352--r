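# Band filtering, Welch spectral estimation and the log-power asymmetry.

# cache of zero-phase Butterworth gain curves keyed by (n, fs, band edges)
.bp_cache <- new.env(parent = emptyenv())

# clip band edges to the usable range [0.5, 0.95 * Nyquist]
clip_band <- function(band, fs) {
  band <- band_def(band)
  lo <- max(band$f_low, 0.5)
  hi <- min(band$f_high, 0.95 * fs / 2)
  if (lo >= hi)
    stop("band '", band$name, "' is empty after clipping to [0.5, ",
         0.95 * fs / 2, "] Hz at fs = ", fs)
  list(name = band$name, f_low = lo, f_high = hi)
}

# squared-magnitude (zero-phase) response of the 4th-order Butterworth
# band-pass on the length-n DFT grid; equals the filtfilt transfer function
butter_zerophase_gain <- function(n, fs, f_low, f_high, order = 4) {
  key <- paste(n, fs, f_low, f_high, order, sep = "|")
  g <- .bp_cache[[key]]
  if (!is.null(g)) return(g)
  ba <- signal::butter(order, c(f_low, f_high) / (fs / 2), type = "pass")
  w <- 2 * pi * (0:(n - 1)) / n
  ew <- exp(-1i * outer(w, 0:(length(ba$b) - 1)))
  h <- as.vector(ew %*% ba$b) / as.vector(ew %*% ba$a)
  g <- Mod(h)^2
  g[g < 1e-12] <- 0
  .bp_cache[[key]] <- g
  g
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters a signal (or each row of a channels x time matrix) into a
#' frequency band with a 4th-order Butterworth band-pass applied without
#' phase distortion. Band edges are clipped to `[0.5, 0.95 * Nyquist]` Hz
#' before filter design; an empty clipped band is an error.
#'
#' The default `"fft"` method applies the forward-backward (squared
#' magnitude) Butterworth response on the DFT grid, which is the filtfilt
#' transfer function with circular boundary handling; `"filtfilt"` uses
#' [signal::filtfilt()] in the time domain. The two agree away from the
#' signal edges.
#'
#' @param x Numeric vector, or matrix with channels in rows.
#' @param fs Sampling rate in Hz.
#' @param band Band name or [band_def()] object.
#' @param method `"fft"` (default) or `"filtfilt"`.
#' @param order Filter order (default 4).
#' @return Filtered signal, same shape as `x`.
#' @export
#' @examples
#' fs <- 128
#' t <- (0:1279) / fs
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, fs, "alpha")   # 10 Hz is mid-alpha: passes
#' z <- bandpass(x, fs, "beta")    # 10 Hz is below beta: blocked
bandpass <- function(x, fs, band, method = c("fft", "filtfilt"), order = 4) {
  method <- match.arg(method)
  cb <- clip_band(band, fs)
  if (is.matrix(x)) {
    if (method == "fft") {
      g <- butter_zerophase_gain(ncol(x), fs, cb$f_low, cb$f_high, order)
      y <- t(Re(mvfft(mvfft(t(x)) * g, inverse = TRUE))) / ncol(x)
      dimnames(y) <- dimnames(x)
      return(y)
    }
    return(t(apply(x, 1, bandpass, fs = fs, band = band,
                   method = method, order = order)))
  }
  if (method == "fft") {
    g <- butter_zerophase_gain(length(x), fs, cb$f_low, cb$f_high, order)
    Re(fft(fft(x) * g, inverse = TRUE)) / length(x)
  } else {
    ba <- signal::butter(order, c(cb$f_low, cb$f_high) / (fs / 2),
                         type = "pass")
    signal::filtfilt(ba, x)
  }
}

#' Welch power spectral density
#'
#' Averaged periodogram over 50%-overlapping Hanning-windowed segments,
#' normalized so that the one-sided density integrates (sum times bin
#' width) to the mean squared amplitude of the signal.
#'
#' @param x Numeric vector, or matrix with channels in rows.
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples (default 256, i.e. 2 s and a
#'   0.5 Hz grid at 128 Hz).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return An object of class `"psd"`: list with `freq` (Hz, 0 to Nyquist)
#'   and `density` (uV^2/Hz; a vector, or channels x frequency matrix).
#' @export
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 10 * (0:1279) / fs)
#' p <- welch_psd(x, fs)
#' sum(p$density) * (p$freq[2] - p$freq[1])  # ~ 0.5, the sine's power
welch_psd <- function(x, fs, seg_len = 256, overlap = 0.5) {
  single <- !is.matrix(x)
  if (single) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (n < seg_len)
    stop("signal of length ", n, " is shorter than the segment length ",
         seg_len, "; at least ", seg_len, " samples are required")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / seg_len))
  nch <- nrow(x)
  # segment matrix: seg_len rows x (nseg * nch) columns, one FFT batch
  idx <- outer(0:(seg_len - 1L), starts, `+`)
  seg <- matrix(0, seg_len, length(starts) * nch)
  for (c in seq_len(nch))
    seg[, (c - 1L) * length(starts) + seq_along(starts)] <-
      x[c, ][idx] * w
  sp <- Mod(mvfft(seg))^2
  nf <- seg_len %/% 2 + 1L
  dens <- matrix(0, nch, nf)
  for (c in seq_len(nch)) {
    cols <- (c - 1L) * length(starts) + seq_along(starts)
    pk <- rowMeans(sp[1:nf, cols, drop = FALSE])
    pk <- pk / (fs * sum(w^2))
    pk[2:(nf - 1L)] <- 2 * pk[2:(nf - 1L)]   # one-sided, keep DC & Nyquist
    dens[c, ] <- pk
  }
  rownames(dens) <- rownames(x)
  structure(list(freq = (0:(nf - 1L)) * fs / seg_len,
                 density = if (single) dens[1, ] else dens,
                 fs = fs, seg_len = seg_len, overlap = overlap),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd: %d bins, 0-%g Hz, df = %g Hz>\n",
              length(x$freq), max(x$freq), x$freq[2] - x$freq[1]))
  invisible(x)
}

# resolve an epoch signal by channel label or quadrant name
epoch_signal <- function(epoch, name) {
  if (name %in% epoch$channels) {
    if (name %in% epoch$bad_channels)
      stop("channel ", name, " is flagged bad")
    return(epoch$samples[match(name, epoch$channels), ])
  }
  if (name %in% names(quadrant_channels()))
    return(quadrant_signal(epoch, name))
  stop("'", name, "' is neither a montage channel of this epoch ",
       "nor a quadrant name")
}

#' Quadrant-averaged signal of an epoch
#'
#' Sample-wise arithmetic mean of the non-bad channels belonging to a scalp
#' quadrant (see [quadrant_channels()]). All members flagged bad is an
#' error.
#'
#' @param epoch An epoch (see [extract_epochs()]).
#' @param quadrant One of `"left_anterior"`, `"right_anterior"`,
#'   `"left_posterior"`, `"right_posterior"`.
#' @return Numeric vector of averaged samples.
#' @export
quadrant_signal <- function(epoch, quadrant) {
  quads <- quadrant_channels()
  quadrant <- match.arg(quadrant, names(quads))
  members <- intersect(quads[[quadrant]], epoch$channels)
  members <- setdiff(members, epoch$bad_channels)
  if (!length(members))
    stop("all channels of quadrant ", quadrant, " are flagged bad")
  colMeans(epoch$samples[match(members, epoch$channels), , drop = FALSE])
}

# log one-sided densities of a set of named signals restricted to the
# in-band bins; returns list(freq, logdens matrix names x bins, zero mask)
band_logdens <- function(signals, fs, band, prefilter = TRUE,
                         seg_len = 256, overlap = 0.5) {
  cb <- clip_band(band, fs)
  x <- do.call(rbind, signals)
  if (prefilter) x <- bandpass(x, fs, band)
  p <- welch_psd(x, fs, seg_len = seg_len, overlap = overlap)
  dens <- if (is.matrix(p$density)) p$density else matrix(p$density, 1)
  sel <- p$freq >= cb$f_low & p$freq <= cb$f_high
  d <- dens[, sel, drop = FALSE]
  rownames(d) <- names(signals)
  list(freq = p$freq[sel], dens = d)
}

#' Log band-power asymmetry of a channel or quadrant pair
#'
#' The asymmetry statistic of one epoch: mean over the frequency bins
#' inside the band of the difference of natural-log Welch power densities,
#' right-hemisphere channel (`ch1`) minus left (`ch2`). Positive values
#' mean more band power on the right. By default the epoch is band-pass
#' filtered before spectral estimation; the statistic is invariant to this
#' choice up to spectral leakage because the filter gain cancels in the
#' log ratio.
#'
#' Frequency bins where either channel has exactly zero density are
#' dropped from the mean (with a warning); if no bin survives, the epoch
#' is degenerate and an error is raised.
#'
#' @param epoch An epoch (see [extract_epochs()]).
#' @param ch1,ch2 Channel labels or quadrant names; `ch1` is conventionally
#'   on the right hemisphere. Must differ, and must not be flagged bad.
#' @param band Band name or [band_def()].
#' @param prefilter Band-pass before the PSD (default `TRUE`)?
#' @param seg_len,overlap Welch parameters, see [welch_psd()].
#' @return One-row data.frame with columns `participant_id`, `run_id`,
#'   `epoch`, `band`, `ch1`, `ch2`, `value`, `swb`.
#' @export
asym <- function(epoch, ch1, ch2, band, prefilter = TRUE,
                 seg_len = 256, overlap = 0.5) {
  if (identical(ch1, ch2)) stop("ch1 and ch2 must differ")
  sig <- list(epoch_signal(epoch, ch1), epoch_signal(epoch, ch2))
  names(sig) <- c(ch1, ch2)
  bl <- band_logdens(sig, epoch$fs, band, prefilter, seg_len, overlap)
  d1 <- bl$dens[1, ]; d2 <- bl$dens[2, ]
  ok <- d1 > 0 & d2 > 0
  if (!all(ok))
    warning(sum(!ok), " zero-density bin(s) excluded from the band mean")
  if (!any(ok))
    stop("degenerate epoch: zero band power on ", ch1, " or ", ch2,
         " in every ", band_def(band)$name, " bin")
  data.frame(participant_id = epoch$participant_id %||% NA_character_,
             run_id = epoch$run_id %||% NA,
             epoch = epoch$t_report,
             band = band_def(band)$name, ch1 = ch1, ch2 = ch2,
             value = mean(log(d1[ok]) - log(d2[ok])),
             swb = epoch$swb,
             stringsAsFactors = FALSE)
}
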