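# Synthetic participants: SWB rating sequences plus band-limited EEG with a
# known, configurable asymmetry-SWB coupling.

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: number of
#' participants and runs, run length and report cadence, sampling rate,
#' the (imbalanced) SWB rating distribution, per-band baseline amplitudes,
#' and the injected asymmetry-SWB couplings that constitute the ground
#' truth for recovery experiments.
#'
#' @param n_participants Number of participants.
#' @param n_runs_per_participant Runs per participant (default 6).
#' @param run_duration Run length in seconds (default 540, i.e. 9 min).
#' @param report_interval Seconds between SWB reports (default 30); must
#'   divide `run_duration`.
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @param swb_probs Named numeric vector of probabilities over ratings
#'   `"1"`..`"10"`; must be non-negative and sum to 1 (within 1e-12). The
#'   default concentrates mass on ratings 6-8, the typical reporting
#'   pattern.
#' @param band_amplitudes Named vector of per-band RMS amplitudes in uV
#'   for the band-limited noise components; bands with zero or absent
#'   amplitude are not synthesized.
#' @param couplings List of couplings, each a list with elements `ch1`
#'   (right channel), `ch2` (left channel), `band`, and `gamma` — the
#'   injected asymmetry slope in asymmetry units per SWB unit.
#' @param asym_noise_sd SD of the zero-mean per-segment noise added to the
#'   injected log-power asymmetry (dimensionless, default 0).
#' @param left_handed_fraction Fraction of left-handed participants; the
#'   realized count is `round(fraction * n_participants)`, assigned to a
#'   seeded random subset.
#' @param seed Master seed; all child seeds derive deterministically.
#' @return A validated list of class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 2, n_runs_per_participant = 1,
#'                     run_duration = 120)
synth_config <- function(n_participants = 30,
                         n_runs_per_participant = 6,
                         run_duration = 540,
                         report_interval = 30,
                         sampling_rate = 128,
                         swb_probs = c("1" = 0.01, "2" = 0.01, "3" = 0.03,
                                       "4" = 0.04, "5" = 0.10, "6" = 0.28,
                                       "7" = 0.28, "8" = 0.18, "9" = 0.06,
                                       "10" = 0.01),
                         band_amplitudes = c(delta = 20, theta = 10,
                                             alpha = 15, beta = 8,
                                             gamma = 5),
                         couplings = list(),
                         asym_noise_sd = 0,
                         left_handed_fraction = 2 / 30,
                         seed = 1L) {
  if (is.null(names(swb_probs)) || !setequal(names(swb_probs), as.character(1:10)))
    stop("swb_probs must be named with the ratings 1..10")
  swb_probs <- swb_probs[as.character(1:10)]
  if (any(swb_probs < 0) || abs(sum(swb_probs) - 1) > 1e-12)
    stop("swb_probs must be non-negative and sum to 1")
  n_reports <- run_duration / report_interval
  if (n_reports < 1 || abs(n_reports - round(n_reports)) > 1e-9)
    stop("run_duration must be a positive integer multiple of report_interval")
  bad_bands <- setdiff(names(band_amplitudes), band_table()$name)
  if (length(bad_bands))
    stop("unknown band(s) in band_amplitudes: ", paste(bad_bands, collapse = ", "))
  for (cp in couplings) {
    stopifnot(is.list(cp), all(c("ch1", "ch2", "band", "gamma") %in% names(cp)))
    unknown <- setdiff(c(cp$ch1, cp$ch2), montage_channels())
    if (length(unknown))
      stop("coupling names channel(s) not in the montage: ",
           paste(unknown, collapse = ", "))
    band_def(cp$band)
    amp <- band_amplitudes[cp$band]
    if (is.na(amp) || amp <= 0)
      stop("coupling on band '", cp$band,
           "' but that band has no synthesized amplitude")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_runs_per_participant = as.integer(n_runs_per_participant),
    run_duration = run_duration, report_interval = report_interval,
    sampling_rate = sampling_rate, swb_probs = swb_probs,
    band_amplitudes = band_amplitudes, couplings = couplings,
    asym_noise_sd = asym_noise_sd,
    left_handed_fraction = left_handed_fraction,
    seed = as.integer(seed)), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_config: %d participants x %d runs, %g s runs, reports every ",
    "%g s, fs = %g Hz, %d coupling(s), seed = %d>\n"),
    x$n_participants, x$n_runs_per_participant, x$run_duration,
    x$report_interval, x$sampling_rate, length(x$couplings), x$seed))
  invisible(x)
}

#' Draw one run's SWB rating sequence
#'
#' One integer rating per report interval, i.i.d. from the configured
#' rating distribution, at times `k * report_interval` for
#' `k = 1..run_duration/report_interval`.
#'
#' @param config A [synth_config()].
#' @param participant_seed Seed for this sequence.
#' @return Data frame with columns `time_s`, `swb`.
#' @export
generate_swb_sequence <- function(config, participant_seed) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(config$run_duration / config$report_interval)
  swb <- with_seed(participant_seed,
                   sample(1:10, n, replace = TRUE, prob = config$swb_probs))
  data.frame(time_s = seq_len(n) * config$report_interval, swb = swb)
}

# Unit-RMS band-limited Gaussian noise via direct spectral synthesis:
# a complex-Gaussian white spectrum, drawn independently on BOTH halves of
# the DFT grid (no Hermitian constraint) and shaped by the zero-phase
# Butterworth band-pass gain. For such a two-sided spectrum the real and
# imaginary parts of one inverse FFT are two independent Gaussian
# processes with the target spectrum: their lag cross-covariance
# sum_k g_k^2 sin(w_k tau) cancels pairwise over +/-w_k. (A one-sided
# spectrum would NOT work: Re and Im would be a Hilbert pair with
# identical spectral envelopes.) Each output is distributionally
# identical to band-pass-filtered white Gaussian noise.
band_noise_pair <- function(n, fs, band) {
  if (n %% 2 != 0)
    stop("band-limited synthesis requires an even number of samples")
  cb <- clip_band(band, fs)
  key <- paste("bn", n, fs, cb$f_low, cb$f_high, sep = "|")
  pre <- .bp_cache[[key]]
  if (is.null(pre)) {
    g <- butter_zerophase_gain(n, fs, cb$f_low, cb$f_high)
    supp <- which(g > 1e-6)            # -60 dB spectral support, two-sided
    pre <- list(supp = supp,
                gs = g[supp] * (n / sqrt(sum(g[supp]^2))))
    .bp_cache[[key]] <- pre
  }
  k <- length(pre$supp)
  re <- numeric(n); im <- numeric(n)
  re[pre$supp] <- stats::rnorm(k) * pre$gs
  im[pre$supp] <- stats::rnorm(k) * pre$gs
  z <- stats::fft(complex(real = re, imaginary = im), inverse = TRUE) / n
  list(Re(z), Im(z))
}

band_noise <- function(n, fs, band) band_noise_pair(n, fs, band)[[1]]

#' Generate one synthetic EEG recording coupled to an SWB sequence
#'
#' Each of the 14 montage channels is a sum over the configured bands of
#' independent band-limited Gaussian noise with the configured RMS
#' amplitude. For every injected coupling `(ch1, ch2, band, gamma)`, the
#' band component is rescaled within each report segment (the
#' `report_interval` seconds ending at a report with rating `s`): the
#' right channel `ch1` by `exp(+(gamma * s + e) / 4)` and the left channel
#' `ch2` by `exp(-(gamma * s + e) / 4)`, with
#' `e ~ Normal(0, asym_noise_sd)`, so the expected log-power asymmetry of
#' the pair in that band is exactly `gamma * s + e`. A pair sharing only
#' one channel with a coupling inherits half the slope.
#'
#' @param swb Data frame with `time_s`, `swb` — one run's rating sequence
#'   (see [generate_swb_sequence()]); must be non-empty.
#' @param config A [synth_config()].
#' @param run_seed Seed for this recording.
#' @param participant_id,run_id Identifiers stored in the recording.
#' @return An `eeg_recording`.
#' @export
generate_recording <- function(swb, config, run_seed,
                               participant_id = "P01", run_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!nrow(swb)) stop("swb sequence is empty")
  fs <- config$sampling_rate
  n <- round(config$run_duration * fs)
  chans <- montage_channels()
  amps <- config$band_amplitudes[config$band_amplitudes > 0]
  seg_len <- round(config$report_interval * fs)
  n_seg <- nrow(swb)
  # per-segment scale factor on the log-power scale for each coupled
  # (channel, band): sum of +/- (gamma*s + e) / 4 over couplings
  with_seed(run_seed, {
    seg_noise <- lapply(seq_along(config$couplings),
                        function(i) stats::rnorm(n_seg, 0, config$asym_noise_sd))
    samples <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
    for (b in names(amps)) {
      ci <- 1L
      while (ci <= length(chans)) {
        pr <- band_noise_pair(n, fs, b)
        for (j in 1:2) {
          if (ci > length(chans)) break
          ch <- chans[ci]
          comp <- amps[[b]] * pr[[j]]
          log_scale <- numeric(n_seg)
          touched <- FALSE
          for (k in seq_along(config$couplings)) {
            cp <- config$couplings[[k]]
            if (cp$band != b || !(ch %in% c(cp$ch1, cp$ch2))) next
            x <- cp$gamma * swb$swb + seg_noise[[k]]
            log_scale <- log_scale + (if (ch == cp$ch1) +x else -x) / 4
            touched <- TRUE
          }
          if (touched)
            comp <- comp * rep(exp(log_scale), each = seg_len)[seq_len(n)]
          samples[ci, ] <- samples[ci, ] + comp
          ci <- ci + 1L
        }
      }
    }
  })
  new_recording(samples, fs, chans, participant_id, run_id)
}

#' Corrupt one channel of a recording
#'
#' Replaces the named channel with a pathological signal for exercising
#' bad-channel detection: all zeros (`"flat"`), Gaussian noise at 50x the
#' channel's baseline SD (`"high_variance"`), or the original signal plus
#' sparse impulses of 100-500 uV magnitude and random sign (`"spikes"`,
#' ~3% of samples).
#'
#' @param rec An `eeg_recording`.
#' @param channel Channel label to corrupt.
#' @param mode One of `"flat"`, `"high_variance"`, `"spikes"`.
#' @return A modified copy of `rec`.
#' @export
inject_bad_channel <- function(rec, channel,
                               mode = c("flat", "high_variance", "spikes")) {
  mode <- match.arg(mode)
  if (!channel %in% rec$channels)
    stop("channel ", channel, " not in recording")
  i <- match(channel, rec$channels)
  n <- ncol(rec$samples)
  rec$samples[i, ] <- switch(
    mode,
    flat = rep(0, n),
    high_variance = stats::rnorm(n, 0, 50 * stats::sd(rec$samples[i, ])),
    spikes = {
      x <- rec$samples[i, ]
      hit <- stats::runif(n) < 0.03
      x[hit] <- x[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
        stats::runif(sum(hit), 100, 500)
      x
    })
  rec
}

#' Simulate a full synthetic dataset
#'
#' Generates every participant's handedness, per-run SWB sequences and EEG
#' recordings from one master seed. Child seeds per participant and run
#' are derived deterministically and recorded in the returned object.
#'
#' @param config A [synth_config()].
#' @return A list of class `"swb_dataset"` with elements `participants`
#'   (each holding `id`, `handedness`, and `runs` — a list of
#'   `(recording, reports)` pairs), plus the `config`.
#' @export
#' @examples
#' cfg <- synth_config(n_participants = 1, n_runs_per_participant = 1,
#'                     run_duration = 60, band_amplitudes = c(alpha = 10))
#' ds <- simulate_dataset(cfg)
#' ds$participants[[1]]$runs[[1]]$recording
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  np <- config$n_participants
  n_left <- round(config$left_handed_fraction * np)
  left_idx <- with_seed(child_seed(config$seed, 0L),
                        sample(np, n_left))
  participants <- vector("list", np)
  for (p in seq_len(np)) {
    id <- sprintf("P%02d", p)
    runs <- vector("list", config$n_runs_per_participant)
    for (r in seq_len(config$n_runs_per_participant)) {
      swb_seed <- child_seed(config$seed, p, r, 1L)
      rec_seed <- child_seed(config$seed, p, r, 2L)
      reports <- generate_swb_sequence(config, swb_seed)
      reports <- cbind(participant_id = id, run_id = r, reports)
      rec <- generate_recording(reports, config, rec_seed,
                                participant_id = id, run_id = r)
      runs[[r]] <- list(recording = rec, reports = reports,
                        seeds = c(swb = swb_seed, recording = rec_seed))
    }
    participants[[p]] <- list(
      id = id,
      handedness = if (p %in% left_idx) "left" else "right",
      runs = runs)
  }
  structure(list(participants = participants, config = config),
            class = "swb_dataset")
}

#' @export
print.swb_dataset <- function(x, ...) {
  hands <- vapply(x$participants, `[[`, "", "handedness")
  nruns <- length(x$participants[[1]]$runs)
  cat(sprintf(
    "<swb_dataset: %d participants (%d left-handed), %d run(s) each>\n",
    length(x$participants), sum(hands == "left"), nruns))
  invisible(x)
}
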