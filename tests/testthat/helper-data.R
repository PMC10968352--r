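# small fixture builders used across the suite (all data generated in code)

fs_default <- 128

# build a single epoch directly from named channel signals
epoch_from <- function(signals, fs = fs_default, swb = 5,
                       bad = character(0)) {
  dur <- length(signals[[1]]) / fs
  rec <- new_recording(do.call(rbind, signals), fs, names(signals),
                       bad_channels = bad)
  extract_epochs(rec, data.frame(time_s = dur, swb = swb),
                 duration = dur)[[1]]
}

# a broadband test signal with power in every band
broadband <- function(n, seed = 42, fs = fs_default) {
  set.seed(seed)
  bandpass(rnorm(n), fs, band_def("non"))
}

# a tiny synthetic recording config (short run, two bands)
tiny_config <- function(seed = 1, ...) {
  synth_config(n_participants = 1, n_runs_per_participant = 1,
               run_duration = 120,
               band_amplitudes = c(theta = 10, alpha = 15),
               left_handed_fraction = 0, seed = seed, ...)
}

# dataset assembled from generated SWB sequences without EEG (participant
# selection only inspects handedness and reports)
reports_only_dataset <- function(hands, probs_list, n_runs = 3,
                                 seed = 1) {
  participants <- vector("list", length(hands))
  for (i in seq_along(hands)) {
    probs <- probs_list[[i]]
    cfg <- synth_config(n_participants = 1, n_runs_per_participant = n_runs,
                        swb_probs = probs, left_handed_fraction = 0,
                        seed = seed)
    runs <- lapply(seq_len(n_runs), function(r) {
      rep <- generate_swb_sequence(cfg, seed * 1000 + i * 100 + r)
      list(recording = NULL, reports = rep)
    })
    participants[[i]] <- list(id = sprintf("P%02d", i),
                              handedness = hands[i], runs = runs)
  }
  structure(list(participants = participants, config = NULL),
            class = "swb_dataset")
}

# brute-force Benjamini-Yekutieli adjustment straight from the formula
by_brute <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    j <- seq(i, m)
    min(m * cm * ps[j] / j)
  }, numeric(1))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
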