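# Orchestration: participant selection, test-family enumeration, execution
# of the balanced-regression inference over the family, FDR, reporting.

#' Configuration of one analysis run
#'
#' @param pair_universe Which contralateral family to test:
#'   `"anterior"` (right frontal x left frontal, 16 pairs),
#'   `"posterior"` (right x left posterior, 9 pairs), or `"quadrants"`
#'   (anterior and posterior quadrant averages, 2 pairs).
#' @param bands Bands to test (default all six).
#' @param reference `"original"`, or `"AF3"` / `"F3"` to re-reference the
#'   posterior sensors; only meaningful (and only permitted) for the
#'   posterior and quadrant universes.
#' @param alpha_fdr FDR level for the Benjamini-Yekutieli procedure
#'   (default 0.1).
#' @param n_repeats SMOTE + regression repeats per participant
#'   (default 10).
#' @param epoch_duration Epoch length in seconds (default 10).
#' @param seed Master seed; every random element of the analysis derives
#'   from it.
#' @param k_neighbors SMOTE neighbourhood size (default 5, auto-reduced).
#' @param orientation Regression orientation passed to
#'   [fit_participant_slope()].
#' @param detect_bad Run probability-based bad-channel detection
#'   (default TRUE).
#' @param prefilter Band-pass epochs before spectral estimation
#'   (default TRUE).
#' @param seg_len,overlap Welch parameters.
#' @return A validated list of class `"analysis_config"`.
#' @export
analysis_config <- function(pair_universe = c("anterior", "posterior",
                                              "quadrants"),
                            bands = band_table()$name,
                            reference = c("original", "AF3", "F3"),
                            alpha_fdr = 0.1, n_repeats = 10,
                            epoch_duration = 10, seed = 1L,
                            k_neighbors = 5, detect_bad = TRUE,
                            prefilter = TRUE, seg_len = 256,
                            overlap = 0.5,
                            orientation = c("swb_on_asym",
                                            "asym_on_swb")) {
  orientation <- match.arg(orientation)
  pair_universe <- sub("_pairs$", "", pair_universe)
  pair_universe <- match.arg(pair_universe)
  reference <- match.arg(reference)
  bands <- band_table()$name[match(bands, band_table()$name)]
  if (anyNA(bands) || !length(bands)) stop("unknown band in 'bands'")
  if (reference != "original" && pair_universe == "anterior")
    stop("re-referencing applies to the posterior sensors only; ",
         "the anterior universe must use the original reference")
  structure(list(pair_universe = pair_universe, bands = bands,
                 reference = reference, alpha_fdr = alpha_fdr,
                 n_repeats = n_repeats, epoch_duration = epoch_duration,
                 seed = as.integer(seed), k_neighbors = k_neighbors,
                 detect_bad = detect_bad, prefilter = prefilter,
                 seg_len = seg_len, overlap = overlap,
                 orientation = orientation),
            class = "analysis_config")
}

#' Select participants for analysis
#'
#' Excludes left-handed participants (handedness interacts with
#' lateralization in ways the group inference does not model), then
#' excludes participants whose pooled SWB reports leave fewer than 3
#' distinct ratings after dropping ratings reported fewer than 3 times.
#'
#' @param dataset An `swb_dataset`.
#' @return List with `included` (participant ids) and `exclusions` (data
#'   frame of id, reason). Zero survivors is an error.
#' @export
select_participants <- function(dataset) {
  included <- character(0)
  excl_id <- excl_reason <- character(0)
  for (p in dataset$participants) {
    if (identical(p$handedness, "left")) {
      excl_id <- c(excl_id, p$id)
      excl_reason <- c(excl_reason, "left-handed")
      next
    }
    swb <- unlist(lapply(p$runs, function(r) r$reports$swb))
    f <- filter_participant_swb(data.frame(value = 0, swb = swb))
    if (f$excluded) {
      excl_id <- c(excl_id, p$id)
      excl_reason <- c(excl_reason,
                       "fewer than 3 distinct SWB values after filtering")
      next
    }
    included <- c(included, p$id)
  }
  if (!length(included)) {
    stop("no participants remain after exclusion; reasons: ",
         paste(paste0(excl_id, " (", excl_reason, ")"), collapse = "; "))
  }
  list(included = included,
       exclusions = data.frame(participant_id = excl_id,
                               reason = excl_reason,
                               stringsAsFactors = FALSE))
}

#' Enumerate the hypothesis-test family
#'
#' Cartesian product of the configured pair universe and bands under one
#' reference scheme, in deterministic band-major order (then ch1, then
#' ch2). The anterior universe crosses the four right frontal channels
#' with the four left (16 pairs), the posterior universe three with three
#' (9 pairs), the quadrant universe pairs the right with the left quadrant
#' within the anterior and posterior regions (2 pairs).
#'
#' @param config An [analysis_config()].
#' @return Data frame with columns `band`, `ch1`, `ch2`.
#' @export
#' @examples
#' nrow(enumerate_tests(analysis_config("anterior")))   # 96
#' nrow(enumerate_tests(analysis_config("posterior")))  # 54
#' nrow(enumerate_tests(analysis_config("quadrants")))  # 12
enumerate_tests <- function(config) {
  pairs <- switch(config$pair_universe,
    anterior  = expand.grid(ch2 = .left_anterior, ch1 = .right_anterior,
                            stringsAsFactors = FALSE),
    posterior = expand.grid(ch2 = .left_posterior, ch1 = .right_posterior,
                            stringsAsFactors = FALSE),
    quadrants = data.frame(
      ch2 = c("left_anterior", "left_posterior"),
      ch1 = c("right_anterior", "right_posterior"),
      stringsAsFactors = FALSE))
  out <- expand.grid(ch2i = seq_len(nrow(pairs)), band = config$bands,
                     stringsAsFactors = FALSE)
  out <- data.frame(band = out$band,
                    ch1 = pairs$ch1[out$ch2i], ch2 = pairs$ch2[out$ch2i],
                    stringsAsFactors = FALSE)
  # band-major, then ch1 (enumeration order), then ch2
  if (!nrow(out)) stop("empty test family")
  out
}

# preprocess one recording per the config; returns the recording (or NULL
# if unusable) plus log entries
preprocess_recording <- function(rec, config) {
  log <- character(0)
  rec <- detrend(rec)
  if (isTRUE(config$detect_bad)) {
    bad <- detect_bad_channels(rec)
    if (length(bad)) {
      rec$bad_channels <- union(rec$bad_channels, bad)
      log <- c(log, paste0("bad channels flagged: ",
                           paste(bad, collapse = ",")))
    }
  }
  if (config$reference != "original") {
    if (config$reference %in% rec$bad_channels) {
      return(list(rec = NULL,
                  log = c(log, paste0("reference channel ", config$reference,
                                      " flagged bad; run skipped"))))
    }
    rec <- rereference(rec, config$reference)
  }
  list(rec = rec, log = log)
}

# batched Welch densities for signals held as time x channels columns
welch_dens_cols <- function(xm, fs, seg_len, overlap) {
  n <- nrow(xm); nch <- ncol(xm)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq.int(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / seg_len))
  idx <- outer(0:(seg_len - 1L), starts, `+`)
  nseg <- length(starts)
  seg <- matrix(0, seg_len, nseg * nch)
  for (c in seq_len(nch))
    seg[, (c - 1L) * nseg + seq_len(nseg)] <- xm[, c][idx] * w
  sp <- Mod(mvfft(seg))^2
  nf <- seg_len %/% 2 + 1L
  scale <- 1 / (fs * sum(w^2))
  dens <- matrix(0, nf, nch)
  for (c in seq_len(nch)) {
    pk <- rowMeans(sp[1:nf, (c - 1L) * nseg + seq_len(nseg), drop = FALSE]) *
      scale
    pk[2:(nf - 1L)] <- 2 * pk[2:(nf - 1L)]
    dens[, c] <- pk
  }
  dens
}

# per-epoch asymmetry values for every test row; returns numeric vector
# aligned with `tests` (NA where a channel/quadrant is unavailable)
epoch_test_values <- function(epoch, tests, config) {
  vals <- rep(NA_real_, nrow(tests))
  needed <- unique(c(tests$ch1, tests$ch2))
  sig <- list()
  for (nm in needed) {
    s <- tryCatch(epoch_signal(epoch, nm), error = function(e) NULL)
    if (!is.null(s)) sig[[nm]] <- s
  }
  if (length(sig) < 2) return(vals)
  sigm <- matrix(unlist(sig, use.names = FALSE),
                 ncol = length(sig))                # time x signals
  fs <- epoch$fs
  nfreq <- (0:(config$seg_len %/% 2)) * fs / config$seg_len
  for (b in unique(tests$band)) {
    cb <- clip_band(b, fs)
    xm <- sigm
    if (config$prefilter) {
      g <- butter_zerophase_gain(nrow(sigm), fs, cb$f_low, cb$f_high)
      xm <- Re(mvfft(mvfft(sigm) * g, inverse = TRUE)) / nrow(sigm)
    }
    dens <- welch_dens_cols(xm, fs, config$seg_len, config$overlap)
    ld <- log(dens[nfreq >= cb$f_low & nfreq <= cb$f_high, , drop = FALSE])
    rows <- which(tests$band == b)
    for (ti in rows) {
      i1 <- match(tests$ch1[ti], names(sig))
      i2 <- match(tests$ch2[ti], names(sig))
      if (is.na(i1) || is.na(i2)) next
      d <- ld[, i1] - ld[, i2]         # -Inf marks zero-density bins
      ok <- is.finite(d)
      if (any(ok)) vals[ti] <- mean(d[ok])
    }
  }
  vals
}

# collect per-epoch asymmetry samples for every test and included
# participant; returns list(store = per-test list of per-participant
# data.frames, log = preprocessing log)
gather_samples <- function(dataset, config, tests, included) {
  nt <- nrow(tests)
  log <- data.frame(participant_id = character(0), run_id = character(0),
                    event = character(0), stringsAsFactors = FALSE)
  store <- vector("list", nt)
  for (ti in seq_len(nt)) store[[ti]] <- list()
  for (p in dataset$participants) {
    if (!p$id %in% included) next
    vals_p <- vector("list", nt)
    swb_p <- vector("list", nt)
    epi_p <- vector("list", nt)
    run_p <- vector("list", nt)
    for (run in p$runs) {
      pp <- preprocess_recording(run$recording, config)
      for (entry in pp$log)
        log <- rbind(log, data.frame(participant_id = p$id,
                                     run_id = as.character(run$recording$run_id),
                                     event = entry, stringsAsFactors = FALSE))
      if (is.null(pp$rec)) next
      epochs <- withCallingHandlers(
        extract_epochs(pp$rec, run$reports, config$epoch_duration),
        warning = function(w) {
          log <<- rbind(log, data.frame(participant_id = p$id,
                                        run_id = as.character(run$recording$run_id),
                                        event = conditionMessage(w),
                                        stringsAsFactors = FALSE))
          invokeRestart("muffleWarning")
        })
      for (e in epochs) {
        v <- epoch_test_values(e, tests, config)
        for (ti in which(!is.na(v))) {
          vals_p[[ti]] <- c(vals_p[[ti]], v[ti])
          swb_p[[ti]] <- c(swb_p[[ti]], e$swb)
          epi_p[[ti]] <- c(epi_p[[ti]], e$t_report)
          run_p[[ti]] <- c(run_p[[ti]], run$recording$run_id)
        }
      }
    }
    for (ti in seq_len(nt)) {
      if (length(vals_p[[ti]]))
        store[[ti]][[p$id]] <- data.frame(participant_id = p$id,
                                          run_id = run_p[[ti]],
                                          epoch = epi_p[[ti]],
                                          value = vals_p[[ti]],
                                          swb = swb_p[[ti]],
                                          stringsAsFactors = FALSE)
    }
  }
  list(store = store, log = log)
}

#' Long-format per-epoch asymmetry samples
#'
#' Runs participant selection, preprocessing and the per-epoch asymmetry
#' computation for every enumerated test, returning the samples as one
#' long data frame (one row per participant, run, epoch, pair and band)
#' suitable for export with [utils::write.table()].
#'
#' @param dataset An `swb_dataset`.
#' @param config An [analysis_config()].
#' @return Data frame with columns `participant_id`, `run_id`, `epoch`,
#'   `reference`, `band`, `ch1`, `ch2`, `value`, `swb`.
#' @export
collect_asym_samples <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "swb_dataset"),
            inherits(config, "analysis_config"))
  sel <- select_participants(dataset)
  tests <- enumerate_tests(config)
  gs <- gather_samples(dataset, config, tests, sel$included)
  out <- list()
  for (ti in seq_len(nrow(tests))) {
    for (pid in names(gs$store[[ti]])) {
      d <- gs$store[[ti]][[pid]]
      out[[length(out) + 1L]] <- data.frame(
        participant_id = d$participant_id, run_id = d$run_id,
        epoch = d$epoch, reference = config$reference,
        band = tests$band[ti], ch1 = tests$ch1[ti], ch2 = tests$ch2[ti],
        value = d$value, swb = d$swb, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full asymmetry-SWB group analysis
#'
#' Executes the complete inference over a dataset: participant selection,
#' per-run preprocessing (detrend, twice-run probability-based bad-channel
#' detection, optional posterior re-referencing), epoch extraction, the
#' per-epoch log band-power asymmetry for every enumerated
#' (pair-or-quadrant, band) test, the per-participant SWB filtering /
#' SMOTE-balanced repeated regression, the group-level slope t-test, and
#' Benjamini-Yekutieli FDR control across the family. Deterministic given
#' the config seed.
#'
#' Tests with fewer than 2 surviving participants are reported with
#' status `"insufficient_data"` and excluded from the FDR family.
#'
#' @param dataset An `swb_dataset` (see [simulate_dataset()] or
#'   [read_dataset()]).
#' @param config An [analysis_config()].
#' @return Object of class `"asym_swb_result"`: `$results` holds one row
#'   per test (band, ch1, ch2, reference, n, mean_slope, t_stat, p_value,
#'   ci_low, ci_high, p_adjusted, significant, status), sorted by adjusted
#'   p-value; plus `$exclusions`, `$family_size`, `$log`, `$config`.
#' @export
run_analysis <- function(dataset, config = analysis_config()) {
  stopifnot(inherits(dataset, "swb_dataset"),
            inherits(config, "analysis_config"))
  sel <- select_participants(dataset)
  tests <- enumerate_tests(config)
  nt <- nrow(tests)
  gs <- gather_samples(dataset, config, tests, sel$included)
  store <- gs$store
  log <- gs$log
  # inference per test
  res <- data.frame(band = tests$band, ch1 = tests$ch1, ch2 = tests$ch2,
                    reference = config$reference, n = NA_integer_,
                    mean_slope = NA_real_, t_stat = NA_real_,
                    p_value = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_adjusted = NA_real_,
                    significant = FALSE, status = "insufficient_data",
                    stringsAsFactors = FALSE)
  pid_index <- seq_along(sel$included)
  names(pid_index) <- sel$included
  for (ti in seq_len(nt)) {
    fits <- list()
    for (pid in names(store[[ti]])) {
      f <- filter_participant_swb(store[[ti]][[pid]])
      if (f$excluded || !nrow(f$samples)) next
      fit <- suppressWarnings(fit_participant_slope(
        f$samples, n_repeats = config$n_repeats,
        seed = child_seed(config$seed, ti, pid_index[[pid]]),
        k_neighbors = config$k_neighbors,
        orientation = config$orientation))
      if (!is.null(fit)) fits[[pid]] <- fit
    }
    if (length(fits) < 2) next
    slopes <- vapply(fits, `[[`, numeric(1), "slope")
    if (stats::var(slopes) == 0) next
    g <- group_slope_test(fits)
    res$n[ti] <- g$n; res$mean_slope[ti] <- g$mean_slope
    res$t_stat[ti] <- g$t_stat; res$p_value[ti] <- g$p_value
    res$ci_low[ti] <- g$ci_low; res$ci_high[ti] <- g$ci_high
    res$status[ti] <- "ok"
  }
  ok <- res$status == "ok"
  if (any(ok)) {
    fdr <- by_fdr(res$p_value[ok], config$alpha_fdr)
    res$p_adjusted[ok] <- fdr$adjusted
    res$significant[ok] <- fdr$reject
  }
  res <- res[order(res$status != "ok", res$p_adjusted,
                   seq_len(nrow(res))), ]
  rownames(res) <- NULL
  structure(list(results = res, exclusions = sel$exclusions,
                 family_size = sum(ok), log = log, config = config),
            class = "asym_swb_result")
}

#' @export
print.asym_swb_result <- function(x, ...) {
  cat(sprintf(
    "Asymmetry-SWB group analysis: %s universe, %s reference, %d band(s)\n",
    x$config$pair_universe, x$config$reference, length(x$config$bands)))
  cat(sprintf("  %d tests (%d in the FDR family), %d participant(s) excluded\n",
              nrow(x$results), x$family_size, nrow(x$exclusions)))
  sig <- x$results[x$results$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig)) {
    cat(sprintf("  %d test(s) significant at BY-FDR alpha = %g:\n",
                nrow(sig), x$config$alpha_fdr))
    print(sig[, c("band", "ch1", "ch2", "p_value", "ci_low", "ci_high",
                  "p_adjusted")], digits = 4)
  } else {
    cat(sprintf("  no tests significant at alpha = %g\n",
                x$config$alpha_fdr))
  }
  invisible(x)
}

#' @export
summary.asym_swb_result <- function(object, ...) {
  cat(sprintf("Family: %s x {%s}, reference %s, %d OK tests\n",
              object$config$pair_universe,
              paste(object$config$bands, collapse = ", "),
              object$config$reference, object$family_size))
  if (nrow(object$exclusions)) {
    cat("Excluded participants:\n")
    print(object$exclusions)
  }
  print(utils::head(object$results, 10), digits = 4)
  invisible(object)
}

#' @export
as.data.frame.asym_swb_result <- function(x, ...) x$results

#' Write the analysis report
#'
#' Writes the results table as TSV, a human-readable summary of the
#' significant rows (band, ch1, ch2, p-value, CI bounds, adjusted p), and
#' the preprocessing/run log as TSV.
#'
#' @param result An `asym_swb_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "asym_swb_result"))
  if (!nrow(result$results)) stop("empty results; nothing to report")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "results.tsv")
  utils::write.table(result$results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sm <- file.path(dir, "summary.txt")
  con <- file(sm, "w"); on.exit(close(con))
  writeLines(sprintf("Asymmetry-SWB analysis: %s universe, reference %s",
                     result$config$pair_universe, result$config$reference),
             con)
  writeLines(sprintf("FDR family size: %d, alpha = %g",
                     result$family_size, result$config$alpha_fdr), con)
  sig <- result$results[result$results$significant %in% TRUE, ,
                        drop = FALSE]
  if (!nrow(sig)) {
    writeLines(sprintf("no tests significant at alpha = %g",
                       result$config$alpha_fdr), con)
  } else {
    writeLines("significant tests (BY-adjusted):", con)
    writeLines(sprintf("  %-6s %-16s %-16s p=%.4g CI=(%.4g, %.4g) p_adj=%.4g",
                       sig$band, sig$ch1, sig$ch2, sig$p_value,
                       sig$ci_low, sig$ci_high, sig$p_adjusted), con)
  }
  lg <- file.path(dir, "run_log.tsv")
  utils::write.table(result$log, lg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(results = tsv, summary = sm, log = lg))
}
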