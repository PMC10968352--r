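# On-disk dataset formats: a wide CSV dialect or 16-bit EDF for the EEG,
# TSV for the SWB reports, TSV for participant metadata.

# ---- EDF (European Data Format), minimal 16-bit implementation ----------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# format a physical bound into EDF's 8-char ASCII field and return the
# value the field actually encodes (so encoding and header agree exactly);
# 7 chars max so the minus sign of the lower bound still fits
edf_phys <- function(v) {
  for (d in 6:1) {
    # round the bound upward so no sample falls outside the encoded range
    cand <- signif(v, d)
    if (cand < v) cand <- signif(v * (1 + 10^(-d + 1)), d)
    s <- gsub(" ", "", formatC(cand, format = "g"))
    val <- suppressWarnings(as.numeric(s))
    if (nchar(s) <= 7 && !is.na(val) && val >= v)
      return(list(text = edf_pad(s, 8), value = val))
  }
  stop("cannot encode physical range ", v, " in an 8-character EDF field")
}

write_edf <- function(samples, fs, channels, path) {
  n <- ncol(samples)
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of 1-second records")
  n_rec <- n %/% fs
  ns <- nrow(samples)
  pmax_raw <- pmax(apply(abs(samples), 1, max), 1)
  phys <- lapply(pmax_raw, edf_phys)
  con <- file(path, "wb"); on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 + 256 * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(channels, 16)
  field(rep("", ns), 80)                        # transducer
  field(rep("uV", ns), 8)                       # physical dimension
  field(vapply(phys, function(p) paste0("-", gsub(" ", "", p$text)), ""), 8)
  field(vapply(phys, function(p) gsub(" ", "", p$text), ""), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)                        # prefiltering
  field(rep(fs, ns), 8)                         # samples per record
  field(rep("", ns), 32)
  pv <- vapply(phys, `[[`, numeric(1), "value")
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (c in seq_len(ns)) {
      x <- samples[c, cols]
      dig <- round((x + pv[c]) / (2 * pv[c]) * 65535 - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trimws(rd(8))
  if (version != "0")
    stop("malformed EDF file '", path, "': bad version field '",
         version, "'")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                          # header bytes
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(n_rec) || is.na(ns) || ns < 1)
    stop("malformed EDF file '", path, "': unreadable record counts")
  fields <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- fields(16)
  fields(80); fields(8)
  pmin_v <- as.numeric(fields(8)); pmax_v <- as.numeric(fields(8))
  dmin_v <- as.numeric(fields(8)); dmax_v <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  fs <- spr[1] / rec_dur
  samples <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (c in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[c], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) < spr[c])
        stop("malformed EDF file '", path, "': truncated data record ", r)
      samples[c, ((r - 1L) * spr[c] + 1L):(r * spr[c])] <-
        (dig - dmin_v[c]) / (dmax_v[c] - dmin_v[c]) *
          (pmax_v[c] - pmin_v[c]) + pmin_v[c]
    }
  }
  list(samples = samples, fs = fs, channels = labels)
}

# ---- wide-CSV dialect ---------------------------------------------------

write_recording_csv <- function(samples, channels, path) {
  # full double precision so the round trip is bit-exact
  df <- as.data.frame(lapply(seq_len(nrow(samples)), function(i)
    formatC(samples[i, ], format = "g", digits = 17)))
  names(df) <- channels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_recording_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop("malformed CSV file '", path, "': ",
                        conditionMessage(e)))
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("malformed CSV file '", path, "': non-numeric sample column '",
         names(df)[which(!vapply(df, is.numeric, TRUE))[1]], "'")
  list(samples = t(as.matrix(df)), channels = names(df))
}

# ---- dataset-level round trip -------------------------------------------

#' Write a dataset to disk
#'
#' Lays out a dataset directory: one EEG file per run (`<id>_run<k>.csv`
#' wide CSV with a channel-label header, or 16-bit EDF), the SWB reports
#' as `swb_reports.tsv` (participant_id, run_id, time_s, swb), and
#' participant metadata with seed provenance as `metadata.tsv`.
#'
#' @param dataset An `swb_dataset`.
#' @param path Output directory (created if missing).
#' @param format `"csv"` (exact round trip) or `"edf"` (16-bit quantized).
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  reports <- list(); meta <- list()
  for (p in dataset$participants) {
    seeds <- vapply(p$runs, function(r)
      if (!is.null(r$seeds)) paste(r$seeds, collapse = ":") else "",
      "")
    meta[[p$id]] <- data.frame(participant_id = p$id,
                               handedness = p$handedness,
                               seeds = paste(seeds, collapse = ";"),
                               stringsAsFactors = FALSE)
    for (run in p$runs) {
      rec <- run$recording
      base <- sprintf("%s_run%d", p$id, rec$run_id)
      if (format == "csv")
        write_recording_csv(rec$samples, rec$channels,
                            file.path(path, paste0(base, ".csv")))
      else
        write_edf(rec$samples, rec$fs, rec$channels,
                  file.path(path, paste0(base, ".edf")))
      reports[[base]] <- data.frame(participant_id = p$id,
                                    run_id = rec$run_id,
                                    time_s = run$reports$time_s,
                                    swb = run$reports$swb,
                                    stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, reports),
                     file.path(path, "swb_reports.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, meta), file.path(path, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("format: ", format),
               paste0("sampling_rate: ",
                      dataset$participants[[1]]$runs[[1]]$recording$fs)),
             file.path(path, "dataset_info.txt"))
  invisible(path)
}

#' Read a dataset from disk
#'
#' Inverse of [write_dataset()]. Channel labels not in the 14-name montage
#' are dropped with a warning; malformed files raise a parse error naming
#' the offending file.
#'
#' @param path Dataset directory.
#' @return An `swb_dataset`.
#' @export
read_dataset <- function(path) {
  info <- readLines(file.path(path, "dataset_info.txt"))
  fmt <- sub("^format: ", "", grep("^format:", info, value = TRUE))
  fs <- as.numeric(sub("^sampling_rate: ", "",
                       grep("^sampling_rate:", info, value = TRUE)))
  meta <- utils::read.delim(file.path(path, "metadata.tsv"),
                            colClasses = "character")
  reports <- utils::read.delim(file.path(path, "swb_reports.tsv"))
  participants <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pid <- meta$participant_id[i]
    prep <- reports[reports$participant_id == pid, , drop = FALSE]
    run_ids <- sort(unique(prep$run_id))
    runs <- vector("list", length(run_ids))
    for (j in seq_along(run_ids)) {
      base <- sprintf("%s_run%d", pid, run_ids[j])
      f <- file.path(path, paste0(base, ".", fmt))
      raw <- if (fmt == "csv") read_recording_csv(f) else read_edf(f)
      keep <- raw$channels %in% montage_channels()
      if (!all(keep)) {
        warning("file ", basename(f), ": ignoring non-montage channel(s) ",
                paste(raw$channels[!keep], collapse = ", "))
      }
      rec <- new_recording(raw$samples[keep, , drop = FALSE],
                           raw$fs %||% fs, raw$channels[keep],
                           participant_id = pid, run_id = run_ids[j])
      runs[[j]] <- list(recording = rec,
                        reports = prep[prep$run_id == run_ids[j], ,
                                       drop = FALSE])
    }
    participants[[i]] <- list(id = pid, handedness = meta$handedness[i],
                              runs = runs)
  }
  structure(list(participants = participants, config = NULL),
            class = "swb_dataset")
}
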