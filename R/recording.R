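#' Construct an EEG recording object
#'
#' A recording is one participant-run of multi-channel EEG: a channels x
#' time matrix in microvolts plus montage labels, sampling rate, the active
#' reference scheme, and the set of channels flagged bad.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels (rows of `samples`);
#'   must be unique and drawn from [montage_channels()].
#' @param participant_id,run_id Identifiers carried through the pipeline.
#' @param reference Reference tag, one of `"original"`, `"AF3"`, `"F3"`.
#' @param bad_channels Character vector of labels flagged bad.
#' @return An object of class `"eeg_recording"`.
#' @export
new_recording <- function(samples, fs, channels = montage_channels(),
                          participant_id = "P01", run_id = 1L,
                          reference = "original",
                          bad_channels = character(0)) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channels))
    stop("samples has ", nrow(samples), " rows but ", length(channels),
         " channel labels were given")
  if (anyDuplicated(channels))
    stop("duplicate channel labels")
  unknown <- setdiff(channels, montage_channels())
  if (length(unknown))
    stop("labels not in the 14-channel montage: ",
         paste(unknown, collapse = ", "))
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples")
  reference <- match.arg(reference, c("original", "AF3", "F3"))
  rownames(samples) <- channels
  structure(
    list(participant_id = participant_id, run_id = run_id,
         fs = fs, channels = channels, samples = samples,
         reference = reference,
         bad_channels = intersect(bad_channels, channels)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording %s run %s: %d channels x %d samples @ %g Hz, ref=%s%s>\n",
    x$participant_id, x$run_id, nrow(x$samples), ncol(x$samples), x$fs,
    x$reference,
    if (length(x$bad_channels))
      paste0(", bad={", paste(x$bad_channels, collapse = ","), "}") else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs

# internal epoch constructor; `samples` is channels x n matrix
new_epoch <- function(samples, fs, channels, swb, t_report,
                      bad_channels = character(0),
                      participant_id = NA_character_, run_id = NA) {
  structure(
    list(samples = samples, fs = fs, channels = channels,
         swb = as.integer(swb), t_report = t_report,
         bad_channels = bad_channels,
         participant_id = participant_id, run_id = run_id),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch ending t=%gs, swb=%d, %d channels x %d samples>\n",
              x$t_report, x$swb, nrow(x$samples), ncol(x$samples)))
  invisible(x)
}
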