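#' The 14-channel consumer-headset montage
#'
#' Channel labels of the 14-electrode 10-20 subset used throughout the
#' package, in recording order. The native reference is the headset's
#' CMS/DRL pair (P3/P4), tagged `"original"`.
#'
#' @return Character vector of 14 channel labels.
#' @export
#' @examples
#' montage_channels()
montage_channels <- function() {
  c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
    "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
}

#' Scalp quadrant membership
#'
#' Channel groups used for quadrant-averaged asymmetries: four frontal
#' sensors per anterior quadrant, three temporo-parieto-occipital sensors
#' per posterior quadrant.
#'
#' @return Named list of character vectors.
#' @export
quadrant_channels <- function() {
  list(
    left_anterior   = c("AF3", "F3", "F7", "FC5"),
    right_anterior  = c("AF4", "F4", "F8", "FC6"),
    left_posterior  = c("T7", "P7", "O1"),
    right_posterior = c("T8", "P8", "O2")
  )
}

# hemisphere-ordered channel sets used to enumerate contralateral pairs;
# ch1 is always drawn from the right hemisphere, ch2 from the left
.right_anterior  <- c("AF4", "F4", "F8", "FC6")
.left_anterior   <- c("AF3", "F3", "F7", "FC5")
.right_posterior <- c("T8", "P8", "O2")
.left_posterior  <- c("T7", "P7", "O1")
.posterior_set   <- c("T7", "P7", "O1", "O2", "P8", "T8")

#' Canonical frequency-band table
#'
#' The six analysis bands: delta 0.5-3 Hz, theta 4-7 Hz, alpha 8-13 Hz,
#' beta 14-30 Hz, gamma 31-100 Hz, and the unfiltered control band "non"
#' spanning 0.5-100 Hz. Upper edges above 0.95 x Nyquist are clipped at
#' filter-design time, not here.
#'
#' @return A data.frame with columns `name`, `f_low`, `f_high`.
#' @export
#' @examples
#' band_table()
band_table <- local({
  tab <- data.frame(
    name   = c("delta", "theta", "alpha", "beta", "gamma", "non"),
    f_low  = c(0.5, 4, 8, 14, 31, 0.5),
    f_high = c(3, 7, 13, 30, 100, 100),
    stringsAsFactors = FALSE)
  function() tab
})

#' Look up a band definition by name
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`,
#'   `"non"`, or an already-built band definition (returned unchanged after
#'   validation).
#' @return A list with elements `name`, `f_low`, `f_high` of class
#'   `"band_def"`.
#' @export
#' @examples
#' band_def("alpha")
band_def <- local({
  tab <- NULL
  function(name) {
    if (inherits(name, "band_def")) {
      stopifnot(name$f_low > 0, name$f_low < name$f_high)
      return(name)
    }
    if (is.null(tab)) {
      bt <- band_table()
      tab <<- lapply(seq_len(nrow(bt)), function(i)
        structure(list(name = bt$name[i], f_low = bt$f_low[i],
                       f_high = bt$f_high[i]), class = "band_def"))
      names(tab) <<- bt$name
    }
    b <- tab[[name]]
    if (is.null(b))
      stop("unknown band '", name, "'; expected one of: ",
           paste(names(tab), collapse = ", "))
    b
  }
})

#' @export
print.band_def <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$f_low, x$f_high))
  invisible(x)
}
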