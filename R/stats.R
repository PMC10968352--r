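# Group inference: per-participant SWB-class filtering, SMOTE balancing,
# repeated regression with averaged coefficients, one-sample t-test of the
# participant slopes, Benjamini-Yekutieli FDR.

#' Filter a participant's samples by SWB class frequency
#'
#' Drops every sample whose SWB rating occurs fewer than 3 times in this
#' participant's data (3 being the minimum class size the balancing step
#' can interpolate from), then marks the participant excluded when fewer
#' than 3 distinct ratings remain — too few levels for a meaningful linear
#' regression.
#'
#' @param samples Data frame of asymmetry samples with at least columns
#'   `value` and `swb` (one participant, one pair, one band).
#' @param min_count Minimum occurrences per rating (default 3).
#' @param min_distinct Minimum distinct surviving ratings (default 3).
#' @return List with elements `samples` (the kept rows) and `excluded`
#'   (logical).
#' @export
#' @examples
#' s <- data.frame(value = rnorm(9), swb = c(6, 6, 6, 7, 7, 7, 8, 8, 2))
#' filter_participant_swb(s)   # rating 2 and 8 dropped -> excluded
filter_participant_swb <- function(samples, min_count = 3, min_distinct = 3) {
  counts <- table(samples$swb)
  keep_levels <- as.numeric(names(counts)[counts >= min_count])
  kept <- samples[samples$swb %in% keep_levels, , drop = FALSE]
  list(samples = kept, excluded = length(keep_levels) < min_distinct)
}

#' Balance SWB classes by synthetic minority over-sampling (SMOTE)
#'
#' Oversamples every minority SWB class up to the majority-class count.
#' Each synthetic point interpolates between a randomly chosen class
#' member `x` and a randomly chosen one of its `k` nearest same-class
#' neighbours `x'`: `x + u (x' - x)` with `u ~ Uniform(0, 1)`. The feature
#' space is the one-dimensional asymmetry value, the class label the SWB
#' rating. Original samples are always retained; `k` is reduced to
#' `class size - 1` where necessary.
#'
#' @param samples Data frame with columns `value` and `swb`.
#' @param k_neighbors Number of nearest neighbours (default 5).
#' @param seed Seed making the oversampling reproducible.
#' @return Data frame with columns `value`, `swb`, `synthetic` (logical);
#'   every class has the majority count of rows.
#' @export
smote_balance <- function(samples, k_neighbors = 5, seed = 1L) {
  classes <- sort(unique(samples$swb))
  sizes <- vapply(classes, function(s) sum(samples$swb == s), integer(1))
  if (any(sizes < 2))
    stop("SWB class(es) ", paste(classes[sizes < 2], collapse = ", "),
         " have fewer than 2 samples; interpolation is impossible")
  sm <- smote_values(samples$value, samples$swb, k_neighbors, seed)
  data.frame(value = sm$value, swb = sm$swb, synthetic = sm$synthetic)
}

# SMOTE core on bare vectors (hot path of the repeated fits); the
# neighbour structure consumes no randomness, so it is computed once and
# reused across seeded draws
smote_prep <- function(value, swb, k_neighbors) {
  classes <- sort(unique(swb))
  per <- lapply(classes, function(s) {
    v <- value[swb == s]
    k <- min(k_neighbors, length(v) - 1L)
    nn <- matrix(0L, length(v), k)
    for (i in seq_along(v)) {
      d <- abs(v - v[i]); d[i] <- Inf
      nn[i, ] <- order(d)[seq_len(k)]      # k nearest same-class neighbours
    }
    list(v = v, nn = nn, k = k)
  })
  list(classes = classes, per = per,
       target = max(vapply(per, function(p) length(p$v), integer(1))),
       value = value, swb = swb)
}

smote_draw <- function(prep, seed) {
  sv <- ss <- list()
  with_seed(seed, {
    for (ci in seq_along(prep$classes)) {
      p <- prep$per[[ci]]
      m <- prep$target - length(p$v)
      if (m == 0) next
      base <- sample.int(length(p$v), m, replace = TRUE)
      pick <- p$nn[cbind(base, sample.int(p$k, m, replace = TRUE))]
      u <- stats::runif(m)
      sv[[length(sv) + 1L]] <- p$v[base] + u * (p$v[pick] - p$v[base])
      ss[[length(ss) + 1L]] <- rep(prep$classes[ci], m)
    }
  })
  nsyn <- length(unlist(sv))
  list(value = c(prep$value, unlist(sv)), swb = c(prep$swb, unlist(ss)),
       synthetic = c(rep(FALSE, length(prep$value)), rep(TRUE, nsyn)))
}

smote_values <- function(value, swb, k_neighbors, seed) {
  smote_draw(smote_prep(value, swb, k_neighbors), seed)
}

#' Per-participant balanced-regression slope
#'
#' The participant-level estimate of the asymmetry-SWB relationship:
#' `n_repeats` times, balance the SWB classes with [smote_balance()] (a
#' fresh derived seed per repeat) and fit an ordinary least-squares
#' regression of SWB on the asymmetry value; report the averaged slope and
#' intercept. Repeats where the balanced asymmetry values are constant are
#' skipped with a warning; if no repeat survives, `NULL` is returned and
#' the participant is dropped for this test.
#'
#' @param samples Data frame with columns `value` and `swb`, already
#'   passed through [filter_participant_swb()].
#' @param n_repeats Number of SMOTE + fit repeats (default 10).
#' @param seed Master seed for the repeats.
#' @param k_neighbors Passed to [smote_balance()].
#' @param orientation `"swb_on_asym"` (default): SWB is the response and
#'   the slope is in SWB units per asymmetry unit; `"asym_on_swb"`
#'   reverses the roles. The group test only asks whether the slope
#'   differs from zero, and its sign is shared by both orientations.
#' @return Object of class `"swb_slope_fit"` (or `NULL`): slope and
#'   intercept are means over the per-repeat fits, which are retained in
#'   `$slopes` / `$intercepts`.
#' @export
fit_participant_slope <- function(samples, n_repeats = 10, seed = 1L,
                                  k_neighbors = 5,
                                  orientation = c("swb_on_asym",
                                                  "asym_on_swb")) {
  orientation <- match.arg(orientation)
  classes <- sort(unique(samples$swb))
  sizes <- vapply(classes, function(s) sum(samples$swb == s), integer(1))
  if (any(sizes < 2))
    stop("SWB class(es) ", paste(classes[sizes < 2], collapse = ", "),
         " have fewer than 2 samples; run filter_participant_swb first")
  prep <- smote_prep(samples$value, samples$swb, k_neighbors)
  slopes <- intercepts <- numeric(0)
  for (r in seq_len(n_repeats)) {
    bal <- smote_draw(prep, child_seed(seed, r))
    if (orientation == "swb_on_asym") {
      x <- bal$value; y <- bal$swb
    } else {
      x <- bal$swb; y <- bal$value
    }
    vx <- stats::var(x)
    if (vx == 0) {
      warning("repeat ", r, ": zero predictor variance after balancing; ",
              "repeat skipped")
      next
    }
    b <- stats::cov(x, y) / vx
    slopes <- c(slopes, b)
    intercepts <- c(intercepts, mean(y) - b * mean(x))
  }
  if (!length(slopes)) return(NULL)
  structure(list(slope = mean(slopes), intercept = mean(intercepts),
                 slopes = slopes, intercepts = intercepts,
                 n_repeats = n_repeats, n_repeats_used = length(slopes),
                 n_samples_used = nrow(samples),
                 participant_id = samples$participant_id[1] %||% NA),
            class = "swb_slope_fit")
}

#' @export
print.swb_slope_fit <- function(x, ...) {
  cat(sprintf(
    "<swb_slope_fit%s: slope %.4f, intercept %.4f (mean of %d repeats, %d samples)>\n",
    if (!is.na(x$participant_id)) paste0(" ", x$participant_id) else "",
    x$slope, x$intercept, x$n_repeats_used, x$n_samples_used))
  invisible(x)
}

#' @export
coef.swb_slope_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Group-level test of the mean participant slope
#'
#' One-sample two-sided t-test of the per-participant averaged slopes
#' against zero, with the 95% confidence interval of the mean slope.
#'
#' @param fits List of `"swb_slope_fit"` objects, or a numeric vector of
#'   slopes. At least 2 values with nonzero variance are required.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `n`, `mean_slope`, `t_stat`, `p_value`, `ci_low`,
#'   `ci_high`.
#' @export
#' @examples
#' group_slope_test(c(0.5, 1.0, 1.5))
group_slope_test <- function(fits, conf_level = 0.95) {
  slopes <- if (is.numeric(fits)) fits
            else vapply(fits, `[[`, numeric(1), "slope")
  if (length(slopes) < 2)
    stop("need at least 2 participant slopes, have ", length(slopes))
  if (stats::var(slopes) == 0)
    stop("participant slopes have zero variance; t-test undefined")
  tt <- stats::t.test(slopes, mu = 0, conf.level = conf_level)
  list(n = length(slopes), mean_slope = mean(slopes),
       t_stat = unname(tt$statistic), p_value = tt$p.value,
       ci_low = tt$conf.int[1], ci_high = tt$conf.int[2])
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Adjusts p-values for multiple testing under arbitrary dependence:
#' with `m` tests and the harmonic correction `c(m) = sum(1/i)`, the
#' sorted adjusted values are
#' `p~_(i) = min_{j >= i} ( m c(m) p_(j) / j )`, capped at 1. Rejections
#' are adjusted values at or below `alpha`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.1).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
#' @examples
#' by_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))$adjusted  # all 0.1141667
by_fdr <- function(p, alpha = 0.1) {
  if (!length(p)) return(list(adjusted = numeric(0), reject = logical(0)))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  adjusted <- stats::p.adjust(p, method = "BY")
  list(adjusted = adjusted, reject = adjusted <= alpha)
}
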