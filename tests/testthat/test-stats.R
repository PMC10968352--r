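# SWB filtering, SMOTE balancing, repeated regression, group test, BY FDR

samples_from_counts <- function(counts, seed = 1) {
  set.seed(seed)
  swb <- rep(as.numeric(names(counts)), counts)
  data.frame(value = rnorm(length(swb)), swb = swb)
}

test_that("SWB-class filtering applies the frequency and diversity rules", {
  # {6:7, 7:5, 8:2, 3:1}: ratings 8 and 3 dropped, 2 classes left -> excluded
  f <- filter_participant_swb(samples_from_counts(c("6" = 7, "7" = 5,
                                                    "8" = 2, "3" = 1)))
  expect_true(f$excluded)
  expect_setequal(unique(f$samples$swb), c(6, 7))

  # {5:3, 6:3, 7:3}: everything kept
  f2 <- filter_participant_swb(samples_from_counts(c("5" = 3, "6" = 3,
                                                     "7" = 3)))
  expect_false(f2$excluded)
  expect_equal(nrow(f2$samples), 9)

  # {6:10, 7:3, 8:3, 2:1}: rating 2 dropped, three classes survive
  f3 <- filter_participant_swb(samples_from_counts(c("6" = 10, "7" = 3,
                                                     "8" = 3, "2" = 1)))
  expect_false(f3$excluded)
  expect_setequal(unique(f3$samples$swb), c(6, 7, 8))
})

test_that("SMOTE balances class counts by within-class interpolation", {
  s <- samples_from_counts(c("6" = 5, "7" = 3))
  b <- smote_balance(s, seed = 11)
  expect_equal(as.vector(table(b$swb)), c(5L, 5L))
  expect_equal(sum(!b$synthetic), nrow(s))

  # synthetics stay inside their own class's value range
  for (cl in c(6, 7)) {
    orig <- s$value[s$swb == cl]
    syn <- b$value[b$swb == cl & b$synthetic]
    if (length(syn))
      expect_true(all(syn >= min(orig) & syn <= max(orig)))
  }

  # already balanced: no synthetics at all
  bal <- samples_from_counts(c("5" = 4, "6" = 4, "7" = 4))
  expect_equal(nrow(smote_balance(bal, seed = 1)), nrow(bal))

  # determinism in the seed; counts invariant across seeds
  expect_identical(smote_balance(s, seed = 5), smote_balance(s, seed = 5))
  b2 <- smote_balance(s, seed = 6)
  expect_false(identical(b, b2))
  expect_equal(table(b$swb), table(b2$swb))

  # singleton class cannot be interpolated
  expect_error(smote_balance(samples_from_counts(c("6" = 4, "7" = 1))),
               "fewer than 2")
})

test_that("participant fits average repeated balanced regressions", {
  # exact line with equal values inside each class: synthetics replicate
  # existing points, so slope/intercept are exact for any seed
  s <- data.frame(value = rep(c(1, 2, 3), times = c(5, 3, 4)))
  s$swb <- 2 * s$value + 1
  fit <- fit_participant_slope(s, n_repeats = 10, seed = 2)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(coef(fit), c(intercept = 1, slope = 2))

  # reported fields are the arithmetic means of the per-repeat fits
  set.seed(8)
  noisy <- data.frame(value = rnorm(30),
                      swb = rep(c(5, 6, 7), times = c(14, 9, 7)))
  noisy$value <- noisy$value + 0.5 * noisy$swb
  f <- fit_participant_slope(noisy, n_repeats = 10, seed = 4)
  expect_equal(f$slope, mean(f$slopes))
  expect_equal(f$intercept, mean(f$intercepts))
  expect_equal(f$n_repeats_used, 10)

  # repeat-count consistency: 10 repeats agree with a large-repeat run
  # within the Monte-Carlo error of the repeat distribution
  f10 <- fit_participant_slope(noisy, n_repeats = 10, seed = 5)
  f500 <- fit_participant_slope(noisy, n_repeats = 500, seed = 6)
  mc_se <- sd(f500$slopes) / sqrt(10)
  expect_lt(abs(f10$slope - f500$slope), 4 * mc_se)

  # degenerate: all asymmetry values equal -> every repeat skipped
  flat <- data.frame(value = rep(1, 12), swb = rep(c(5, 6, 7), each = 4))
  expect_warning(out <- fit_participant_slope(flat, n_repeats = 1, seed = 1),
                 "zero predictor variance")
  expect_null(out)
})

test_that("group slope test matches the closed-form t distribution", {
  g <- group_slope_test(c(0.5, 1.0, 1.5))
  expect_equal(g$t_stat, 3.4641, tolerance = 1e-4)
  expect_equal(g$p_value, 0.0742, tolerance = 1e-3)
  # closed form: 1 -+ qt(0.975, 2) * 0.5 / sqrt(3)
  expect_equal(g$ci_low, 1 - qt(0.975, 2) * 0.5 / sqrt(3),
               tolerance = 1e-12)
  expect_equal(round(g$ci_low, 4), -0.2421)
  expect_equal(round(g$ci_high, 4), 2.2421)

  sym <- group_slope_test(c(-1, 0, 1))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)

  # location equivariance of the CI
  shift <- group_slope_test(c(0.5, 1.0, 1.5) + 3)
  expect_equal(shift$ci_low, g$ci_low + 3)
  expect_equal(shift$ci_high, g$ci_high + 3)

  expect_error(group_slope_test(0.5), "at least 2")
  expect_error(group_slope_test(c(1, 1, 1)), "zero variance")
})

test_that("BY adjustment matches the formula and dominates BH", {
  r <- by_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))
  expect_equal(r$adjusted, rep(0.1141667, 5), tolerance = 1e-6)

  expect_equal(by_fdr(0.03)$adjusted, 0.03)
  expect_equal(by_fdr(rep(1, 4))$adjusted, rep(1, 4))
  expect_false(any(by_fdr(rep(1, 4))$reject))

  set.seed(33)
  for (i in 1:25) {
    m <- sample(2:20, 1)
    p <- runif(m)
    adj <- by_fdr(p)$adjusted
    expect_equal(adj, by_brute(p), tolerance = 1e-12)
    bh <- p.adjust(p, "BH")
    expect_true(all(adj >= bh - 1e-15))
    expect_true(all(bh >= p - 1e-15))
    # monotone when sorted
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }

  expect_error(by_fdr(c(0.5, 0)), "must lie in")
  expect_error(by_fdr(c(0.5, 1.2)), "must lie in")
  expect_length(by_fdr(numeric(0))$adjusted, 0)
})
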