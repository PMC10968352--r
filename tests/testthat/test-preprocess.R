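# detrending, bad-channel detection, re-referencing, epoch extraction

test_that("detrend removes exactly the least-squares line", {
  n <- 512
  t <- 0:(n - 1)
  expect_equal(detrend(rep(3.7, n)), rep(0, n))
  expect_equal(detrend(2.5 * t + 1), rep(0, n), tolerance = 1e-10)

  # sine + ramp: result equals the sine minus its own best-fit line
  x <- sin(2 * pi * 5 * t / 128)
  y <- detrend(x + 0.3 * t - 2)
  fit <- lm(x ~ t)
  expect_equal(y, unname(x - fitted(fit)), tolerance = 1e-8)
  res_slope <- coef(lm(y ~ t))[2]
  expect_lt(abs(res_slope), 1e-10)

  # idempotence
  expect_equal(detrend(y), y, tolerance = 1e-10)

  # recording method: every channel mean and trend vanish
  cfg <- tiny_config(seed = 5)
  rec <- generate_recording(generate_swb_sequence(cfg, 1), cfg, 2)
  rec$samples <- rec$samples + 5 + outer(1:14, seq_len(ncol(rec$samples)))
  d <- detrend(rec)
  expect_lt(max(abs(rowMeans(d$samples))), 1e-8)
})

test_that("clean i.i.d. channels are rarely flagged", {
  n_flagged <- 0
  for (seed in 1:100) {
    set.seed(seed)
    rec <- new_recording(matrix(rnorm(14 * 4096), 14), fs_default)
    n_flagged <- n_flagged + (length(detect_bad_channels(rec)) > 0)
  }
  expect_lte(n_flagged, 5)   # no flags in at least 95% of seeds
})

test_that("injected pathological channels are detected", {
  cfg <- tiny_config(seed = 8)
  rec <- generate_recording(generate_swb_sequence(cfg, 1), cfg, 2)

  expect_true("P8" %in%
    detect_bad_channels(inject_bad_channel(rec, "P8", "flat")))

  set.seed(3)
  sp <- inject_bad_channel(rec, "O1", "spikes")
  expect_true("O1" %in% detect_bad_channels(sp))

  set.seed(4)
  hv <- inject_bad_channel(rec, "F4", "high_variance")
  expect_true("F4" %in% detect_bad_channels(hv))

  # pre-flagged channels reduce the pool; < 4 unflagged is an error
  rec$bad_channels <- rec$channels[1:11]
  expect_error(detect_bad_channels(rec), "at least 4")
})

test_that("rereference subtracts the reference from the posterior subset", {
  cfg <- tiny_config(seed = 12)
  rec <- generate_recording(generate_swb_sequence(cfg, 1), cfg, 2)

  # a subset channel carrying the reference signal becomes zero
  rec2 <- rec
  rec2$samples["T7", ] <- rec2$samples["AF3", ]
  rr <- rereference(rec2, "AF3")
  expect_equal(max(abs(rr$samples["T7", ])), 0)
  expect_equal(rr$reference, "AF3")

  # channels outside the subset are untouched
  expect_identical(rr$samples["F4", ], rec2$samples["F4", ])

  # pairwise differences within the subset are preserved
  d_before <- rec$samples["P8", ] - rec$samples["O1", ]
  rr2 <- rereference(rec, "F3")
  expect_equal(rr2$samples["P8", ] - rr2$samples["O1", ], d_before,
               tolerance = 1e-12)

  # common-mode offset cancels
  rec3 <- rec
  rec3$samples <- rec3$samples + 42
  rr3 <- rereference(rec3, "F3")
  expect_equal(rr3$samples["T8", ], rr2$samples["T8", ], tolerance = 1e-10)

  # not idempotent: second application subtracts again
  twice <- rereference(rr2, "F3")
  expect_false(isTRUE(all.equal(twice$samples["T8", ],
                                rr2$samples["T8", ])))

  # guards
  rec$bad_channels <- "AF3"
  expect_error(rereference(rec, "AF3"), "bad channel")
  expect_error(rereference(rec, "T7"), "must not belong")
})

test_that("epochs are extracted on half-open 10-s windows before reports", {
  cfg <- tiny_config(seed = 14)
  swb <- generate_swb_sequence(cfg, 1)
  rec <- generate_recording(swb, cfg, 2)

  eps <- extract_epochs(rec, swb)
  expect_equal(length(eps), nrow(swb))
  expect_true(all(vapply(eps, function(e) ncol(e$samples), numeric(1)) ==
                    1280))
  # report at t = 30 s maps to sample indices 2560..3839 (0-based)
  expect_identical(eps[[1]]$samples[, 1],
                   rec$samples[, 2561])
  expect_identical(eps[[1]]$samples[, 1280],
                   rec$samples[, 3840])
  expect_equal(eps[[1]]$swb, swb$swb[1])

  # early report: skipped with a warning, not zero-padded
  expect_warning(
    short <- extract_epochs(rec, data.frame(time_s = 5, swb = 6)),
    "skipped")
  expect_length(short, 0)

  # windows never overlap at cadence >= duration
  starts <- vapply(eps, function(e) e$t_report - 10, numeric(1))
  expect_true(all(diff(starts) >= 10))
})
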