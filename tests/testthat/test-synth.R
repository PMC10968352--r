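# synthetic-data generator: rating sequences, recordings, corruption

test_that("SWB sequences follow the configured cadence and distribution", {
  # degenerate distribution: every report is a 7
  point <- synth_config(n_participants = 1,
                        swb_probs = c("1" = 0, "2" = 0, "3" = 0, "4" = 0,
                                      "5" = 0, "6" = 0, "7" = 1, "8" = 0,
                                      "9" = 0, "10" = 0))
  s <- generate_swb_sequence(point, 1)
  expect_true(all(s$swb == 7))

  # default 9-min run at 30 s cadence: exactly 18 reports at k * 30 s
  cfg <- synth_config(n_participants = 1)
  s <- generate_swb_sequence(cfg, 5)
  expect_equal(nrow(s), 18)
  expect_equal(s$time_s, (1:18) * 30)
  expect_true(all(s$swb %in% 1:10))

  # empirical mass on {6,7,8} within 3 SE of the configured mass
  big <- synth_config(n_participants = 1, run_duration = 300000,
                      report_interval = 30)
  draws <- generate_swb_sequence(big, 11)$swb
  mass <- sum(cfg$swb_probs[c("6", "7", "8")])
  se <- sqrt(mass * (1 - mass) / length(draws))
  expect_lt(abs(mean(draws %in% 6:8) - mass), 3 * se)

  # reproducibility
  expect_identical(generate_swb_sequence(cfg, 7),
                   generate_swb_sequence(cfg, 7))
})

test_that("rating histogram is consistent with the configured distribution", {
  cfg <- synth_config(n_participants = 1, run_duration = 300000)
  n_bad <- 0
  for (seed in 1:20) {
    draws <- generate_swb_sequence(cfg, seed)$swb
    obs <- tabulate(draws, 10)
    keep <- cfg$swb_probs > 0
    gof <- suppressWarnings(
      chisq.test(obs[keep], p = cfg$swb_probs[keep] / sum(cfg$swb_probs[keep])))
    if (gof$p.value < 0.01) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 2)   # 95% non-rejection at the 1% level, 20 seeds
})

test_that("generator config is validated", {
  expect_error(synth_config(swb_probs = setNames(rep(0.2, 10),
                                                 as.character(1:10))),
               "sum to 1")
  expect_error(synth_config(run_duration = 100, report_interval = 30),
               "integer multiple")
  expect_error(
    synth_config(couplings = list(list(ch1 = "XX", ch2 = "AF3",
                                       band = "alpha", gamma = 0.1))),
    "not in the montage")
  expect_error(
    synth_config(band_amplitudes = c(alpha = 10),
                 couplings = list(list(ch1 = "AF4", ch2 = "AF3",
                                       band = "beta", gamma = 0.1))),
    "no synthesized amplitude")
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- tiny_config()
  swb <- generate_swb_sequence(cfg, 3)
  r1 <- generate_recording(swb, cfg, 17)
  r2 <- generate_recording(swb, cfg, 17)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_recording(swb, cfg, 18)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("uncoupled recordings have zero expected asymmetry", {
  cfg <- tiny_config(seed = 21)
  vals <- c()
  for (run_seed in 1:13) {
    swb <- generate_swb_sequence(cfg, run_seed)
    rec <- generate_recording(swb, cfg, 100 + run_seed)
    eps <- extract_epochs(rec, swb)
    vals <- c(vals, vapply(eps, function(e)
      asym(e, "AF4", "AF3", "alpha")$value, numeric(1)))
  }
  expect_gte(length(vals), 39)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("an injected coupling realizes the target log-power ratio", {
  # gamma = 0.2 at a constant rating of 10 -> expected asymmetry 2.0
  cfg <- synth_config(
    n_participants = 1, n_runs_per_participant = 1, run_duration = 600,
    swb_probs = setNames(c(rep(0, 9), 1), as.character(1:10)),
    band_amplitudes = c(alpha = 15),
    couplings = list(list(ch1 = "AF4", ch2 = "F7", band = "alpha",
                          gamma = 0.2)),
    asym_noise_sd = 0, seed = 7)
  swb <- generate_swb_sequence(cfg, 11)
  rec <- generate_recording(swb, cfg, 12)
  eps <- extract_epochs(detrend(rec), swb)
  vals <- vapply(eps, function(e) asym(e, "AF4", "F7", "alpha")$value,
                 numeric(1))
  expect_lt(abs(mean(vals) - 2.0), 3 * sd(vals) / sqrt(length(vals)) + 0.05)
  # a pair sharing only the coupled right channel carries half the effect
  half <- vapply(eps, function(e) asym(e, "AF4", "F3", "alpha")$value,
                 numeric(1))
  expect_lt(abs(mean(half) - 1.0), 3 * sd(half) / sqrt(length(half)) + 0.05)
})

test_that("epoch-level regression recovers the injected slope", {
  cfg <- synth_config(
    n_participants = 1, n_runs_per_participant = 6,
    band_amplitudes = c(alpha = 15),
    couplings = list(list(ch1 = "AF4", ch2 = "F7", band = "alpha",
                          gamma = 0.3)),
    asym_noise_sd = 0, seed = 3)
  ds <- simulate_dataset(cfg)
  v <- s <- c()
  for (run in ds$participants[[1]]$runs) {
    eps <- extract_epochs(detrend(run$recording), run$reports)
    v <- c(v, vapply(eps, function(e) asym(e, "AF4", "F7", "alpha")$value,
                     numeric(1)))
    s <- c(s, vapply(eps, function(e) e$swb, integer(1)))
  }
  expect_gte(length(v), 100)
  slope <- coef(lm(v ~ s))[2]
  expect_lt(abs(slope - 0.3) / 0.3, 0.10)
})

test_that("inject_bad_channel produces the advertised pathologies", {
  cfg <- tiny_config(seed = 31)
  swb <- generate_swb_sequence(cfg, 1)
  rec <- generate_recording(swb, cfg, 2)

  flat <- inject_bad_channel(rec, "T7", "flat")
  expect_equal(var(flat$samples["T7", ]), 0)

  set.seed(1)
  hv <- inject_bad_channel(rec, "T7", "high_variance")
  sds <- apply(hv$samples, 1, sd)
  expect_gte(sds["T7"] / median(sds), 10)

  set.seed(2)
  sp <- inject_bad_channel(rec, "T7", "spikes")
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  kk <- apply(sp$samples, 1, kurt)
  expect_true(kk["T7"] > max(kk[names(kk) != "T7"]))

  expect_error(inject_bad_channel(rec, "Cz", "flat"), "not in recording")
  expect_error(inject_bad_channel(rec, "T7", "weird"))
})
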