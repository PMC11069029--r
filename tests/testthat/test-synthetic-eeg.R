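# Synthetic EEG generator: background spectra, effect injection,
# artifacts, and dataset assembly.

reduced_montage <- montage_1020(default_config(reduced = TRUE)$channels)

fit_psd_slope <- function(x, fs) {
  ps <- spec.pgram(ts(x, frequency = fs), spans = 25, plot = FALSE,
                   detrend = TRUE)
  sel <- ps$freq >= 2 & ps$freq <= 40
  unname(coef(lm(log10(ps$spec[sel]) ~ log10(ps$freq[sel])))[2])
}

test_that("background noise realizes the requested spectral exponent", {
  m <- reduced_montage
  white <- simulate_background(m, 60, 250, onef_exponent = 0,
                               alpha_sd = 0, seed = 4)
  expect_lt(abs(fit_psd_slope(white$data[1, ], 250)), 0.2)
  pink <- simulate_background(m, 60, 250, onef_exponent = 1,
                              alpha_sd = 0, seed = 4)
  expect_lt(abs(fit_psd_slope(pink$data[3, ], 250) + 1), 0.2)
})

test_that("background generation is deterministic and spatially mixed", {
  m <- reduced_montage
  a <- simulate_background(m, 10, 250, seed = 7)
  b <- simulate_background(m, 10, 250, seed = 7)
  expect_identical(a$data, b$data)
  # neighboring channels more correlated than distant ones
  cc <- cor(t(a$data[1:8, ]))
  expect_gt(cc["F3", "FZ"], cc["F3", "P4"])
})

test_that("a 0 dB effect leaves the recording unchanged", {
  m <- reduced_montage
  rec <- simulate_background(m, 20, 250, seed = 1)
  rec$events <- data.frame(sample = c(1500, 3000), run = 1, trial = 1:2)
  trials <- make_trials(c("ASA", "ASA"), c(1, 1), c(0, 0))
  eff <- effect_spec(c(8, 12), c(0, 1), "F3", db = 0, selector = "all")
  expect_identical(inject_effect(rec, trials, eff)$data, rec$data)
})

test_that("+6.02 dB doubles the amplitude of a pure in-band sinusoid", {
  m <- reduced_montage
  fs <- 250
  n <- 20 * fs
  rec <- eeg_recording(matrix(0, nrow(m), n), m$label, fs, montage = m)
  tgrid <- seq_len(n) / fs
  rec$data[1, ] <- sin(2 * pi * 10 * tgrid)
  rec$events <- data.frame(sample = 8 * fs, run = 1, trial = 1)
  trials <- make_trials("ASA", 1, 0)
  eff <- effect_spec(c(8, 12), c(0, 2), "F3", db = 20 * log10(2),
                     selector = "all")
  out <- inject_effect(rec, trials, eff)
  # core of the window (outside the 0.1 s tapers)
  core <- (8 * fs + 0.3 * fs):(8 * fs + 1.7 * fs)
  ratio <- max(abs(out$data[1, core])) / max(abs(rec$data[1, core]))
  expect_equal(ratio, 2, tolerance = 0.02)
  # outside the window: untouched
  before <- 1:(7.5 * fs)
  expect_equal(out$data[1, before], rec$data[1, before], tolerance = 1e-9)
  expect_error(inject_effect(rec, trials,
                             effect_spec(c(8, 12), c(0, 1), "F3", db = 1)),
               NA)
})

test_that("band above Nyquist is rejected", {
  m <- reduced_montage
  rec <- simulate_background(m, 5, 60, seed = 1)
  rec$events <- data.frame(sample = 150, run = 1, trial = 1)
  eff <- effect_spec(c(20, 40), c(0, 1), "F3", db = 1, selector = "all")
  expect_error(inject_effect(rec, make_trials("ASA", 1, 0), eff), "Nyquist")
})

test_that("the pipeline's TFR recovers an injected dB change", {
  # steady-state round trip: -2 dB on half of 60 trials, measured at band
  # center away from window and band edges
  m <- reduced_montage
  cfg <- default_config(reduced = TRUE)
  cfg$n_runs <- 1; cfg$trials_per_condition <- 25
  cfg$effects <- list(effect_spec(c(7, 13), c(0, 3), c("F3", "FZ"),
                                  db = -2, selector = "attended_correct"))
  cfg$behavior$accuracy_model <- default_accuracy_model() * 0 + 0.5
  cfg$behavior$subject_sd <- 0
  sub <- simulate_subject(cfg, "MT", seed = 21)
  ep <- extract_epochs(sub$recording, c(-1, 4))
  tfr <- morlet_transform(ep, freqs = 10, t_step_ms = 20,
                          channels = c("F3", "FZ"))
  sel <- oscidiff:::select_trials("attended_correct", sub$trials) > 0
  ti <- tfr$time_s >= 0.5 & tfr$time_s <= 2.5
  lg <- function(rows) 10 * mean(log10(tfr$power[rows, , 1, ti]))
  diff_db <- lg(which(sel)) - lg(which(!sel))
  expect_lt(abs(diff_db + 2), 0.5)
})

test_that("blink artifacts appear at the expected rate and topography", {
  m <- reduced_montage
  rec <- simulate_background(m, 60, 250, seed = 3)
  out <- add_artifacts(rec, blink_rate = 12, seed = 5)
  k <- length(out$blink_times)
  expect_true(k >= 5 && k <= 19)  # 12 +/- 2 sd of Poisson(12)
  # blinks dominate the vertical EOG pair with opposite polarity
  vu <- out$recording$data["VEOGU", ] - rec$data["VEOGU", ]
  vl <- out$recording$data["VEOGL", ] - rec$data["VEOGL", ]
  expect_lt(cor(vu, vl), -0.9)
  expect_gt(max(abs(vu)), 100)
  # untouched when rate is zero and no noisy channels
  same <- add_artifacts(rec, blink_rate = 0, seed = 5)
  expect_identical(same$recording$data, rec$data)
})

test_that("declared noisy channels exceed the variance criterion", {
  m <- reduced_montage
  rec <- simulate_background(m, 30, 250, seed = 6)
  out <- add_artifacts(rec, noisy_channels = "C4", seed = 1)
  expect_identical(detect_noisy_channels(out$recording), "C4")
  expect_error(add_artifacts(rec, noisy_channels = "NOPE"), "unknown")
})

test_that("synthesized datasets satisfy the structural invariants", {
  cfg <- default_config(reduced = TRUE)
  cfg$n_per_group <- c(MT = 2, NMT = 2)
  cfg$n_runs <- 1
  ds <- synthesize_dataset(cfg, seed = 31)
  expect_length(ds$subjects, 4)
  for (s in ds$subjects) {
    tt <- ds$trial_table[ds$trial_table$subject == s$id, ]
    # one stimulus-onset event per trial
    expect_equal(nrow(s$recording$events), nrow(tt))
    expect_setequal(paste(s$recording$events$run, s$recording$events$trial),
                    paste(tt$run, tt$trial))
  }
  expect_equal(table(ds$trial_table$condition)[["P"]], 4 * 10)
  expect_length(ds$ground_truth$effects, 2)
  # determinism end to end
  ds2 <- synthesize_dataset(cfg, seed = 31)
  expect_identical(ds$subjects[[1]]$recording$data,
                   ds2$subjects[[1]]$recording$data)
  expect_identical(ds$trial_table, ds2$trial_table)
})

test_that("invalid configurations are reported with offending keys", {
  cfg <- default_config(reduced = TRUE)
  cfg$bogus_key <- 1
  cfg$fs <- -5
  err <- tryCatch(validate_config(cfg), error = function(e) e)
  expect_s3_class(err, "oscidiff_config_error")
  expect_match(conditionMessage(err), "bogus_key")
  expect_match(conditionMessage(err), "fs")
})

test_that("zero-amplitude effects yield a null simulation", {
  cfg <- default_config(reduced = TRUE)
  cfg$effects <- lapply(cfg$effects, function(e) { e$db <- 0; e })
  expect_equal(vapply(cfg$effects, `[[`, 0, "db"), c(0, 0))
  # generation still runs and records the zero-amplitude ground truth
  cfg$n_per_group <- c(MT = 2, NMT = 2); cfg$n_runs <- 1
  ds <- synthesize_dataset(cfg, seed = 2)
  expect_equal(vapply(ds$ground_truth$effects, `[[`, 0, "db"), c(0, 0))
})
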