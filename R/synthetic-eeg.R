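# Synthetic continuous EEG with known ground truth.
#
# The generator is this package's own construct (no biophysical forward
# model): 1/f^a background noise mixed across channels by a smooth spatial
# kernel, an amplitude-modulated posterior alpha rhythm so baseline alpha
# exists to desynchronize, stereotyped blink transients, optional noisy
# channels, and band-limited multiplicative power effects injected into
# selected trials with known amplitude in dB.

#' Recording constructor (continuous multichannel EEG)
#'
#' @param data numeric matrix channels x samples, microvolts.
#' @param channels channel labels (rownames of `data`).
#' @param fs sampling rate in Hz.
#' @param events data.frame with at least `sample` (1-based stimulus-onset
#'   sample), `run`, `trial`.
#' @param montage montage data.frame covering the channels.
#' @param reference reference descriptor string.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(data, channels, fs, events = NULL, montage = NULL,
                          reference = "linked mastoids") {
  stopifnot(nrow(data) == length(channels))
  rownames(data) <- channels
  structure(list(data = data, channels = channels, fs = fs,
                 events = events, montage = montage, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data) / x$fs, x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

scalp_idx <- function(rec) which(rec$montage$type[
  match(rec$channels, rec$montage$label)] == "eeg")

# 1/f^a noise, one column per channel, unit variance.  Synthesized
# directly in the frequency domain (complex white spectrum times the
# target amplitude shape, one inverse FFT per channel), which realizes the
# target power spectral density exactly.
onef_noise <- function(n, n_chan, fs, exponent) {
  zr <- matrix(rnorm(n * n_chan), n, n_chan)
  zi <- matrix(rnorm(n * n_chan), n, n_chan)
  spec <- complex(real = zr, imaginary = zi)
  dim(spec) <- c(n, n_chan)
  if (exponent != 0) {
    f <- (seq_len(n) - 1) * fs / n
    f[f > fs / 2] <- fs - f[f > fs / 2]
    shape <- c(0, 1 / f[-1]^(exponent / 2))
    spec <- spec * shape
  }
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), "/")
}

# unit-variance band-limited Gaussian process (spectral bump at f0 with
# width sigma_f); its envelope waxes and wanes like ongoing alpha
narrowband_noise <- function(n, fs, f0, sigma_f = 1) {
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- exp(-(f - f0)^2 / (2 * sigma_f^2))
  spec <- complex(real = rnorm(n), imaginary = rnorm(n)) * shape
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate background EEG
#'
#' Each scalp channel receives 1/f^`onef_exponent` noise (unit-variance,
#' scaled to `noise_sd`), spatially correlated by mixing with a Gaussian
#' angular kernel over the montage, plus a spatially coherent ongoing
#' alpha rhythm (band-limited Gaussian process whose envelope waxes and
#' wanes) weighted toward posterior channels.  EOG channels receive
#' independent low-amplitude noise.
#'
#' @param montage montage data.frame (scalp + EOG channels).
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (default 1000).
#' @param onef_exponent spectral exponent `a` of the 1/f^a background.
#' @param noise_sd per-channel background SD in microvolts (default 10).
#' @param alpha_hz,alpha_sd frequency and SD (microvolts) of the ongoing
#'   posterior alpha rhythm; `alpha_sd = 0` disables it.
#' @param mixing_width angular width (degrees) of the spatial kernel.
#' @param seed integer seed.
#' @return an `eeg_recording` without events.
#' @export
simulate_background <- function(montage, duration_s, fs = 1000,
                                onef_exponent = 1, noise_sd = 10,
                                alpha_hz = 10, alpha_sd = 5,
                                mixing_width = 35, seed = NULL) {
  if (duration_s <= 0 || fs <= 0) stop_param("duration and fs must be > 0")
  with_seed(seed, {
    # round the sample count up to an FFT-friendly length; the spectral
    # synthesis and later filtering all profit and the extra tail is inert
    n <- next_fast_len(round(duration_s * fs))
    sc <- montage[montage$type == "eeg", ]
    nch <- nrow(sc)
    x <- onef_noise(n, nch, fs, onef_exponent)
    # smooth spatial mixing, rows scaled to preserve unit variance
    xyz <- as.matrix(sc[, c("x", "y", "z")])
    ang <- acos(clamp_cos(tcrossprod(xyz))) * 180 / pi
    K <- exp(-ang^2 / (2 * mixing_width^2))
    K <- K / sqrt(rowSums(K^2))
    x <- x %*% t(K)
    x <- x * noise_sd
    if (alpha_sd > 0) {
      osc <- narrowband_noise(n, fs, alpha_hz) * alpha_sd
      w <- topography_weights(montage, "posterior")
      x <- x + outer(osc, w[sc$label])
    }
    eogn <- montage$label[montage$type == "eog"]
    eog <- matrix(rnorm(n * length(eogn), 0, 3), length(eogn), n)
    dat <- rbind(t(x), eog)
    eeg_recording(dat, c(sc$label, eogn), fs, montage = montage)
  })
}

# zero-phase spectral band-pass with raised-cosine transitions (trans Hz)
bandpass_mask <- function(n, fs, lo, hi, trans) {
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- rep(0, n)
  mask[f >= lo & f <= hi] <- 1
  up <- f >= lo - trans & f < lo
  mask[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / trans))
  dn <- f > hi & f <= hi + trans
  mask[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / trans))
  mask
}

fft_bandpass <- function(x, fs, lo, hi, trans = 1) {
  n <- length(x)
  Re(fft(fft(x) * bandpass_mask(n, fs, lo, hi, trans), inverse = TRUE)) / n
}

# row-wise version (channels x time)
fft_bandpass_rows <- function(x, fs, lo, hi, trans = 1) {
  n <- ncol(x)
  mask <- bandpass_mask(n, fs, lo, hi, trans)
  t(Re(mvfft(mvfft(t(x)) * mask, inverse = TRUE)) / n)
}

#' Specify a band-limited power effect
#'
#' @param band frequency band `c(lo, hi)` in Hz, within `[1, 45]`.
#' @param window time window `c(t0, t1)` in seconds relative to stimulus
#'   onset, within `[-1, 4]`.
#' @param channels character vector of target channels, or a topography
#'   preset name (see [topography_weights()]).
#' @param db amplitude change in dB: the band-limited amplitude in the
#'   window is scaled by `10^(db/20)`, i.e. band power changes by `db` dB.
#' @param selector `"attended_correct"` (correct retrieval of the attended
#'   modality; both for divided attention), `"correct_tasks"` (effect
#'   amplitude scales with the number of subsequently-correct retrieval
#'   tasks, 0-2), `"all"`, or a `function(trial_table)` returning
#'   per-trial weights.
#' @param groups which group(s) receive the effect (default `"MT"`).
#' @param name label used in ground-truth records.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(band, window, channels, db,
                        selector = "attended_correct", groups = "MT",
                        name = "effect") {
  if (band[1] >= band[2] || band[1] < 1 || band[2] > 45)
    stop_param("band must be increasing and within [1, 45] Hz")
  if (window[1] >= window[2] || window[1] < -1 || window[2] > 4)
    stop_param("window must be increasing and within [-1, 4] s")
  if (!is.finite(db)) stop_param("db must be finite")
  structure(list(band = band, window = window, channels = channels,
                 db = db, selector = selector, groups = groups, name = name),
            class = "effect_spec")
}

# Evaluate an effect's trial selector on a trial table.  Returns a
# per-trial weight: 0 = unaffected, 1 = one unit of the effect, 2 = two
# units (amplitude in dB scales with the weight).
#
# "attended_correct": 1 when the attended modality's retrieval was correct
#   (both, for divided attention) - the estimand of the Model 1
#   correctness regressors.
# "correct_tasks": the number of subsequently-correct retrieval tasks
#   (0-2), mirroring the additive Model 2 correctness regressors so that
#   an injected amplitude of d dB appears as ~d dB on each per-task
#   regressor.  A binary any-correct version is nearly collinear with the
#   condition dummies at realistic accuracy and is not estimable.
# "all": every trial.
select_trials <- function(selector, trials) {
  if (is.function(selector)) {
    sel <- as.numeric(selector(trials))
    sel[is.na(sel)] <- 0
    return(sel)
  }
  camt <- !is.na(trials$correct_amt) & trials$correct_amt == 1
  cvmt <- !is.na(trials$correct_vmt) & trials$correct_vmt == 1
  switch(selector,
    attended_correct = as.numeric(
      ifelse(trials$condition == "ASA", camt,
      ifelse(trials$condition == "VSA", cvmt,
      ifelse(trials$condition == "DA", camt & cvmt, FALSE)))),
    correct_tasks = as.numeric(camt) + as.numeric(cvmt),
    all = rep(1, nrow(trials)),
    stop_param("unknown trial selector: ", selector))
}

resolve_effect_channels <- function(effect, montage) {
  ch <- effect$channels
  if (length(ch) == 1L && ch %in% c("frontocentral", "left_parietal",
                                    "right_parietal", "left_frontal",
                                    "right_frontal", "posterior")) {
    w <- topography_weights(montage, ch)
    ch <- names(w)[w >= 0.5]
  }
  ch
}

#' Inject a band-limited power effect into selected trials
#'
#' For each selected trial and target channel, the band component of the
#' signal (zero-phase spectral band-pass) within the effect window is
#' scaled by `10^(db/20)`, with cosine ramps at the window edges;
#' everything else is untouched.
#'
#' @param recording an `eeg_recording` with events.
#' @param trial_table trial metadata for this recording's events.
#' @param effect an [effect_spec()].
#' @param ramp_s taper length at each window edge (default 0.1 s).
#' @param trans_hz transition width of the injection band-pass (default
#'   2 Hz, matching the spectral bandwidth of a 5-cycle wavelet around
#'   10 Hz so that an injected change is measurable at its nominal size).
#' @return the modified recording.
#' @export
inject_effect <- function(recording, trial_table, effect, ramp_s = 0.1,
                          trans_hz = 2) {
  fs <- recording$fs
  if (effect$band[2] >= fs / 2)
    stop_param("effect band exceeds Nyquist frequency")
  if (effect$db == 0) return(recording)
  if (!is.null(effect$groups) &&
      !any(trial_table$group[1] %in% effect$groups))
    return(recording)
  wts <- select_trials(effect$selector, trial_table)
  if (!any(wts > 0)) return(recording)
  chans <- resolve_effect_channels(effect, recording$montage)
  ci <- match(chans, recording$channels)
  if (anyNA(ci)) stop_param("effect channel not present in recording")
  ev <- recording$events
  key_ev <- paste(ev$run, ev$trial)
  key_tr <- paste(trial_table$run, trial_table$trial)
  sel <- which(wts > 0)
  samples <- ev$sample[match(key_tr[sel], key_ev)]
  gains <- 10^(effect$db * wts[sel] / 20)
  pad <- round(fs)  # 1 s margin for the spectral filter
  n <- ncol(recording$data)
  w0 <- round(effect$window[1] * fs); w1 <- round(effect$window[2] * fs)
  nr <- round(ramp_s * fs)
  wlen <- w1 - w0 + 1
  taper <- rep(1, wlen)
  if (nr > 0 && 2 * nr < wlen) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    taper[seq_len(nr)] <- ramp
    taper[wlen + 1 - seq_len(nr)] <- rev(ramp)
  }
  for (k in seq_along(samples)) {
    s <- samples[k]
    if (is.na(s)) next
    a <- max(1, s + w0 - pad); b <- min(n, s + w1 + pad)
    idx <- (s + w0):(s + w1)
    if (idx[1] < 1 || idx[wlen] > n) next
    rel <- idx - a + 1
    seg <- recording$data[ci, a:b, drop = FALSE]
    bp <- fft_bandpass_rows(seg, fs, effect$band[1], effect$band[2],
                            trans = trans_hz)
    recording$data[ci, idx] <- recording$data[ci, idx] +
      (gains[k] - 1) * bp[, rel, drop = FALSE] *
      rep(taper, each = length(ci))
  }
  recording
}

#' Add blink artifacts and noisy channels
#'
#' Blinks are stereotyped ~400 ms biphasic transients, maximal (and of
#' opposite polarity) on the vertical EOG pair, propagated to scalp
#' channels with a fixed frontal spatial decay.  Noisy channels receive
#' additional white noise raising their variance well above the median.
#'
#' @param recording an `eeg_recording`.
#' @param blink_rate blinks per minute (Poisson; default 0).
#' @param noisy_channels labels of channels to degrade.
#' @param blink_amp peak blink amplitude on the upper VEOG, microvolts.
#' @param seed integer seed.
#' @return list with the modified `recording`, `blink_times` (seconds), and
#'   `noisy_channels`.
#' @export
add_artifacts <- function(recording, blink_rate = 0,
                          noisy_channels = character(0), blink_amp = 200,
                          seed = NULL) {
  if (blink_rate < 0) stop_param("blink_rate must be >= 0")
  unknown <- setdiff(noisy_channels, recording$channels)
  if (length(unknown))
    stop_param("unknown channel label(s): ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    fs <- recording$fs
    n <- ncol(recording$data)
    dur_min <- n / fs / 60
    blink_times <- numeric(0)
    if (blink_rate > 0) {
      k <- rpois(1, blink_rate * dur_min)
      if (k > 0) {
        blink_times <- sort(runif(k, 0.5, n / fs - 0.5))
        blen <- round(0.4 * fs)
        tt <- seq_len(blen) / fs
        shape <- sin(pi * tt / 0.4)^2 * sin(2 * pi * tt / 0.4)
        # frontal decay on scalp channels
        sc <- scalp_idx(recording)
        pos <- recording$montage[match(recording$channels,
                                       recording$montage$label), ]
        seed_vec <- sph_unit(72, 0)  # just above the nasion
        wts <- numeric(length(recording$channels))
        for (i in sc) {
          v <- c(pos$x[i], pos$y[i], pos$z[i])
          ang <- acos(max(-1, min(1, sum(v * seed_vec)))) * 180 / pi
          wts[i] <- 0.5 * exp(-ang^2 / (2 * 30^2))
        }
        wts[match("VEOGU", recording$channels)] <- 1
        wts[match("VEOGL", recording$channels)] <- -0.7
        for (bt in blink_times) {
          i0 <- round(bt * fs)
          idx <- i0:(i0 + blen - 1)
          if (idx[1] < 1 || idx[blen] > n) next
          recording$data[, idx] <- recording$data[, idx] +
            blink_amp * outer(wts, shape)
        }
      }
    }
    if (length(noisy_channels)) {
      med_sd <- median(apply(recording$data[scalp_idx(recording), ,
                                            drop = FALSE], 1, sd))
      ci <- match(noisy_channels, recording$channels)
      for (c in ci)
        recording$data[c, ] <- recording$data[c, ] +
          rnorm(n, 0, 5 * med_sd)
    }
    list(recording = recording, blink_times = blink_times,
         noisy_channels = noisy_channels)
  })
}

#' Default dataset configuration
#'
#' Full-scale defaults mirror the study: two groups, 2 runs x 40 trials
#' (10 per condition), 40 scalp + 4 EOG channels at 1000 Hz, and the two
#' ground-truth effects carried by the musically trained group: a -2 dB
#' alpha (8-12 Hz) modulation around stimulus onset on correct
#' attended-modality trials, and a +2 dB theta/alpha (4-12 Hz) increase at
#' 2.4-2.9 s on trials with any correct response.
#'
#' @param reduced logical; use the reduced desk-scale configuration
#'   (8 channels, 250 Hz, 6 subjects per group, no artifacts).
#' @return a `dataset_config` list; edit fields before passing to
#'   [synthesize_dataset()].
#' @export
default_config <- function(reduced = FALSE) {
  cfg <- list(
    n_per_group = c(MT = 18, NMT = 18),
    n_runs = 2, trials_per_condition = 10,
    fs = 1000, channels = NULL,
    epoch_window = c(-1, 4), gap_s = 1,
    noise = list(onef_exponent = 1, noise_sd = 10, alpha_hz = 10,
                 alpha_sd = 5),
    artifacts = list(blink_rate = 6, n_noisy = 0),
    behavior = list(accuracy_model = default_accuracy_model(),
                    subject_sd = 1.5),
    effects = list(
      effect_spec(c(8, 12), c(-0.5, 0.4),
                  c("FZ", "FCZ", "FC3", "FC4", "F3", "F4", "P3", "P5",
                    "CP3"),
                  db = -2, selector = "attended_correct", groups = "MT",
                  name = "alpha_onset"),
      effect_spec(c(4, 12), c(2.4, 2.9),
                  c("F3", "F5", "F7", "FC3", "P4", "P6", "CP4"),
                  db = 2, selector = "correct_tasks", groups = "MT",
                  name = "theta_alpha_encoding")))
  if (reduced) {
    cfg$n_per_group <- c(MT = 6, NMT = 6)
    cfg$fs <- 250
    cfg$channels <- c("F3", "FZ", "F4", "C3", "C4", "P3", "PZ", "P4")
    cfg$gap_s <- 0.5
    cfg$artifacts <- list(blink_rate = 0, n_noisy = 0)
    cfg$effects <- list(
      effect_spec(c(8, 12), c(-0.5, 0.4), c("F3", "FZ", "F4", "P3"),
                  db = -2, selector = "attended_correct", groups = "MT",
                  name = "alpha_onset"),
      effect_spec(c(4, 12), c(2.4, 2.9), c("F3", "FZ", "P3", "P4"),
                  db = 2, selector = "correct_tasks", groups = "MT",
                  name = "theta_alpha_encoding"))
  }
  structure(cfg, class = "dataset_config")
}

#' Validate a dataset configuration
#'
#' Checks structure and values; on failure raises a structured
#' `oscidiff_config_error` listing every offending key.
#' @param cfg a `dataset_config` list.
#' @return the config, invisibly, when valid.
#' @export
validate_config <- function(cfg) {
  required <- c("n_per_group", "n_runs", "trials_per_condition", "fs",
                "epoch_window", "gap_s", "noise", "artifacts", "behavior",
                "effects")
  missing <- setdiff(required, names(cfg))
  extra <- setdiff(names(cfg), c(required, "channels"))
  bad <- character(0)
  if (length(missing)) bad <- c(bad, paste("missing:", missing))
  if (length(extra)) bad <- c(bad, paste("unknown:", extra))
  if (!length(missing)) {
    if (!all(c("MT", "NMT") %in% names(cfg$n_per_group)))
      bad <- c(bad, "n_per_group: needs named MT and NMT entries")
    if (cfg$fs <= 0) bad <- c(bad, "fs: must be positive")
    for (e in cfg$effects)
      if (!inherits(e, "effect_spec")) bad <- c(bad, "effects: not effect_spec")
  }
  if (length(bad))
    stop(structure(class = c("oscidiff_config_error", "error", "condition"),
                   list(message = paste0("invalid config:\n  ",
                                         paste(bad, collapse = "\n  ")),
                        call = NULL)))
  invisible(cfg)
}

#' Simulate one subject's recording and trials
#'
#' @param cfg a `dataset_config`.
#' @param group `"MT"` or `"NMT"`.
#' @param subject subject id string.
#' @param seed integer seed.
#' @return list with `recording` (events attached), `trials`
#'   (`trial_table`), `blink_times`, `noisy_channels`.
#' @export
simulate_subject <- function(cfg, group, subject = "S01", seed = NULL) {
  with_seed(seed, {
    montage <- montage_1020(cfg$channels)
    sched <- generate_schedule(cfg$n_runs, cfg$trials_per_condition)
    trials <- simulate_behavior(sched, group, cfg$behavior$accuracy_model,
                                subject_sd = cfg$behavior$subject_sd,
                                subject = subject)
    ew <- cfg$epoch_window
    spacing <- (ew[2] - ew[1]) + cfg$gap_s
    n_tr <- nrow(sched)
    lead <- -ew[1] + 0.5
    duration <- lead + (n_tr - 1) * spacing + ew[2] + 0.5
    rec <- simulate_background(montage, duration, cfg$fs,
                               cfg$noise$onef_exponent, cfg$noise$noise_sd,
                               cfg$noise$alpha_hz, cfg$noise$alpha_sd)
    rec$events <- data.frame(
      sample = round((lead + (seq_len(n_tr) - 1) * spacing) * cfg$fs) + 1L,
      run = sched$run, trial = sched$trial,
      condition = sched$condition, stringsAsFactors = FALSE)
    for (e in cfg$effects) rec <- inject_effect(rec, trials, e)
    noisy <- character(0)
    if (cfg$artifacts$n_noisy > 0)
      noisy <- sample(montage$label[montage$type == "eeg"],
                      cfg$artifacts$n_noisy)
    art <- add_artifacts(rec, cfg$artifacts$blink_rate, noisy)
    list(recording = art$recording, trials = trials,
         blink_times = art$blink_times, noisy_channels = art$noisy_channels)
  })
}

#' Synthesize a full dataset with ground truth
#'
#' Generates per-subject recordings (held in memory, or written as
#' BrainVision triplets when `out_dir` is given to bound memory), the
#' combined trial table, and a ground-truth record sufficient to
#' reconstruct the injected band-power differences.
#'
#' @param cfg a `dataset_config` (see [default_config()]).
#' @param seed integer seed; drives everything.
#' @param out_dir optional directory: recordings are written there and
#'   dropped from memory.
#' @return list with `subjects` (id, group, and recording or file paths),
#'   `trial_table`, `ground_truth`, `config`.
#' @export
synthesize_dataset <- function(cfg = default_config(), seed = NULL,
                               out_dir = NULL) {
  validate_config(cfg)
  with_seed(seed, {
    groups <- rep(c("MT", "NMT"), cfg$n_per_group[c("MT", "NMT")])
    ids <- sprintf("S%02d", seq_along(groups))
    seeds <- sample.int(2^31 - 2, length(groups))
    subjects <- vector("list", length(groups))
    tabs <- vector("list", length(groups))
    gt_art <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      sub <- simulate_subject(cfg, groups[i], ids[i], seeds[i])
      tabs[[i]] <- sub$trials
      gt_art[[i]] <- list(subject = ids[i], blink_times = sub$blink_times,
                          noisy_channels = sub$noisy_channels)
      entry <- list(id = ids[i], group = groups[i])
      if (is.null(out_dir)) {
        entry$recording <- sub$recording
      } else {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        entry$files <- write_brainvision(
          sub$recording, file.path(out_dir, ids[i]))
      }
      subjects[[i]] <- entry
    }
    trial_table <- do.call(rbind, tabs)
    class(trial_table) <- c("trial_table", "data.frame")
    ground_truth <- list(effects = cfg$effects, noise = cfg$noise,
                         artifacts = gt_art, seed = seed)
    list(subjects = subjects, trial_table = trial_table,
         ground_truth = ground_truth, config = cfg)
  })
}
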