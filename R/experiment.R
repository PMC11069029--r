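# Task structure, stimulus specifications, and simulated behavior for the
# bimodal (auditory/visual) attention and working-memory paradigm.
#
# Each trial presents a 4 s melody and a 4 s figure simultaneously under one
# of four attention conditions: auditory selective attention (ASA), visual
# selective attention (VSA), divided attention (DA), or passive viewing (P).
# Non-passive trials are followed by same/different retrieval probes for
# both modalities (auditory memory task AMT, visual memory task VMT) in
# randomized order.

CONDITIONS <- c("ASA", "VSA", "DA", "P")

#' Generate the block-randomized task schedule
#'
#' Trials of the same attention condition are presented as a contiguous
#' block within each run; block order is randomized per subject.  Every
#' trial receives unique melody and figure ids, so no stimulus repeats
#' anywhere in the experiment.
#'
#' @param n_runs number of runs (default 2).
#' @param trials_per_condition trials per condition per run (default 10).
#' @param seed integer seed; the schedule is a pure function of it.
#' @return a data.frame (class `task_schedule`) with one row per trial:
#'   `run`, `trial` (within run), `block`, `condition`, `mt_order`
#'   (`"AMT-first"`, `"VMT-first"`, or `"none"` for passive trials),
#'   `melody_id`, `figure_id`.
#' @examples
#' sched <- generate_schedule(2, 10, seed = 1)
#' table(sched$condition)  # 20 trials per condition
#' @export
generate_schedule <- function(n_runs = 2, trials_per_condition = 10,
                              seed = NULL) {
  n_runs <- assert_count(n_runs, "n_runs")
  k <- assert_count(trials_per_condition, "trials_per_condition")
  with_seed(seed, {
    per_run <- lapply(seq_len(n_runs), function(r) {
      blocks <- sample(CONDITIONS)
      cond <- rep(blocks, each = k)
      data.frame(run = r, trial = seq_len(4L * k),
                 block = rep(seq_len(4L), each = k),
                 condition = cond, stringsAsFactors = FALSE)
    })
    sched <- do.call(rbind, per_run)
    n <- nrow(sched)
    sched$mt_order <- ifelse(sched$condition == "P", "none",
                             sample(c("AMT-first", "VMT-first"), n,
                                    replace = TRUE))
    sched$melody_id <- sample.int(n)
    sched$figure_id <- sample.int(n)
    class(sched) <- c("task_schedule", "data.frame")
    sched
  })
}

# note name -> semitone offset within octave (C = 0)
PITCH_CLASS <- c(C = 0, D = 2, E = 4, F = 5, G = 7, A = 9, B = 11)

#' Equal-temperament frequency of a note
#'
#' Scientific pitch notation with A4 = 440 Hz:
#' `f = 440 * 2^(k/12)` where `k` is the semitone distance from A4.
#'
#' @param note pitch string such as `"A4"`, `"F#3"`, `"Eb5"` (vectorized).
#' @return frequency in Hz.
#' @examples
#' pitch_frequency("A4")          # 440
#' pitch_frequency("F3")          # 174.61, the bottom of the melody range
#' pitch_frequency("F4") / pitch_frequency("F3")  # exactly 2
#' @export
pitch_frequency <- function(note) {
  m <- regmatches(note, regexec("^([A-Ga-g])([#b]?)(-?[0-9]+)$", note))
  vapply(seq_along(note), function(i) {
    p <- m[[i]]
    if (length(p) != 4L)
      stop_param("unparseable note: ", note[i])
    pc <- PITCH_CLASS[[toupper(p[2])]]
    pc <- pc + switch(p[3], "#" = 1, "b" = -1, 0)
    octave <- as.integer(p[4])
    k <- (pc - 9) + 12 * (octave - 4)
    440 * 2^(k / 12)
  }, numeric(1))
}

NOTE_VALUES <- c(half = 2, quarter = 1, eighth = 0.5)  # in beats

#' Duration of a note value at a given tempo
#'
#' @param bpm tempo in quarter-note beats per minute.
#' @param value `"half"`, `"quarter"`, or `"eighth"`.
#' @return duration in milliseconds (exact, not rounded); a quarter note at
#'   180 BPM is 333.33 ms.
#' @export
note_duration <- function(bpm, value = c("quarter", "half", "eighth")) {
  if (!is.numeric(bpm) || length(bpm) != 1L || !is.finite(bpm) || bpm <= 0)
    stop_param("bpm must be a positive number")
  value <- match.arg(value)
  60000 / bpm * NOTE_VALUES[[value]]
}

#' Generate one melody specification
#'
#' A 4000 ms melody at 180 BPM (12 beats) in a random major key, with note
#' values drawn uniformly from half/quarter/eighth under backtracking so the
#' rhythm tiles the duration exactly, pitches random-walked on the scale
#' within the 175-784 Hz range, and exactly one chord event (a major triad
#' on the melody note) at a uniformly chosen position.
#'
#' @param seed integer seed.
#' @param bpm tempo (default 180).
#' @param total_ms total duration (default 4000).
#' @return list of class `melody_spec`: `notes` data.frame (`pitch`,
#'   `freq_hz`, `onset_ms`, `duration_ms`, `is_chord`), `tempo_bpm`,
#'   `total_ms`, `key`.
#' @export
generate_melody <- function(seed = NULL, bpm = 180, total_ms = 4000) {
  if (bpm <= 0) stop_param("bpm must be positive")
  with_seed(seed, {
    beat_ms <- 60000 / bpm
    total_beats <- total_ms / beat_ms
    if (abs(total_beats - round(total_beats * 2) / 2) > 1e-9)
      stop_param("total_ms must tile in eighth notes at this tempo")
    durs <- sample_rhythm(total_beats)
    n <- length(durs)
    # random major key; scale degrees within the playable range
    key_pc <- sample(0:11, 1)
    key <- c("C", "C#", "D", "Eb", "E", "F", "F#", "G", "Ab", "A", "Bb",
             "B")[key_pc + 1]
    major <- c(0, 2, 4, 5, 7, 9, 11)
    cand <- expand.grid(deg = major, oct = 2:7)
    midi <- 12 * (cand$oct + 1) + key_pc + cand$deg
    freq <- 440 * 2^((midi - 69) / 12)
    ok <- freq >= pitch_frequency("F3") - 1e-6 &
      freq <= pitch_frequency("G5") + 1e-6  # 175-784 Hz range
    pool <- sort(unique(midi[ok]))
    # random walk over the scale pool with small steps
    idx <- numeric(n)
    idx[1] <- sample(seq_along(pool), 1)
    for (i in seq_len(n - 1)) {
      step <- sample(-3:3, 1)
      idx[i + 1] <- min(max(idx[i] + step, 1), length(pool))
    }
    midi_seq <- pool[idx]
    onset_beats <- cumsum(c(0, durs[-n]))
    chord_at <- sample.int(n, 1)
    notes <- data.frame(
      pitch = midi_to_name(midi_seq),
      freq_hz = 440 * 2^((midi_seq - 69) / 12),
      onset_ms = round(onset_beats * beat_ms, 6),
      duration_ms = round(durs * beat_ms, 6),
      is_chord = seq_len(n) == chord_at,
      stringsAsFactors = FALSE)
    structure(list(notes = notes, tempo_bpm = bpm, total_ms = total_ms,
                   key = key),
              class = "melody_spec")
  })
}

# uniform draws from {2, 1, 0.5} beats, backtracking when the remainder
# cannot be tiled (remainder is always a multiple of 0.5, so only overshoot
# needs retrying)
sample_rhythm <- function(total_beats) {
  repeat {
    durs <- numeric(0)
    left <- total_beats
    while (left > 1e-9) {
      feas <- NOTE_VALUES[NOTE_VALUES <= left + 1e-9]
      pick <- feas[[sample.int(length(feas), 1)]]
      durs <- c(durs, pick)
      left <- left - pick
    }
    if (abs(left) < 1e-9) return(durs)
  }
}

midi_to_name <- function(midi) {
  names12 <- c("C", "C#", "D", "Eb", "E", "F", "F#", "G", "Ab", "A", "Bb", "B")
  paste0(names12[midi %% 12 + 1], midi %/% 12 - 1)
}

#' Generate one figure specification
#'
#' An abstract line drawing of nine black lines and one red line, appearing
#' one line every 300 ms so the figure is complete at 3000 ms and then held
#' for 1000 ms.  Lines are unit segments on a grid; every new line abuts an
#' endpoint of the current drawing, with horizontal/vertical orientation
#' chosen at random and duplicate segments rejected.
#'
#' @param seed integer seed.
#' @param n_lines number of lines (default 10).
#' @param onset_step_ms spacing of line onsets (default 300).
#' @param hold_ms hold after completion (default 1000).
#' @return list of class `figure_spec`: `lines` data.frame (`x0`, `y0`,
#'   `x1`, `y1`, `onset_ms`, `color`), `completion_ms`, `hold_ms`.
#' @export
generate_figure <- function(seed = NULL, n_lines = 10, onset_step_ms = 300,
                            hold_ms = 1000) {
  n_lines <- assert_count(n_lines, "n_lines")
  with_seed(seed, {
    segs <- matrix(NA_real_, n_lines, 4)
    segs[1, ] <- c(0, 0, 1, 0)
    key <- function(s) paste(pmin(s[1], s[3]), pmin(s[2], s[4]),
                             pmax(s[1], s[3]), pmax(s[2], s[4]))
    seen <- key(segs[1, ])
    for (i in seq_len(n_lines - 1) + 1) {
      repeat {
        prev <- segs[sample.int(i - 1, 1), ]
        pt <- if (runif(1) < 0.5) prev[1:2] else prev[3:4]
        dir <- sample(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), 1)[[1]]
        cand <- c(pt, pt + dir)
        if (!key(cand) %in% seen) break
      }
      segs[i, ] <- cand
      seen <- c(seen, key(cand))
    }
    red <- sample.int(n_lines, 1)
    lines <- data.frame(
      x0 = segs[, 1], y0 = segs[, 2], x1 = segs[, 3], y1 = segs[, 4],
      onset_ms = (seq_len(n_lines) - 1) * onset_step_ms,
      color = ifelse(seq_len(n_lines) == red, "red", "black"),
      stringsAsFactors = FALSE)
    structure(list(lines = lines,
                   completion_ms = n_lines * onset_step_ms,
                   hold_ms = hold_ms),
              class = "figure_spec")
  })
}

#' Default per-cell accuracy model
#'
#' Probabilities of a correct retrieval response for each group x attention
#' focus x task cell, parameterized so that the expected correct counts per
#' 20 trials reproduce the study's marginal ordering (musically trained >
#' untrained, focus > non-focus, visual > auditory task).
#'
#' @param grand grand mean correct count per 20 trials (default 14.66).
#' @param group_dev,focus_dev,task_dev half-differences of the marginal
#'   means in count units (defaults 1.19, 1.2, 1.6).
#' @return array `[group (MT/NMT), focus (focus/nonfocus), task (AMT/VMT)]`
#'   of probabilities.
#' @export
default_accuracy_model <- function(grand = 14.66, group_dev = 1.19,
                                   focus_dev = 1.2, task_dev = 1.6) {
  a <- array(NA_real_, c(2, 2, 2),
             dimnames = list(group = c("MT", "NMT"),
                             focus = c("focus", "nonfocus"),
                             task = c("AMT", "VMT")))
  for (g in 1:2) for (f in 1:2) for (t in 1:2) {
    mu <- grand + c(1, -1)[g] * group_dev + c(1, -1)[f] * focus_dev +
      c(-1, 1)[t] * task_dev
    a[g, f, t] <- mu / 20
  }
  pmin(pmax(a, 0.02), 0.98)
}

# focus mapping: the attended modality's task is "focus"; DA attends both
task_focus <- function(condition, task) {
  ifelse(condition == "DA", "focus",
         ifelse((condition == "ASA" & task == "AMT") |
                  (condition == "VSA" & task == "VMT"),
                "focus", "nonfocus"))
}

#' Simulate retrieval behavior for one subject
#'
#' Correctness is drawn independently per trial and task from the cell
#' probability for the subject's group and the trial's focus/task cell,
#' optionally perturbed by a subject-level ability offset.  Passive trials
#' receive `NA` correctness and no reaction times.  Reaction times of both
#' tasks are log-normal with the given mean/SD.
#'
#' @param schedule a `task_schedule`.
#' @param group `"MT"` or `"NMT"`.
#' @param accuracy_model probability array from [default_accuracy_model()],
#'   or a single probability applied to every cell.
#' @param rt_model list with `mean_ms` and `sd_ms` (defaults 834 and 208).
#' @param subject_sd SD of the subject-level offset added to all cell
#'   probabilities (count units per 20 trials; default 0 = none).
#' @param seed integer seed.
#' @return data.frame (class `trial_table`) with columns `subject`, `group`,
#'   `run`, `trial`, `condition`, `block`, `correct_amt`, `correct_vmt`,
#'   `rt_amt_ms`, `rt_vmt_ms`.
#' @export
simulate_behavior <- function(schedule, group = "MT",
                              accuracy_model = default_accuracy_model(),
                              rt_model = list(mean_ms = 834, sd_ms = 208),
                              subject_sd = 0, seed = NULL,
                              subject = "S01") {
  if (length(accuracy_model) == 1L)
    accuracy_model <- default_accuracy_model() * 0 + accuracy_model
  if (any(accuracy_model < 0 | accuracy_model > 1))
    stop_param("accuracy probabilities must lie in [0, 1]")
  if (!group %in% c("MT", "NMT")) stop_param("group must be MT or NMT")
  with_seed(seed, {
    n <- nrow(schedule)
    offset <- rnorm(1, 0, subject_sd) / 20
    draw <- function(task) {
      p <- accuracy_model[cbind(group, task_focus(schedule$condition, task),
                                task)]
      p <- pmin(pmax(p + offset, 0.01), 0.99)
      out <- rbinom(n, 1, p)
      out[schedule$condition == "P"] <- NA_integer_
      out
    }
    camt <- draw("AMT"); cvmt <- draw("VMT")
    # log-normal RT with the requested mean/SD
    s2 <- log(1 + (rt_model$sd_ms / rt_model$mean_ms)^2)
    rt <- function() rlnorm(n, log(rt_model$mean_ms) - s2 / 2, sqrt(s2))
    rt_a <- rt(); rt_v <- rt()
    rt_a[is.na(camt)] <- NA_real_; rt_v[is.na(cvmt)] <- NA_real_
    out <- data.frame(subject = subject, group = group,
                      run = schedule$run, trial = schedule$trial,
                      condition = schedule$condition, block = schedule$block,
                      correct_amt = camt, correct_vmt = cvmt,
                      rt_amt_ms = rt_a, rt_vmt_ms = rt_v,
                      stringsAsFactors = FALSE)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Simulate behavior for a two-group cohort
#'
#' @param n_mt,n_nmt subjects per group (defaults 17 and 19).
#' @param n_runs,trials_per_condition schedule parameters.
#' @param subject_sd between-subject ability SD in count units (default 1.5).
#' @param seed integer seed.
#' @inheritParams simulate_behavior
#' @return combined `trial_table` for all subjects.
#' @export
simulate_cohort_behavior <- function(n_mt = 17, n_nmt = 19, n_runs = 2,
                                     trials_per_condition = 10,
                                     accuracy_model = default_accuracy_model(),
                                     subject_sd = 1.5, seed = NULL) {
  with_seed(seed, {
    groups <- c(rep("MT", n_mt), rep("NMT", n_nmt))
    tabs <- lapply(seq_along(groups), function(i) {
      sched <- generate_schedule(n_runs, trials_per_condition)
      simulate_behavior(sched, groups[i], accuracy_model,
                        subject_sd = subject_sd,
                        subject = sprintf("S%02d", i))
    })
    out <- do.call(rbind, tabs)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Write / read a trial table as CSV
#'
#' `NA` is encoded as an empty field.
#' @param trial_table a `trial_table` data.frame.
#' @param path file path.
#' @export
write_trial_table <- function(trial_table, path) {
  write.csv(trial_table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "character"))
  for (col in c("correct_amt", "correct_vmt"))
    out[[col]] <- as.integer(out[[col]])
  class(out) <- c("trial_table", "data.frame")
  out
}
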