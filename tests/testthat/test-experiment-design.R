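# Task schedule, stimulus generators, and simulated behavior.

test_that("schedules satisfy the block and count invariants", {
  for (par in list(c(2, 10), c(1, 1), c(3, 4))) {
    s <- generate_schedule(par[1], par[2], seed = 11)
    expect_equal(nrow(s), 4 * par[1] * par[2])
    counts <- table(s$run, s$condition)
    expect_true(all(counts == par[2]))
    # trials of a condition are contiguous within each run
    for (r in unique(s$run)) {
      runc <- s$condition[s$run == r]
      expect_equal(sum(runc[-1] != runc[-length(runc)]), 3)
    }
    # passive trials have no memory-task order, others do
    expect_true(all(s$mt_order[s$condition == "P"] == "none"))
    expect_true(all(s$mt_order[s$condition != "P"] %in%
                      c("AMT-first", "VMT-first")))
    # stimulus uniqueness across the whole experiment
    expect_equal(length(unique(s$melody_id)), nrow(s))
    expect_equal(length(unique(s$figure_id)), nrow(s))
  }
})

test_that("the full experiment uses 80 trials and 160 unique stimuli", {
  s <- generate_schedule(2, 10, seed = 5)
  expect_equal(nrow(s), 80)
  expect_equal(sum(s$run == 1), 40)
  expect_equal(length(unique(s$melody_id)) + length(unique(s$figure_id)),
               160)
})

test_that("generators are pure functions of their seed", {
  expect_identical(generate_schedule(2, 10, seed = 3),
                   generate_schedule(2, 10, seed = 3))
  expect_identical(generate_melody(seed = 9), generate_melody(seed = 9))
  expect_identical(generate_figure(seed = 9), generate_figure(seed = 9))
  expect_false(identical(generate_melody(seed = 9),
                         generate_melody(seed = 10)))
})

test_that("schedule rejects non-positive counts", {
  expect_error(generate_schedule(0, 10), "n_runs")
  expect_error(generate_schedule(2, -1), "trials_per_condition")
})

test_that("equal-temperament pitch frequencies are correct", {
  expect_equal(pitch_frequency("A4"), 440)
  expect_equal(round(pitch_frequency("F3")), 175)
  expect_equal(pitch_frequency("F4") / pitch_frequency("F3"), 2)
  expect_equal(pitch_frequency("C4"), 261.6256, tolerance = 1e-6)
  expect_equal(pitch_frequency("F#3"), pitch_frequency("Gb3"))
  expect_error(pitch_frequency("H2"), "unparseable")
})

test_that("note durations follow the tempo", {
  expect_equal(note_duration(60, "quarter"), 1000)
  expect_equal(note_duration(180, "quarter"), 1000 / 3)
  expect_equal(note_duration(180, "eighth"),
               note_duration(180, "quarter") / 2)
  expect_equal(note_duration(180, "half"),
               2 * note_duration(180, "quarter"))
  expect_error(note_duration(0, "quarter"), "positive")
})

test_that("melodies tile 4000 ms with one chord in the playable range", {
  for (seed in 1:8) {
    m <- generate_melody(seed = seed)
    expect_equal(sum(m$notes$duration_ms), 4000, tolerance = 1e-6)
    expect_equal(max(m$notes$onset_ms + m$notes$duration_ms), 4000,
                 tolerance = 1e-6)
    expect_equal(sum(m$notes$is_chord), 1)
    expect_true(all(m$notes$freq_hz >= 174.6 & m$notes$freq_hz <= 784.1))
    # note values restricted to half/quarter/eighth at 180 BPM
    beats <- m$notes$duration_ms / (60000 / 180)
    expect_true(all(vapply(beats, function(b)
      min(abs(b - c(2, 1, 0.5))) < 1e-6, logical(1))))
  }
})

test_that("figures draw ten connected lines, one red, complete at 3 s", {
  for (seed in 1:8) {
    f <- generate_figure(seed = seed)
    expect_equal(nrow(f$lines), 10)
    expect_equal(sum(f$lines$color == "red"), 1)
    expect_equal(f$lines$onset_ms, seq(0, 2700, by = 300))
    expect_equal(f$completion_ms, 3000)
    expect_equal(f$hold_ms, 1000)
    # each new line touches an endpoint of the existing drawing
    pts <- matrix(unlist(f$lines[1, c("x0", "y0", "x1", "y1")]), 2, byrow = TRUE)
    for (i in 2:10) {
      ends <- rbind(c(f$lines$x0[i], f$lines$y0[i]),
                    c(f$lines$x1[i], f$lines$y1[i]))
      touches <- any(apply(pts, 1, function(p)
        any(colSums(abs(t(ends) - p)) < 1e-9)))
      expect_true(touches)
      pts <- rbind(pts, ends)
    }
  }
})

test_that("simulated behavior respects the accuracy model", {
  sched <- generate_schedule(1, 5, seed = 2)
  tt <- simulate_behavior(sched, "MT", accuracy_model = 1, seed = 1)
  expect_true(all(tt$correct_amt[tt$condition != "P"] == 1))
  expect_true(all(is.na(tt$correct_amt[tt$condition == "P"])))
  expect_true(all(is.na(tt$rt_amt_ms[tt$condition == "P"])))
  expect_error(simulate_behavior(sched, "MT", accuracy_model = 1.2),
               "\\[0, 1\\]")
})

test_that("behavioral cell frequencies converge to the model", {
  sched <- generate_schedule(1, 2500, seed = 4)  # 10,000 trials
  tt <- simulate_behavior(sched, "NMT", accuracy_model = 0.5, seed = 8)
  obs <- mean(tt$correct_amt, na.rm = TRUE)
  expect_lt(abs(obs - 0.5), 0.02)  # ~3 binomial SEs at n = 7500
})

test_that("default accuracy model reproduces the marginal ordering", {
  sched <- generate_schedule(2, 60, seed = 3)
  tt <- rbind(simulate_behavior(sched, "MT", seed = 1, subject = "A"),
              simulate_behavior(sched, "NMT", seed = 2, subject = "B"))
  acc <- aggregate_accuracy(tt)
  expect_gt(mean(acc$proportion[acc$task == "VMT"]),
            mean(acc$proportion[acc$task == "AMT"]))
  expect_gt(mean(acc$proportion[acc$focus == "focus"]),
            mean(acc$proportion[acc$focus == "nonfocus"]))
  expect_gt(mean(acc$proportion[acc$group == "MT"]),
            mean(acc$proportion[acc$group == "NMT"]))
})

test_that("trial tables round-trip through CSV with empty-field NAs", {
  tt <- simulate_behavior(generate_schedule(1, 3, seed = 1), "MT", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tt, path)
  txt <- readLines(path)
  expect_false(any(grepl("NA", txt)))
  back <- read_trial_table(path)
  expect_equal(back$correct_amt, tt$correct_amt)
  expect_equal(back$condition, tt$condition)
  expect_equal(back$rt_vmt_ms, tt$rt_vmt_ms, tolerance = 1e-9)
})
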