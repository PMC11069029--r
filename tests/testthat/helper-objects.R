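# Shared builders for compact test fixtures.

# epochs object around a [trial, channel, time] array
make_epochs <- function(dat, fs, channels = NULL, types = NULL,
                        t0 = -1) {
  nt <- dim(dat)[3]
  if (is.null(channels))
    channels <- paste0("CH", seq_len(dim(dat)[2]))
  if (is.null(types)) types <- rep("eeg", length(channels))
  structure(list(
    data = dat, time_s = t0 + (seq_len(nt) - 1) / fs,
    channels = channels, channel_types = types, fs = fs,
    trial_keys = data.frame(run = 1, trial = seq_len(dim(dat)[1])),
    rejected = rep(FALSE, dim(dat)[1]),
    reject_reason = rep(NA_character_, dim(dat)[1]),
    interpolated = character(0), log = list()),
    class = "eeg_epochs")
}

# linear-power TFR with explicit power array [trial, channel, freq, time]
make_tfr <- function(pw, freqs, time_s, channels = NULL, trials = NULL,
                     rejected = NULL) {
  d <- dim(pw)
  if (is.null(channels)) channels <- paste0("CH", seq_len(d[2]))
  if (is.null(trials)) trials <- data.frame(run = 1, trial = seq_len(d[1]))
  if (is.null(rejected)) rejected <- rep(FALSE, d[1])
  structure(list(power = pw, freqs_hz = freqs, time_s = time_s,
                 channels = channels, units = "linear", n_cycles = 5,
                 fs = 250, edge_mask = matrix(TRUE, d[3], d[4]),
                 trial_keys = trials, rejected = rejected,
                 baseline = NULL),
            class = "eeg_tfr")
}

# dB-units TFR wrapping a trials x sites response matrix
make_db_tfr <- function(Y) {
  tfr <- make_tfr(array(Y, c(nrow(Y), 1, ncol(Y), 1)),
                  freqs = seq_len(ncol(Y)), time_s = 0)
  tfr$units <- "dB"
  tfr
}

# small two-condition trial table with explicit correctness
make_trials <- function(condition, camt, cvmt, subject = "S01",
                        group = "MT") {
  data.frame(subject = subject, group = group, run = 1,
             trial = seq_along(condition), condition = condition,
             block = 1, correct_amt = camt, correct_vmt = cvmt,
             rt_amt_ms = NA_real_, rt_vmt_ms = NA_real_,
             stringsAsFactors = FALSE)
}
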