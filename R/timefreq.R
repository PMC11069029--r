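# Morlet time-frequency decomposition and dB baseline normalization.
#
# Power is computed by convolution with complex Morlet wavelets
# (sigma_t = n_cycles / (2 pi f), unit energy, analytic) and decimated to
# the requested temporal grid by pure subsampling.  An edge-validity mask
# flags (frequency, time) cells within half the wavelet support
# (2 sigma_t) of either epoch edge; masked cells are excluded from
# baselines and all downstream statistics.

next_fast_len <- function(n) {
  # smallest 2^a * 3^b * 5^c >= n
  best <- Inf
  p5 <- 1
  while (p5 < 8 * n) {
    p35 <- p5
    while (p35 < 8 * n) {
      p <- p35
      while (p < n) p <- p * 2
      best <- min(best, p)
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  best
}

#' Morlet wavelet transform of epoched data
#'
#' @param epochs an `eeg_epochs` object (see [extract_epochs()]).
#' @param freqs analysis frequencies in Hz (default 1-45 Hz in 1 Hz steps).
#' @param n_cycles wavelet width in cycles (default 5).
#' @param t_step_ms temporal resolution of the output grid in ms (default 5);
#'   must be a multiple of the sampling step.
#' @param channels optional subset of channels to transform (default: all
#'   scalp channels).
#' @return an `eeg_tfr` object: `power` array `[trial, channel, freq, time]`
#'   in linear units, `freqs_hz`, `time_s`, `channels`, `units`
#'   (`"linear"`), `edge_mask` (`[freq, time]`, `TRUE` = valid), `trial_keys`
#'   and the trial rejection mask inherited from the epochs.
#' @export
morlet_transform <- function(epochs, freqs = 1:45, n_cycles = 5,
                             t_step_ms = 5, channels = NULL) {
  fs <- epochs$fs
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop_param("analysis frequencies must lie in (0, Nyquist)")
  step <- t_step_ms / 1000 * fs
  if (abs(step - round(step)) > 1e-8)
    stop_param("t_step_ms must be a multiple of the sampling step")
  step <- as.integer(round(step))
  if (is.null(channels)) channels <- scalp_channels(epochs)
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop_param("unknown channel in `channels`")

  n_time <- length(epochs$time_s)
  dec <- seq(1L, n_time, by = step)
  # pad so wavelet tails do not wrap into the epoch; transform length is a
  # multiple of the decimation step (exact folded-spectrum subsampling)
  margin <- ceiling(3 * n_cycles / (2 * pi * min(freqs)) * fs)
  nfft <- step * next_fast_len(ceiling((n_time + 2L * margin) / step))
  dat <- epochs$data[, ci, , drop = FALSE]
  dat[is.na(dat)] <- 0
  pw <- morlet_power_cpp(dat, as.numeric(freqs), n_cycles, fs,
                         as.integer(step), as.integer(nfft))
  time_s <- epochs$time_s[dec]
  # edge validity: half support = 2 sigma_t from either epoch edge
  half <- 2 * n_cycles / (2 * pi * freqs)
  t0 <- epochs$time_s[1]; t1 <- epochs$time_s[n_time]
  mask <- outer(half, time_s, function(h, t) t >= t0 + h & t <= t1 - h)
  structure(list(power = pw, freqs_hz = as.numeric(freqs),
                 time_s = time_s, channels = channels,
                 units = "linear", n_cycles = n_cycles, fs = fs,
                 edge_mask = mask, trial_keys = epochs$trial_keys,
                 rejected = epochs$rejected, baseline = NULL),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<eeg_tfr> %d trials x %d channels x %d freqs (%g-%g Hz) x %d times, %s units\n",
    d[1], d[2], d[3], min(x$freqs_hz), max(x$freqs_hz), d[4], x$units))
  invisible(x)
}

#' Passive-condition baseline power
#'
#' Mean linear power over the pre-stimulus second (-1 to 0 s) of
#' non-rejected passive-condition trials, per channel and frequency.  Only
#' edge-valid time samples enter the mean; frequencies whose baseline
#' window is entirely edge-masked get `NA` with a warning and are excluded
#' downstream.
#'
#' @param tfr linear-power `eeg_tfr`.
#' @param trial_table trial metadata matching the TFR's trials.
#' @param window baseline window in seconds (default `c(-1, 0)`).
#' @return matrix `[channel, freq]` of class `baseline_power`.
#' @export
compute_baseline <- function(tfr, trial_table, window = c(-1, 0)) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$units != "linear")
    stop_param("baseline must be computed on linear power")
  keys <- paste(trial_table$run, trial_table$trial)
  tk <- paste(tfr$trial_keys$run, tfr$trial_keys$trial)
  cond <- trial_table$condition[match(tk, keys)]
  use <- !is.na(cond) & cond == "P" & !tfr$rejected
  if (!any(use, na.rm = TRUE))
    stop("no usable passive-condition trials for the baseline; ",
         "provide a schedule containing non-rejected P trials")
  tin <- tfr$time_s >= window[1] & tfr$time_s <= window[2]
  nf <- length(tfr$freqs_hz); nc <- length(tfr$channels)
  out <- matrix(NA_real_, nc, nf,
                dimnames = list(tfr$channels, tfr$freqs_hz))
  dead <- logical(nf)
  for (j in seq_len(nf)) {
    tv <- tin & tfr$edge_mask[j, ]
    if (!any(tv)) { dead[j] <- TRUE; next }
    seg <- tfr$power[use, , j, tv, drop = FALSE]
    dim(seg) <- c(dim(seg)[1], nc * sum(tv))
    out[, j] <- rowMeans(matrix(colMeans(seg), nc))
  }
  if (any(dead))
    warning("no edge-valid baseline samples at ",
            paste(tfr$freqs_hz[dead], collapse = ", "),
            " Hz; these frequencies are NA and excluded downstream")
  class(out) <- c("baseline_power", "matrix")
  out
}

#' Convert linear power to dB relative to a baseline
#'
#' `10 * log10(power / baseline)` elementwise over channel x frequency.
#'
#' @param tfr linear-power `eeg_tfr`.
#' @param baseline a `baseline_power` matrix from [compute_baseline()].
#' @return `eeg_tfr` with `units = "dB"` and the baseline attached.
#' @export
to_decibels <- function(tfr, baseline) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$units != "linear") stop_param("tfr is already in dB units")
  bad <- which(!is.na(baseline) & baseline <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive baseline at channel ", rownames(baseline)[bad[1, 1]],
         ", ", colnames(baseline)[bad[1, 2]], " Hz")
  d <- dim(tfr$power)
  b <- array(rep(as.numeric(baseline), each = d[1]), dim = d)
  tfr$power <- 10 * log10(tfr$power / b)
  tfr$units <- "dB"
  tfr$baseline <- baseline
  # frequencies without baseline are invalid everywhere
  tfr$edge_mask[is.na(baseline[1, ]) |
                  apply(is.na(baseline), 2, any), ] <- FALSE
  tfr
}
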