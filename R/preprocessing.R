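# Preprocessing: high-pass filtering, ICA blink removal, epoching,
# artifact-trial rejection, spherical-spline channel interpolation.

#' Design the minimum-order Butterworth high-pass filter
#'
#' Meets the template: at most `ripple_db` attenuation at `pass_hz` and at
#' least `atten_db` at `stop_hz`.  The order comes from
#' [signal::buttord()]; the returned object carries both the (b, a)
#' coefficients used for zero-phase application and a zero-pole-gain form
#' for numerically stable response evaluation near DC.
#'
#' @param stop_hz stopband edge (default 0.05 Hz).
#' @param pass_hz passband edge (default 0.1 Hz).
#' @param atten_db minimum stopband attenuation (default 15 dB).
#' @param ripple_db maximum passband ripple (default 1 dB).
#' @param fs sampling rate in Hz.
#' @return object of class `hp_filter` with elements `n` (order), `b`, `a`,
#'   `z`, `p`, `g`, `fs`, and `response(f)` returning linear gain.
#' @examples
#' filt <- design_highpass(fs = 1000)
#' -20 * log10(filt$response(0.05))  # >= 15 dB
#' @export
design_highpass <- function(stop_hz = 0.05, pass_hz = 0.1, atten_db = 15,
                            ripple_db = 1, fs = 1000) {
  if (stop_hz >= pass_hz) stop_param("stopband edge must be below passband")
  if (atten_db <= ripple_db) stop_param("attenuation must exceed ripple")
  if (fs <= 2 * pass_hz) stop_param("fs too low for the passband edge")
  bo <- signal::buttord(pass_hz / (fs / 2), stop_hz / (fs / 2),
                        ripple_db, atten_db)
  ba <- signal::butter(bo$n, bo$Wc, type = "high")
  # zero-pole-gain form via bilinear transform of the analog prototype
  wa <- tan(pi * bo$Wc / 2)
  k <- seq_len(bo$n)
  q <- exp(1i * pi * (2 * k + bo$n - 1) / (2 * bo$n))
  pa <- wa / q
  pd <- (1 + pa) / (1 - pa)
  g <- Re(prod(-1 - pd) / (-2)^bo$n)  # unity gain at Nyquist
  zp <- list(z = rep(1 + 0i, bo$n), p = pd, g = g)
  response <- function(f) {
    vapply(f, function(fi) {
      e <- exp(1i * 2 * pi * fi / fs)
      abs(zp$g) * prod(abs(e - zp$z)) / prod(abs(e - zp$p))
    }, numeric(1))
  }
  structure(list(n = bo$n, Wc = bo$Wc, b = ba$b, a = ba$a,
                 z = zp$z, p = zp$p, g = zp$g, fs = fs,
                 stop_hz = stop_hz, pass_hz = pass_hz,
                 response = response),
            class = "hp_filter")
}

#' Apply a filter to a recording (zero-phase by default)
#'
#' Forward-backward application ([signal::filtfilt()]) doubles the
#' effective attenuation and cancels phase distortion; set
#' `zero_phase = FALSE` for a single forward pass.
#'
#' @param recording an `eeg_recording`.
#' @param filt an `hp_filter` from [design_highpass()].
#' @param zero_phase logical.
#' @return the filtered recording.
#' @export
apply_filter <- function(recording, filt, zero_phase = TRUE) {
  for (i in seq_len(nrow(recording$data))) {
    x <- recording$data[i, ]
    recording$data[i, ] <- if (zero_phase)
      signal::filtfilt(filt$b, filt$a, x)
    else as.numeric(signal::filter(filt$b, filt$a, x))
  }
  recording
}

# FastICA (symmetric orthogonalization, tanh contrast) on the rows of X.
# Restarts from fresh random rotations if an orbit fails to converge;
# errors with diagnostics only after all restarts are exhausted.
# Returns unmixing of the whitened data plus the maps back to sensor space.
fast_ica <- function(X, n_comp, max_iter = 1000, tol = 1e-3, seed = 1,
                     restarts = 3) {
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  ok <- eg$values > max(eg$values) * 1e-9
  keep <- which(ok)[seq_len(min(n_comp, sum(ok)))]
  E <- eg$vectors[, keep, drop = FALSE]
  D <- eg$values[keep]
  Z <- crossprod(E, Xc) / sqrt(D)  # whitened k x T
  k <- length(keep)
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% W
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      W <- sym_decor(qr.Q(qr(matrix(rnorm(k * k), k))))
      Wprev <- W
      it <- 0; delta <- Inf
      while (it < max_iter) {
        it <- it + 1
        S <- W %*% Z
        G <- tanh(S)
        Wn <- tcrossprod(G, Z) / ncol(Z) - diag(rowMeans(1 - G^2), k) %*% W
        Wn <- sym_decor(Wn)
        # near-Gaussian components make the symmetric decorrelation
        # two-cycle, so compare against the last two iterates
        delta <- min(max(abs(1 - abs(rowSums(Wn * W)))),
                     max(abs(1 - abs(rowSums(Wn * Wprev)))))
        Wprev <- W
        W <- Wn
        if (delta < tol) break
      }
      if (is.null(best) || delta < best$change)
        best <- list(W = W, iterations = it, change = delta)
      if (delta < tol) break
    }
  })
  if (best$change >= tol)
    stop("ICA did not converge: ", restarts, " restarts of ", max_iter,
         " iterations, smallest change ", signif(best$change, 3),
         " (tolerance ", tol, ")")
  W <- best$W
  list(S = W %*% Z,                       # sources k x T
       A = E %*% (sqrt(D) * t(W)),        # sensor-space patterns ch x k
       W = W, iterations = best$iterations, change = best$change)
}

#' Remove blink components by ICA
#'
#' Decomposes the scalp channels with FastICA and zeroes the components
#' whose absolute correlation with the vertical EOG difference signal
#' (upper minus lower) exceeds `corr_threshold`; the cleaned recording is
#' the original minus the removed components' sensor-space contribution,
#' so an empty removal set returns the input unchanged.
#'
#' @param recording an `eeg_recording` (high-pass filtered).
#' @param veog_labels the two vertical EOG labels, upper first.
#' @param corr_threshold removal criterion (default 0.7).
#' @param n_comp maximum number of components (default 20).
#' @param seed seed for the ICA initialization.
#' @return list: `recording` (cleaned), `report` data.frame (`component`,
#'   `correlation`, `removed`), `iterations`.
#' @export
remove_blinks <- function(recording, veog_labels = c("VEOGU", "VEOGL"),
                          corr_threshold = 0.7, n_comp = 20, seed = 1) {
  vi <- match(veog_labels, recording$channels)
  if (anyNA(vi)) stop_param("VEOG channels not found in recording")
  sc <- scalp_idx(recording)
  X <- recording$data[sc, , drop = FALSE]
  ica <- fast_ica(X, min(n_comp, length(sc)), seed = seed)
  veog <- recording$data[vi[1], ] - recording$data[vi[2], ]
  corr <- as.numeric(cor(t(ica$S), veog))
  removed <- which(abs(corr) > corr_threshold)
  if (length(removed)) {
    contrib <- ica$A[, removed, drop = FALSE] %*%
      ica$S[removed, , drop = FALSE]
    recording$data[sc, ] <- X - contrib
  }
  list(recording = recording,
       report = data.frame(component = seq_along(corr), correlation = corr,
                           removed = seq_along(corr) %in% removed),
       iterations = ica$iterations)
}

#' Extract stimulus-locked epochs
#'
#' One epoch per stimulus-onset event, `window[1]` to `window[2]` seconds
#' around it; sample values are copied unchanged and the sample at t = 0 is
#' the event sample.  Events too close to the recording edges yield a
#' trial marked rejected with reason `"edge"` (data `NA`).
#'
#' @param recording an `eeg_recording` with events.
#' @param window epoch window in seconds (default `c(-1, 4)`).
#' @return an `eeg_epochs` object: `data` `[trial, channel, time]`,
#'   `time_s`, `channels`, `channel_types`, `fs`, `trial_keys`, `rejected`,
#'   `reject_reason`, `interpolated`, `log`.
#' @export
extract_epochs <- function(recording, window = c(-1, 4)) {
  fs <- recording$fs
  ev <- recording$events
  if (is.null(ev)) ev <- data.frame(sample = integer(0), run = integer(0),
                                    trial = integer(0))
  i0 <- round(window[1] * fs); i1 <- round(window[2] * fs)
  nt <- i1 - i0 + 1
  n_ev <- nrow(ev)
  nch <- length(recording$channels)
  dat <- array(NA_real_, c(n_ev, nch, nt))
  rejected <- logical(n_ev)
  reason <- rep(NA_character_, n_ev)
  nsamp <- ncol(recording$data)
  for (e in seq_len(n_ev)) {
    a <- ev$sample[e] + i0; b <- ev$sample[e] + i1
    if (a < 1 || b > nsamp) {
      rejected[e] <- TRUE; reason[e] <- "edge"
      next
    }
    dat[e, , ] <- recording$data[, a:b]
  }
  types <- recording$montage$type[match(recording$channels,
                                        recording$montage$label)]
  structure(list(data = dat, time_s = seq(i0, i1) / fs,
                 channels = recording$channels,
                 channel_types = types %||% rep("eeg", nch), fs = fs,
                 trial_keys = ev, rejected = rejected,
                 reject_reason = reason, interpolated = character(0),
                 log = list(window = window)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz (%d rejected)\n",
              d[1], d[2], d[3], x$fs, sum(x$rejected)))
  invisible(x)
}

scalp_channels <- function(epochs) {
  epochs$channels[epochs$channel_types == "eeg"]
}

#' Flag artifact trials by amplitude and spectral criteria
#'
#' A trial is flagged when (a) on any scalp channel its peak absolute
#' amplitude exceeds that channel's across-trial mean + `amp_sd` SDs of
#' per-trial peaks, or (b) on any scalp channel more than `spec_fraction`
#' of the Fourier amplitude bins within `spec_band` exceed that bin's
#' across-trial mean + `spec_sd` SDs.  Both criteria use strict excess, so
#' degenerate zero-variance data flags nothing.  Flags are combined into
#' the epochs' rejection mask.
#'
#' @param epochs an `eeg_epochs` (>= 2 usable trials).
#' @param amp_sd amplitude criterion in SDs (default 3).
#' @param spec_sd spectral criterion in SDs (default 2).
#' @param spec_fraction fraction of violating bins required (default 0.2).
#' @param spec_band spectral band in Hz (default `c(1, 80)`, clipped to
#'   Nyquist).
#' @return the epochs with updated `rejected`/`reject_reason`, plus a
#'   `detect` entry in the log (per-trial summary table).
#' @export
detect_artifact_trials <- function(epochs, amp_sd = 3, spec_sd = 2,
                                   spec_fraction = 0.2,
                                   spec_band = c(1, 80)) {
  usable <- which(!epochs$rejected)
  if (length(usable) < 2)
    stop("need at least 2 usable trials to estimate rejection thresholds")
  sci <- which(epochs$channel_types == "eeg")
  d <- dim(epochs$data)
  nt <- d[3]
  # (a) per-channel across-trial distribution of per-trial peak amplitude
  peaks <- apply(abs(epochs$data[usable, sci, , drop = FALSE]), c(1, 2), max)
  thr_a <- colMeans(peaks) + amp_sd * apply(peaks, 2, sd)
  amp_bad <- rowSums(sweep(peaks, 2, thr_a, ">")) > 0
  # (b) Fourier amplitude spectrum per trial/channel within the band
  # (zero-padded to an FFT-friendly length)
  nfft <- next_fast_len(nt)
  f <- (seq_len(nfft) - 1) * epochs$fs / nfft
  bins <- which(f >= spec_band[1] & f <= min(spec_band[2], epochs$fs / 2))
  spec_bad <- logical(length(usable))
  pad <- matrix(0, nfft, length(usable))
  for (ci in seq_along(sci)) {
    pad[seq_len(nt), ] <- t(epochs$data[usable, sci[ci], ])
    amps <- abs(mvfft(pad))[bins, , drop = FALSE]
    thr <- rowMeans(amps) + spec_sd * apply(amps, 1, sd)
    frac <- colMeans(amps > thr)
    spec_bad <- spec_bad | frac > spec_fraction
  }
  reasons <- ifelse(amp_bad & spec_bad, "amplitude+spectrum",
                    ifelse(amp_bad, "amplitude",
                           ifelse(spec_bad, "spectrum", NA)))
  flag <- usable[amp_bad | spec_bad]
  epochs$rejected[flag] <- TRUE
  epochs$reject_reason[flag] <- reasons[amp_bad | spec_bad]
  epochs$log$detect <- data.frame(
    trial = usable, peak_over = amp_bad, spec_over = spec_bad)
  epochs
}

# Spherical-spline interpolation matrix (order m = 4, Legendre expansion
# truncated at 7 terms): rows = bad electrodes, cols = good electrodes.
spline_transfer <- function(good_xyz, bad_xyz, m = 4, terms = 7) {
  legendre_g <- function(x) {
    # g(x) = 1/(4 pi) sum_n (2n+1) / (n (n+1))^m  P_n(x)
    pn_m1 <- rep(1, length(x)); pn <- x
    out <- 3 / (1 * 2)^m * pn
    for (n in 2:terms) {
      pnew <- ((2 * n - 1) * x * pn - (n - 1) * pn_m1) / n
      pn_m1 <- pn; pn <- pnew
      out <- out + (2 * n + 1) / (n * (n + 1))^m * pn
    }
    out / (4 * pi)
  }
  cosang <- function(A, B) clamp_cos(tcrossprod(A, B))
  ng <- nrow(good_xyz)
  G <- matrix(legendre_g(cosang(good_xyz, good_xyz)), ng)
  Gb <- matrix(legendre_g(cosang(bad_xyz, good_xyz)), nrow(bad_xyz))
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  # the truncated expansion makes A numerically rank-deficient on dense
  # montages; a pseudoinverse keeps the interpolant well defined
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * 1e-12
  Ainv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  (cbind(Gb, 1) %*% Ainv)[, seq_len(ng), drop = FALSE]
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces each listed channel by the order-4 spherical-spline estimate
#' (Legendre expansion truncated at 7 terms) from the remaining good scalp
#' channels, at every trial and time point.
#'
#' @param epochs an `eeg_epochs`.
#' @param bad labels of channels to interpolate.
#' @param montage montage with unit-sphere positions for the scalp channels.
#' @return the epochs with interpolated data and the `interpolated` list
#'   updated.
#' @export
interpolate_channels <- function(epochs, bad, montage = montage_1020()) {
  if (!length(bad)) return(epochs)
  sc <- scalp_channels(epochs)
  if (!all(bad %in% sc)) stop_param("bad channels must be scalp channels")
  good <- setdiff(sc, bad)
  if (length(good) < 4) stop("need at least 4 good channels to interpolate")
  pos <- montage[match(c(good, bad), montage$label), c("x", "y", "z")]
  if (anyNA(pos)) stop_param("montage lacks positions for some channels")
  Tm <- spline_transfer(as.matrix(pos[seq_along(good), ]),
                        as.matrix(pos[length(good) + seq_along(bad), ]))
  gi <- match(good, epochs$channels); bi <- match(bad, epochs$channels)
  d <- dim(epochs$data)
  for (tr in seq_len(d[1])) {
    seg <- epochs$data[tr, gi, , drop = TRUE]
    if (anyNA(seg)) next
    epochs$data[tr, bi, ] <- Tm %*% seg
  }
  epochs$interpolated <- union(epochs$interpolated, bad)
  epochs
}

#' Identify noisy channels by excess variance
#'
#' A scalp channel is declared noisy when its variance exceeds the
#' across-channel center by more than `sd_mult` spreads.  Robust location
#' and spread (median and scaled MAD) are used so a single very noisy
#' channel cannot mask itself by inflating the spread estimate.
#' @param recording an `eeg_recording`.
#' @param sd_mult threshold (default 3).
#' @return character vector of noisy channel labels.
#' @export
detect_noisy_channels <- function(recording, sd_mult = 3) {
  sc <- scalp_idx(recording)
  v <- apply(recording$data[sc, , drop = FALSE], 1, var)
  spread <- stats::mad(v)
  if (spread == 0) return(character(0))
  thr <- median(v) + sd_mult * spread
  recording$channels[sc][v > thr]
}
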