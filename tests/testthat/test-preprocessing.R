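# Filtering, blink removal, epoching, artifact rejection, interpolation.

test_that("the high-pass filter meets the design template", {
  filt <- design_highpass(fs = 1000)
  atten <- function(f) -20 * log10(filt$response(f))
  expect_gte(atten(0.05), 15)
  expect_lte(atten(0.1), 1 + 1e-6)
  expect_lt(abs(filt$response(10) - 1), 0.01)
  expect_lt(abs(filt$response(100) - 1), 0.01)
  # template checks
  expect_error(design_highpass(stop_hz = 0.2, pass_hz = 0.1), "below")
  expect_error(design_highpass(atten_db = 0.5, ripple_db = 1), "exceed")
})

test_that("the zero-pole response matches the polynomial response", {
  filt <- design_highpass(fs = 250)
  for (f in c(1, 5, 20)) {
    e <- exp(-1i * 2 * pi * f / 250)
    hp <- abs(sum(filt$b * e^(0:filt$n)) / sum(filt$a * e^(0:filt$n)))
    expect_equal(filt$response(f), hp, tolerance = 1e-4)
  }
})

test_that("zero-phase filtering is linear", {
  m <- montage_1020(c("CZ", "PZ"))
  filt <- design_highpass(fs = 250)
  set.seed(9)
  x <- simulate_background(m, 4, 250, seed = 1)
  y <- simulate_background(m, 4, 250, seed = 2)
  z <- x; z$data <- 2 * x$data + 3 * y$data
  fx <- apply_filter(x, filt); fy <- apply_filter(y, filt)
  fz <- apply_filter(z, filt)
  expect_equal(fz$data, 2 * fx$data + 3 * fy$data, tolerance = 1e-5)
})

test_that("epoch extraction is exact and flags edge events", {
  m <- montage_1020(c("CZ", "PZ"))
  fs <- 250
  rec <- simulate_background(m, 30, fs, seed = 2)
  rec$events <- data.frame(sample = c(100, 2000, 4000), run = 1, trial = 1:3)
  ep <- extract_epochs(rec, c(-1, 4))
  expect_equal(dim(ep$data), c(3, nrow(m), 5 * fs + 1))
  expect_true(ep$rejected[1])
  expect_equal(ep$reject_reason[1], "edge")
  # sample at t = 0 is the event sample, values copied exactly
  i0 <- which(ep$time_s == 0)
  expect_equal(ep$data[2, , i0], unname(rec$data[, 2000]))
  expect_equal(ep$data[2, 1, ], unname(rec$data[1, (2000 - fs):(2000 + 4 * fs)]))
  # empty event list
  rec$events <- NULL
  ep0 <- extract_epochs(rec)
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("identical trials are never flagged as artifacts", {
  one <- matrix(rnorm(2 * 500), 2, 500)
  dat <- array(0, c(10, 2, 500))
  for (i in 1:10) dat[i, , ] <- one
  ep <- make_epochs(dat, 250)
  out <- detect_artifact_trials(ep)
  expect_false(any(out$rejected))
  expect_error(detect_artifact_trials(make_epochs(dat[1, , , drop = FALSE],
                                                  250)),
               "at least 2")
})

test_that("amplitude spikes and broadband noise are flagged with reasons", {
  set.seed(3)
  dat <- array(rnorm(41 * 2 * 500), c(41, 2, 500))
  dat[7, 1, 250] <- 10 * max(abs(dat))       # amplitude spike
  dat[13, 2, ] <- dat[13, 2, ] + rnorm(500, sd = 3)  # broadband noise
  ep <- make_epochs(dat, 250)
  out <- detect_artifact_trials(ep)
  expect_true(out$rejected[7])
  expect_match(out$reject_reason[7], "amplitude")
  expect_true(out$rejected[13])
  expect_match(out$reject_reason[13], "spectrum")
  expect_lte(sum(out$rejected), 4)
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  mont <- montage_1020()
  sc <- mont[mont$type == "eeg", ]
  # independent construction of a field inside the interpolant space:
  # order-4 spline kernel (7 Legendre terms) anchored at good electrodes
  g_kernel <- function(x) {
    p0 <- rep(1, length(x)); p1 <- x
    out <- 3 / 2^4 * p1
    for (n in 2:7) {
      p2 <- ((2 * n - 1) * x * p1 - (n - 1) * p0) / n
      p0 <- p1; p1 <- p2
      out <- out + (2 * n + 1) / (n * (n + 1))^4 * p2
    }
    out / (4 * pi)
  }
  set.seed(5)
  xyz <- as.matrix(sc[, c("x", "y", "z")])
  anchors <- xyz[sc$label %in% c("FZ", "T7", "T8", "PZ", "OZ"), ]
  coef <- rnorm(5, sd = 10)
  coef <- coef - mean(coef)  # the interpolant space is sum-to-zero
  field <- as.vector(g_kernel(pmax(pmin(xyz %*% t(anchors), 1), -1)) %*%
                       coef) + 2
  nt <- 5
  dat <- array(rep(field, each = 1), c(1, nrow(sc), nt))
  for (t in seq_len(nt)) dat[1, , t] <- field * t
  ep <- make_epochs(dat, 100, channels = sc$label)
  bad <- "CZ"
  out <- interpolate_channels(ep, bad, mont)
  i <- match(bad, ep$channels)
  err <- max(abs(out$data[1, i, ] - dat[1, i, ]) / max(abs(dat[1, i, ])))
  expect_lt(err, 0.01)
  expect_equal(out$interpolated, bad)
  # no bad channels: identity; all-zero neighbors: zeros
  expect_identical(interpolate_channels(ep, character(0))$data, ep$data)
  zero <- ep; zero$data[] <- 0
  expect_equal(max(abs(interpolate_channels(zero, "CZ", mont)$data)), 0)
  expect_error(interpolate_channels(
    make_epochs(dat[, 1:3, , drop = FALSE], 100,
                channels = sc$label[1:3]), sc$label[1], mont),
    "at least 4")
})

test_that("ICA blink removal cleans frontal channels and reports", {
  m <- montage_1020(c("FP1", "FPZ", "FP2", "FZ", "CZ", "PZ", "O1", "O2"))
  rec <- simulate_background(m, 60, 250, seed = 11)
  art <- add_artifacts(rec, blink_rate = 20, seed = 3)
  dirty <- art$recording
  veog <- dirty$data["VEOGU", ] - dirty$data["VEOGL", ]
  expect_gt(abs(cor(dirty$data["FPZ", ], veog)), 0.5)
  out <- remove_blinks(dirty, n_comp = 8)
  expect_true(any(out$report$removed))
  expect_lt(abs(cor(out$recording$data["FPZ", ], veog)), 0.3)
  # clean recording: nothing removed, output close to input
  out0 <- remove_blinks(rec, n_comp = 8)
  expect_false(any(out0$report$removed))
  expect_lt(max(abs(out0$recording$data - rec$data)), 1)
  # unreachable threshold removes nothing even on dirty data
  out1 <- remove_blinks(dirty, corr_threshold = 1.01, n_comp = 8)
  expect_identical(out1$recording$data, dirty$data)
})

test_that("preprocessing is deterministic", {
  m <- montage_1020(c("FP1", "FPZ", "FP2", "FZ", "CZ", "PZ", "O1", "O2"))
  rec <- simulate_background(m, 30, 250, seed = 11)
  rec <- add_artifacts(rec, blink_rate = 10, seed = 3)$recording
  a <- remove_blinks(rec, n_comp = 6, seed = 2)
  b <- remove_blinks(rec, n_comp = 6, seed = 2)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$report, b$report)
})
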