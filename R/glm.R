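# First-level mass-univariate GLM of single-trial oscillatory power.
#
# Model 1 regresses dB power at each (channel, frequency, time) site on an
# intercept, dummies for the three active attention conditions (ASA, VSA,
# DA), and dummies for trials followed by a correct response to the
# attended modality (ASAcAMT, VSAcVMT, DAcAMTandVMT).  Model 2 adds the
# unattended-modality correctness dummies (ASAcVMT, VSAcAMT).  Passive
# trials carry the intercept only (reference level).

MODEL1_COLS <- c("intercept", "ASA", "VSA", "DA",
                 "ASAcAMT", "VSAcVMT", "DAcAMTandVMT")
MODEL2_COLS <- c(MODEL1_COLS, "ASAcVMT", "VSAcAMT")

CONTRASTS <- list(
  `attended-correct` = c("ASAcAMT", "VSAcVMT", "DAcAMTandVMT"),
  `any-correct` = c("ASAcAMT", "VSAcVMT", "DAcAMTandVMT", "ASAcVMT",
                    "VSAcAMT"))

#' Build the single-trial design matrix
#'
#' @param trial_table rows for the retained trials of one subject.
#' @param model 1 or 2.
#' @return numeric matrix (trials x regressors) with the fixed column order
#'   documented above; class `glm_design`.
#' @export
build_design <- function(trial_table, model = 1) {
  if (!model %in% c(1, 2)) stop_param("model must be 1 or 2")
  cond <- trial_table$condition
  bad <- setdiff(unique(cond), c("ASA", "VSA", "DA", "P"))
  if (length(bad)) stop_param("unknown condition label(s): ",
                              paste(bad, collapse = ", "))
  camt <- trial_table$correct_amt %in% 1
  cvmt <- trial_table$correct_vmt %in% 1
  X <- cbind(
    intercept = 1,
    ASA = as.numeric(cond == "ASA"),
    VSA = as.numeric(cond == "VSA"),
    DA = as.numeric(cond == "DA"),
    ASAcAMT = as.numeric(cond == "ASA" & camt),
    VSAcVMT = as.numeric(cond == "VSA" & cvmt),
    DAcAMTandVMT = as.numeric(cond == "DA" & camt & cvmt))
  if (model == 2)
    X <- cbind(X,
               ASAcVMT = as.numeric(cond == "ASA" & cvmt),
               VSAcAMT = as.numeric(cond == "VSA" & camt))
  class(X) <- c("glm_design", class(X))
  X
}

#' Design diagnostics
#'
#' @param design a design matrix from [build_design()].
#' @return list with `column_sums`, `rank`, `condition_number`,
#'   `empty_columns`, `rank_deficient`.
#' @export
check_design <- function(design) {
  cs <- colSums(design)
  empty <- names(cs)[cs == 0]
  keep <- design[, cs > 0, drop = FALSE]
  qrk <- qr(keep)$rank
  sv <- svd(keep, nu = 0, nv = 0)$d
  list(column_sums = cs, rank = qrk,
       condition_number = if (min(sv) > 0) max(sv) / min(sv) else Inf,
       empty_columns = empty,
       rank_deficient = qrk < ncol(keep))
}

#' Fit the mass-univariate GLM
#'
#' Independent ordinary least squares across trials at every (channel,
#' frequency, time) site; `t_j = beta_j / SE(beta_j)` with the residual
#' variance on `n - p` degrees of freedom.  Regressor columns with no
#' qualifying trials are dropped for this subject (their t-maps are `NA`)
#' with a warning.  Sites that are edge-masked, or whose response is `NA`,
#' yield `NA`.  Zero-residual-variance sites get t capped at `+/- 1e6`.
#'
#' @param tfr a dB-units `eeg_tfr` whose trial axis matches `design` rows
#'   after dropping rejected trials.
#' @param design matrix from [build_design()] (all trials); rejected trials
#'   are dropped in register with the TFR.
#' @return object of class `tstat_map`: `t` and `beta` arrays
#'   `[regressor, channel, freq, time]`, `df`, `regressors`,
#'   `dropped` (empty columns), `n_trials`.
#' @export
fit_glm <- function(tfr, design) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$units != "dB")
    warning("fitting on ", tfr$units, " power; the standard pipeline fits dB")
  use <- !tfr$rejected
  if (nrow(design) != length(use))
    stop_param("design rows (", nrow(design),
               ") do not match TFR trials (", length(use), ")")
  X <- design[use, , drop = FALSE]
  d <- dim(tfr$power)
  nsite <- prod(d[2:4])
  Y <- matrix(tfr$power[use, , , ], nrow = sum(use))
  cs <- colSums(X)
  dropped <- colnames(X)[cs == 0]
  keep <- which(cs > 0)
  # a correctness dummy can coincide with its condition dummy when a cell
  # is answered perfectly (or always incorrectly); such columns are not
  # estimable for this subject and are dropped like empty ones.  Greedy
  # rank construction in column order prefers keeping the condition
  # dummies over the correctness dummies.
  sel <- integer(0)
  for (j in keep) {
    cand <- c(sel, j)
    if (qr(X[, cand, drop = FALSE])$rank == length(cand)) sel <- cand
    else dropped <- c(dropped, colnames(X)[j])
  }
  if (length(dropped))
    warning("dropping non-estimable regressor column(s): ",
            paste(dropped, collapse = ", "))
  keep <- sel
  Xk <- X[, keep, drop = FALSE]
  n <- nrow(Xk); p <- ncol(Xk)
  if (n <= p) stop("not enough trials (", n, ") for ", p, " regressors")
  qx <- qr(Xk)
  # site order is channel-fastest, then frequency, then time
  vmask <- rep(as.vector(tfr$edge_mask), each = d[2])
  beta <- qr.coef(qx, Y)
  res <- Y - Xk %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  xtxinv_diag <- diag(chol2inv(qr.R(qx)))
  se <- sqrt(outer(xtxinv_diag, sigma2))
  tval <- beta / se
  # (near-)zero residual variance: cap at +/- 1e6 (0 for a zero
  # coefficient) instead of letting t blow up on rounding noise
  zv <- which(sigma2 <= 1e-10 * (colMeans(Y^2) + 1e-300))
  if (length(zv)) {
    capped <- sign(beta[, zv, drop = FALSE]) * 1e6
    tval[, zv] <- capped
  }
  inf <- is.infinite(tval)
  tval[inf] <- sign(beta[inf]) * 1e6
  tval[is.nan(tval)] <- 0
  tval[, !vmask] <- NA_real_
  full_t <- matrix(NA_real_, ncol(X), nsite)
  full_b <- matrix(NA_real_, ncol(X), nsite)
  full_t[keep, ] <- tval
  full_b[keep, ] <- beta
  dim(full_t) <- c(ncol(X), d[2], d[3], d[4])
  dim(full_b) <- c(ncol(X), d[2], d[3], d[4])
  dimnames(full_t)[[1]] <- colnames(X)
  structure(list(t = full_t, beta = full_b, df = n - p,
                 regressors = colnames(X), dropped = dropped,
                 n_trials = n, channels = tfr$channels,
                 freqs_hz = tfr$freqs_hz, time_s = tfr$time_s,
                 edge_mask = tfr$edge_mask),
            class = "tstat_map")
}

#' @export
print.tstat_map <- function(x, ...) {
  cat(sprintf("<tstat_map> %d regressors x %d channels x %d freqs x %d times (df = %d)\n",
              dim(x$t)[1], dim(x$t)[2], dim(x$t)[3], dim(x$t)[4], x$df))
  invisible(x)
}

#' Average regressor t-maps into a contrast map
#'
#' `"attended-correct"` (Model 1) averages the t-maps of ASAcAMT, VSAcVMT,
#' DAcAMTandVMT; `"any-correct"` (Model 2) additionally includes ASAcVMT
#' and VSAcAMT.  Constituents dropped at fit time are skipped with a
#' warning (the mean uses the available maps).
#'
#' @param tmaps a `tstat_map`.
#' @param contrast `"attended-correct"` or `"any-correct"`.
#' @return array `[channel, freq, time]` with attributes `contrast` and
#'   `constituents`.
#' @export
make_contrast <- function(tmaps, contrast = c("attended-correct",
                                              "any-correct")) {
  contrast <- match.arg(contrast)
  want <- CONTRASTS[[contrast]]
  missing <- setdiff(want, tmaps$regressors)
  if (length(missing))
    stop_param("model lacks regressor(s) ", paste(missing, collapse = ", "),
               " required by contrast ", contrast)
  avail <- setdiff(want, tmaps$dropped)
  if (!length(avail))
    stop("all constituent regressors were dropped; no contrast available")
  if (length(avail) < length(want))
    warning("contrast ", contrast, " uses ", length(avail), "/",
            length(want), " constituents (dropped: ",
            paste(setdiff(want, avail), collapse = ", "), ")")
  idx <- match(avail, tmaps$regressors)
  d <- dim(tmaps$t)
  m <- array(colMeans(matrix(tmaps$t[idx, , , , drop = FALSE],
                             nrow = length(idx))), d[2:4])
  attr(m, "contrast") <- contrast
  attr(m, "constituents") <- avail
  m
}
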