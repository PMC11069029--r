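# Single-trial design matrices, mass-univariate OLS, and contrasts.

test_that("design rows encode condition and correctness dummies", {
  trials <- make_trials(c("ASA", "P", "DA", "VSA"),
                        camt = c(1, NA, 1, 0), cvmt = c(0, NA, 0, 1))
  X1 <- build_design(trials, 1)
  expect_equal(colnames(X1),
               c("intercept", "ASA", "VSA", "DA", "ASAcAMT", "VSAcVMT",
                 "DAcAMTandVMT"))
  expect_equal(unname(X1[1, ]), c(1, 1, 0, 0, 1, 0, 0))  # ASA, correct AMT
  expect_equal(unname(X1[3, ]), c(1, 0, 0, 1, 0, 0, 0))  # DA correct AMT only
  X2 <- build_design(trials, 2)
  expect_equal(unname(X2[2, ]), c(1, rep(0, 8)))  # passive: intercept only
  expect_equal(unname(X2[4, ]), c(1, 0, 1, 0, 0, 1, 0, 0, 0))
  expect_error(build_design(make_trials("XX", 1, 1), 1), "condition")
  expect_error(build_design(trials, 3), "model")
})

test_that("design diagnostics report empty columns and rank", {
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), each = 5),
                        camt = c(1, 1, 1, 0, 0, 0, 1, 0, 0, 1,
                                 1, 1, 0, 1, 0, rep(NA, 5)),
                        cvmt = c(0, 1, 0, 1, 1, 1, 1, 1, 0, 1,
                                 1, 1, 0, 1, 0, rep(NA, 5)))
  chk <- check_design(build_design(trials, 1))
  expect_equal(chk$rank, 7)
  expect_length(chk$empty_columns, 0)
  # no correct ASA trials: empty column flagged
  trials2 <- trials; trials2$correct_amt[trials2$condition == "ASA"] <- 0
  chk2 <- check_design(build_design(trials2, 1))
  expect_equal(chk2$empty_columns, "ASAcAMT")
  # duplicated column: rank deficiency flagged
  X <- build_design(trials, 1)
  X[, "VSAcVMT"] <- X[, "VSA"]
  expect_true(check_design(X)$rank_deficient)
})

test_that("OLS matches the closed-form normal-equations oracle", {
  set.seed(7)
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), times = c(3, 2, 2, 1)),
                        camt = c(1, 0, 1, 0, 1, 1, 0, NA),
                        cvmt = c(0, 0, 1, 1, 0, 1, 0, NA))
  X <- build_design(trials, 1)
  keep <- colSums(X) > 0
  y <- c(2.3, -1.1, 0.4, 1.9, -0.7, 0.2, 1.4, -0.6)
  Xk <- X[, keep]
  b_oracle <- solve(crossprod(Xk)) %*% crossprod(Xk, y)
  fit <- suppressWarnings(fit_glm(make_db_tfr(matrix(y)), X))
  got <- fit$beta[which(keep), 1, 1, 1]
  expect_equal(unname(got), as.numeric(b_oracle), tolerance = 1e-10)
  # and the full random-fixture sweep
  chk <- glm_oracle_check(n_fixtures = 10, seed = 3)
  expect_lt(chk$max_beta_err, 1e-8)
  expect_lt(chk$max_t_err, 1e-8)
})

test_that("noiseless responses give exact coefficients and capped t", {
  trials <- make_trials(rep(c("ASA", "P"), each = 10),
                        camt = rep(c(1, NA), each = 10),
                        cvmt = rep(c(0, NA), each = 10))
  X <- build_design(trials, 1)
  y <- 2 * X[, "ASA"]
  fit <- suppressWarnings(fit_glm(make_db_tfr(matrix(y)), X))
  i <- match("ASA", fit$regressors)
  expect_equal(fit$beta[i, 1, 1, 1], 2, tolerance = 1e-10)
  expect_true(is.finite(fit$t[i, 1, 1, 1]))
  expect_equal(unname(abs(fit$t[i, 1, 1, 1])), 1e6)
})

test_that("results are invariant to trial order", {
  set.seed(8)
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), each = 6),
                        camt = rep(c(1, 0), 12), cvmt = rep(c(0, 1), 12))
  X <- build_design(trials, 2)
  Y <- matrix(rnorm(24 * 5), 24)
  f1 <- suppressWarnings(fit_glm(make_db_tfr(Y), X))
  perm <- sample(24)
  f2 <- suppressWarnings(fit_glm(make_db_tfr(Y[perm, , drop = FALSE]),
                                 X[perm, ]))
  expect_equal(f1$t, f2$t, tolerance = 1e-9)
})

test_that("rejected trials are excluded listwise", {
  set.seed(9)
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), each = 6),
                        camt = rep(c(1, 0), 12), cvmt = rep(c(0, 1), 12))
  X <- build_design(trials, 1)
  Y <- matrix(rnorm(24 * 3), 24)
  tfr <- make_db_tfr(Y)
  tfr$rejected[c(2, 17)] <- TRUE
  f1 <- suppressWarnings(fit_glm(tfr, X))
  tfr2 <- make_db_tfr(Y[-c(2, 17), , drop = FALSE])
  f2 <- suppressWarnings(fit_glm(tfr2, X[-c(2, 17), ]))
  expect_equal(f1$t, f2$t)
  expect_equal(f1$df, f2$df)
})

test_that("contrasts average the requested regressor maps", {
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), each = 8),
                        camt = rep(c(1, 0), 16), cvmt = rep(c(0, 1), 16))
  X2 <- build_design(trials, 2)
  set.seed(10)
  fit <- suppressWarnings(fit_glm(make_db_tfr(matrix(rnorm(32 * 4), 32)), X2))
  cm <- suppressWarnings(make_contrast(fit, "any-correct"))
  want <- c("ASAcAMT", "VSAcVMT", "DAcAMTandVMT", "ASAcVMT", "VSAcAMT")
  avail <- setdiff(want, fit$dropped)
  idx <- match(avail, fit$regressors)
  expect_equal(as.numeric(cm),
               as.numeric(colMeans(matrix(fit$t[idx, , , ], length(idx)))))
  expect_equal(attr(cm, "constituents"), avail)
  # maps valued 1, 2, 3 at a site average to 2
  fit3 <- fit
  fit3$dropped <- character(0)
  fit3$t[match(c("ASAcAMT", "VSAcVMT", "DAcAMTandVMT"), fit3$regressors),
         1, 1, 1] <- 1:3
  cm3 <- make_contrast(fit3, "attended-correct")
  expect_equal(cm3[1, 1, 1], 2)
  # model 1 cannot provide the any-correct contrast
  X1 <- build_design(trials, 1)
  fit1 <- suppressWarnings(fit_glm(make_db_tfr(matrix(rnorm(32 * 2), 32)),
                                   X1))
  expect_error(make_contrast(fit1, "any-correct"), "lacks")
})

test_that("parameter recovery at 160 trials is unbiased with Student-t errors", {
  set.seed(11)
  trials <- make_trials(rep(c("ASA", "VSA", "DA", "P"), each = 40),
                        camt = rbinom(160, 1, 0.6),
                        cvmt = rbinom(160, 1, 0.6))
  trials$correct_amt[trials$condition == "P"] <- NA
  trials$correct_vmt[trials$condition == "P"] <- NA
  X <- build_design(trials, 1)
  beta <- c(0, 0.5, -0.5, 0.3, 1, -1, 0.7)
  nsite <- 1500
  Y <- as.numeric(X %*% beta) + matrix(rnorm(160 * nsite), 160)
  fit <- suppressWarnings(fit_glm(make_db_tfr(Y), X))
  bhat <- matrix(fit$beta, nrow = 7)
  expect_lt(max(abs(rowMeans(bhat) - beta)), 0.05)
  # null site t-values follow Student t with df = n - p
  Y0 <- matrix(rnorm(160 * nsite), 160)
  f0 <- suppressWarnings(fit_glm(make_db_tfr(Y0), X))
  tnull <- as.numeric(f0$t[2, , , ])
  ks <- suppressWarnings(ks.test(tnull, function(q) pt(q, f0$df)))
  expect_gt(ks$p.value, 0.01)
  crit <- qt(0.975, f0$df)
  frac <- mean(abs(tnull) > crit)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nsite))
})
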