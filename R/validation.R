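# Simulation-based validation suites.  These run the package's own
# machinery on replicated synthetic datasets with known ground truth:
# family-wise error under the null, recovery of the injected effects, and
# statistical power of the behavioral ANOVA.  They back both the test
# suite and scripts/acceptance.R.

# one reduced dataset -> cluster test(s); effects optionally zeroed
run_reduced_replicate <- function(seed, null = FALSE,
                                  contrasts = c("attended-correct"),
                                  n_perm = 200, n_runs = 2) {
  cfg <- default_config(reduced = TRUE)
  cfg$n_runs <- n_runs
  if (null) cfg$effects <- lapply(cfg$effects, function(e) {
    e$db <- 0; e
  })
  analysis <- default_analysis(reduced = TRUE)
  analysis$n_perm <- n_perm
  analysis$contrasts <- lapply(
    stats::setNames(contrasts, contrasts),
    function(cn) if (cn == "attended-correct") 1 else 2)
  run_pipeline(cfg, analysis, seed = seed)
}

#' Family-wise error rate under the null
#'
#' Generates replicate datasets in which both groups share the same
#' generative model (all effect amplitudes zero) at the reduced scale
#' (8 channels, 250 Hz, 6 subjects per group) and runs the full pipeline
#' with the attended-correct contrast.  A false positive is a dataset
#' whose cluster test reports any cluster with `p < alpha`.
#'
#' @param n_datasets number of replicate null datasets (default 100).
#' @param n_perm permutations per test (default 200).
#' @param alpha cluster-level significance criterion (default 0.05).
#' @param n_runs runs per subject in the null datasets (default 1).
#' @param seed integer seed.
#' @return list: `fwer` (fraction of datasets with a false positive),
#'   `n_datasets`, `min_p` per dataset.
#' @export
fwer_simulation <- function(n_datasets = 100, n_perm = 200, alpha = 0.05,
                            n_runs = 1, seed = 1) {
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_datasets)
    min_p <- vapply(seq_len(n_datasets), function(i) {
      res <- run_reduced_replicate(seeds[i], null = TRUE, n_perm = n_perm,
                                   n_runs = n_runs)
      ct <- res$cluster_tests[["attended-correct"]]
      if (nrow(ct$clusters)) min(ct$clusters$p_cluster) else 1
    }, numeric(1))
    list(fwer = mean(min_p < alpha), n_datasets = n_datasets, min_p = min_p)
  })
}

# does any significant cluster of the right sign overlap the effect's
# injected (channel x freq x time) support?
cluster_overlaps_effect <- function(ct, effect, channels, freqs, times,
                                    alpha = 0.05) {
  ch_idx <- match(intersect(effect$channels, channels), channels)
  f_idx <- which(freqs >= effect$band[1] & freqs <= effect$band[2])
  t_idx <- which(times >= effect$window[1] & times <= effect$window[2])
  sig <- which(ct$clusters$p_cluster < alpha &
                 ct$clusters$sign == sign(effect$db))
  for (k in sig) {
    m <- ct$members[[k]]
    hit <- m[, "channel"] %in% ch_idx & m[, "freq"] %in% f_idx &
      m[, "time"] %in% t_idx
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Recovery of the injected ground-truth effects
#'
#' Replicates the reduced-scale experiment with the default injected
#' effects (-2 dB alpha around stimulus onset on attended-correct trials
#' of the trained group; +2 dB theta/alpha at 2.4-2.9 s on any-correct
#' trials) and asks, per replicate, whether each effect is recovered as a
#' significant cluster of the correct sign overlapping its injected
#' channel x band x window support (alpha-onset effect in the
#' attended-correct contrast; late theta/alpha effect in the any-correct
#' contrast).
#'
#' @param n_rep number of replicates (default 50).
#' @param n_perm permutations per test (default 200).
#' @param alpha cluster significance criterion (default 0.05).
#' @param seed integer seed.
#' @return list: `rate_both`, `rate_alpha`, `rate_theta`, and the
#'   per-replicate logical matrix `recovered`.
#' @export
effect_recovery_simulation <- function(n_rep = 50, n_perm = 200,
                                       alpha = 0.05, seed = 1) {
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_rep)
    cfg <- default_config(reduced = TRUE)
    eff_alpha <- cfg$effects[[1]]; eff_theta <- cfg$effects[[2]]
    rec <- matrix(NA, n_rep, 2, dimnames = list(NULL, c("alpha", "theta")))
    for (i in seq_len(n_rep)) {
      res <- run_reduced_replicate(
        seeds[i], null = FALSE,
        contrasts = c("attended-correct", "any-correct"), n_perm = n_perm)
      times <- seq(res$config$epoch_window[1], res$config$epoch_window[2],
                   by = res$analysis$t_step_ms / 1000)
      rec[i, 1] <- cluster_overlaps_effect(
        res$cluster_tests[["attended-correct"]], eff_alpha,
        res$channels, res$freqs_hz, times, alpha)
      rec[i, 2] <- cluster_overlaps_effect(
        res$cluster_tests[["any-correct"]], eff_theta,
        res$channels, res$freqs_hz, times, alpha)
    }
    list(rate_both = mean(rec[, 1] & rec[, 2]),
         rate_alpha = mean(rec[, 1]), rate_theta = mean(rec[, 2]),
         recovered = rec)
  })
}

#' Statistical power of the behavioral ANOVA
#'
#' Simulates cohorts (17 trained / 19 untrained subjects) from the default
#' accuracy model with between-subject heterogeneity, runs the mixed
#' ANOVA, and reports how often each of the three main effects (group,
#' focus, task) reaches `p < alpha`.
#'
#' @param n_rep number of replicates (default 200).
#' @param n_mt,n_nmt group sizes (defaults 17 and 19).
#' @param alpha significance criterion (default 0.05).
#' @param seed integer seed.
#' @return list: `power` (named vector for group/focus/task), `all_three`
#'   (fraction of replicates where all three are significant), `n_rep`.
#' @export
behavioral_power_simulation <- function(n_rep = 200, n_mt = 17, n_nmt = 19,
                                        alpha = 0.05, seed = 1) {
  with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_rep)
    hits <- matrix(NA, n_rep, 3,
                   dimnames = list(NULL, c("group", "focus", "task")))
    for (i in seq_len(n_rep)) {
      tt <- simulate_cohort_behavior(n_mt = n_mt, n_nmt = n_nmt,
                                     seed = seeds[i])
      an <- mixed_anova(aggregate_accuracy(tt))
      p <- an$p[match(c("group", "focus", "task"), an$effect)]
      hits[i, ] <- p < alpha
    }
    list(power = colMeans(hits), all_three = mean(rowSums(hits) == 3),
         n_rep = n_rep)
  })
}

#' Mass-univariate GLM against a direct normal-equations oracle
#'
#' Random small design/response fixtures are fit both by [fit_glm()]'s QR
#' path and by an explicit `(X'X)^-1 X'y` solve with hand-computed t
#' statistics; returns the largest absolute discrepancy.
#'
#' @param n_fixtures number of random fixtures (default 50).
#' @param seed integer seed.
#' @return list: `max_beta_err`, `max_t_err`.
#' @export
glm_oracle_check <- function(n_fixtures = 50, seed = 1) {
  with_seed(seed, {
    max_b <- 0; max_t <- 0
    for (i in seq_len(n_fixtures)) {
      n <- sample(15:40, 1)
      sched <- generate_schedule(1, max(2, ceiling(n / 4)))
      sched <- sched[seq_len(n), ]
      trials <- simulate_behavior(sched, sample(c("MT", "NMT"), 1), 0.6)
      model <- sample(1:2, 1)
      X <- build_design(trials, model)
      nsite <- 7
      Y <- matrix(rnorm(n * nsite), n)
      tfr <- toy_tfr(Y)
      # random fixtures routinely produce empty dummy cells; the drop
      # warnings are part of the scenario being checked
      fit <- suppressWarnings(fit_glm(tfr, X))
      # oracle: explicit normal equations per site, on the same columns
      # the fit retained (empty or unidentifiable ones excluded)
      keep <- !colnames(X) %in% fit$dropped
      Xk <- X[, keep, drop = FALSE]
      XtXi <- solve(crossprod(Xk))
      p <- ncol(Xk)
      for (s in seq_len(nsite)) {
        b <- XtXi %*% crossprod(Xk, Y[, s])
        r <- Y[, s] - Xk %*% b
        s2 <- sum(r^2) / (n - p)
        tv <- b / sqrt(s2 * diag(XtXi))
        bi <- fit$beta[which(keep), , s, 1]
        ti <- fit$t[which(keep), , s, 1]
        max_b <- max(max_b, max(abs(bi - b) / pmax(abs(b), 1)))
        max_t <- max(max_t, max(abs(ti - tv) / pmax(abs(tv), 1)))
      }
    }
    list(max_beta_err = max_b, max_t_err = max_t)
  })
}

# minimal dB-units TFR wrapper around a trials x sites response matrix
# (one channel, `nsite` frequencies, one time point), used by oracles
toy_tfr <- function(Y) {
  n <- nrow(Y); nsite <- ncol(Y)
  pw <- array(Y, c(n, 1, nsite, 1))
  structure(list(power = pw, freqs_hz = seq_len(nsite), time_s = 0,
                 channels = "CZ", units = "dB", n_cycles = 5, fs = 250,
                 edge_mask = matrix(TRUE, nsite, 1),
                 trial_keys = data.frame(run = 1, trial = seq_len(n)),
                 rejected = rep(FALSE, n), baseline = NULL),
            class = "eeg_tfr")
}

#' Rank-sum normal approximation against exhaustive enumeration
#'
#' For every group-size pair with `n, m <= nmax`, draws random data
#' (optionally with ties) and compares the implementation's exact-mode
#' p-value and the normal-approximation p-value against an independent
#' enumeration oracle over all group labelings.
#'
#' @param nmax largest group size (default 6).
#' @param reps random datasets per size pair (default 5).
#' @param ties also include tied data (default TRUE).
#' @param seed integer seed.
#' @return list: `max_exact_err` (implementation exact p vs oracle),
#'   `max_approx_err` (normal p vs oracle), `n_cases`.
#' @export
ranksum_oracle_check <- function(nmax = 6, reps = 5, ties = TRUE, seed = 1) {
  with_seed(seed, {
    max_exact <- 0; max_approx <- 0; cases <- 0
    for (n in 2:nmax) for (m in n:nmax) for (r in seq_len(reps)) {
      x <- if (ties && r %% 2 == 0) sample(1:4, n + m, TRUE)
           else rnorm(n + m)
      a <- x[seq_len(n)]; b <- x[n + seq_len(m)]
      impl <- ranksum_z(a, b, exact = TRUE)
      approx <- ranksum_z(a, b)
      # independent oracle: enumerate labelings, two-sided tail of U
      rk <- rank(x)
      combs <- combn(n + m, n)
      mu <- n * m / 2
      us <- apply(combs, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
      u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
      p_oracle <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
      max_exact <- max(max_exact, abs(impl$p - p_oracle))
      max_approx <- max(max_approx, abs(approx$p - p_oracle))
      cases <- cases + 1
    }
    list(max_exact_err = max_exact, max_approx_err = max_approx,
         n_cases = cases)
  })
}

#' Toy cluster-permutation test against the exhaustive-labeling answer
#'
#' A 3-vs-3 subject, 1-channel, 4 x 4 frequency-time grid with a strong
#' group difference in one corner block.  The Monte-Carlo cluster p-value
#' is compared with the exact p obtained by enumerating all 20 labelings.
#'
#' @param n_perm Monte-Carlo permutations (default 1000).
#' @param seed integer seed.
#' @return list: `p_mc`, `p_exact`, `abs_err`, `binom_tol`
#'   (`2 * sqrt(p(1-p)/n_perm)`).
#' @export
cluster_toy_check <- function(n_perm = 1000, seed = 1) {
  with_seed(seed, {
    n_subj <- 6
    X <- array(rnorm(n_subj * 1 * 4 * 4, sd = 0.5), c(n_subj, 1, 4, 4))
    X[1:3, 1, 1:2, 1:2] <- X[1:3, 1, 1:2, 1:2] + 10
    labels <- rep(c("A", "B"), each = 3)
    res <- permutation_test(X, labels, n_perm = n_perm, alpha_ctd = 0.05,
                            neighbors = NULL, channels = "CZ")
    obs_mass <- abs(res$clusters$mass[1])
    # exhaustive oracle: recompute max |mass| under all 20 labelings using
    # the same building blocks
    combs <- combn(6, 3)
    exact_max <- apply(combs, 2, function(idx) {
      lab <- rep("B", 6); lab[idx] <- "A"
      r <- permutation_test(X, factor(lab, levels = c("A", "B")),
                            n_perm = 1, alpha_ctd = 0.05,
                            neighbors = NULL, channels = "CZ")
      if (nrow(r$clusters)) max(abs(r$clusters$mass)) else 0
    })
    p_exact <- mean(exact_max >= obs_mass)
    p_mc <- res$clusters$p_cluster[1]
    tol <- 2 * sqrt(p_exact * (1 - p_exact) / n_perm) + 1 / n_perm
    list(p_mc = p_mc, p_exact = p_exact, abs_err = abs(p_mc - p_exact),
         binom_tol = tol)
  })
}
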