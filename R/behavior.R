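# Behavioral analysis: accuracy aggregation into the group x attention
# focus x retrieval task design, the 2 x 2 x 2 mixed ANOVA (Type-III sums
# of squares, Greenhouse-Geisser correction, generalized eta squared), and
# Bonferroni-corrected pairwise t-tests.

#' Aggregate trial-level correctness into the focus x task design
#'
#' Responses are pooled by whether attention was directed at the retrieved
#' modality: for the auditory task, ASA and DA trials are "focus" and VSA
#' trials "non-focus" (symmetrically for the visual task; DA counts as
#' focus for both).  Passive trials are excluded.  `score` rescales the
#' proportion to a correct count per 20 trials, the scale on which group
#' summaries are reported.
#'
#' @param trial_table a `trial_table`.
#' @return data.frame of class `accuracy_table`: `subject`, `group`,
#'   `focus`, `task`, `n_correct`, `n_trials`, `proportion`, `score`.
#' @export
aggregate_accuracy <- function(trial_table) {
  tt <- trial_table[trial_table$condition != "P", , drop = FALSE]
  if (!nrow(tt)) {
    warning("trial table contains only passive trials; empty accuracy table")
    out <- data.frame(subject = character(0), group = character(0),
                      focus = character(0), task = character(0),
                      n_correct = integer(0), n_trials = integer(0),
                      proportion = numeric(0), score = numeric(0))
    class(out) <- c("accuracy_table", "data.frame")
    return(out)
  }
  long <- rbind(
    data.frame(subject = tt$subject, group = tt$group,
               task = "AMT", focus = task_focus(tt$condition, "AMT"),
               correct = tt$correct_amt, stringsAsFactors = FALSE),
    data.frame(subject = tt$subject, group = tt$group,
               task = "VMT", focus = task_focus(tt$condition, "VMT"),
               correct = tt$correct_vmt, stringsAsFactors = FALSE))
  long <- long[!is.na(long$correct), ]
  agg <- aggregate(correct ~ subject + group + focus + task, long,
                   function(x) c(sum(x), length(x)))
  out <- data.frame(subject = agg$subject, group = agg$group,
                    focus = agg$focus, task = agg$task,
                    n_correct = agg$correct[, 1],
                    n_trials = agg$correct[, 2])
  out$proportion <- out$n_correct / out$n_trials
  out$score <- out$proportion * 20
  out <- out[order(out$subject, out$focus, out$task), ]
  rownames(out) <- NULL
  class(out) <- c("accuracy_table", "data.frame")
  out
}

acc_wide <- function(acc, value = "score") {
  cells <- c("focus.AMT", "focus.VMT", "nonfocus.AMT", "nonfocus.VMT")
  subj <- unique(acc$subject)
  w <- matrix(NA_real_, length(subj), 4,
              dimnames = list(subj, cells))
  w[cbind(match(acc$subject, subj),
          match(paste(acc$focus, acc$task, sep = "."), cells))] <-
    acc[[value]]
  grp <- acc$group[match(subj, acc$subject)]
  incomplete <- rownames(w)[!complete.cases(w)]
  list(w = w, group = grp, incomplete = incomplete)
}

#' 2 x 2 x 2 mixed ANOVA on accuracy
#'
#' Between-subject factor group (MT/NMT), within-subject factors attention
#' focus (focus/non-focus) and retrieval task (AMT/VMT).  Type-III sums of
#' squares via [car::Anova()] on the multivariate linear model;
#' Greenhouse-Geisser epsilon is reported (identically 1 for two-level
#' within factors); generalized eta squared is
#' `SS_effect / (SS_effect + sum of all error SS)`.
#'
#' @param acc an `accuracy_table`; subjects with missing cells are dropped
#'   with a warning.
#' @param value response column (default `"score"`, correct count per 20).
#' @return data.frame of class `anova_table`: `effect`, `F`, `df1`, `df2`,
#'   `MSE`, `p`, `ges`, `gg_epsilon`, `p_gg`.
#' @export
mixed_anova <- function(acc, value = "score") {
  aw <- acc_wide(acc, value)
  if (length(aw$incomplete)) {
    warning("dropping subject(s) with missing cells: ",
            paste(aw$incomplete, collapse = ", "))
    keep <- !rownames(aw$w) %in% aw$incomplete
    aw$w <- aw$w[keep, , drop = FALSE]
    aw$group <- aw$group[keep]
  }
  if (length(unique(aw$group)) < 2 || min(table(aw$group)) < 2)
    stop("need two groups with at least 2 complete subjects each")
  group <- factor(aw$group)
  idata <- data.frame(
    focus = factor(rep(c("focus", "nonfocus"), each = 2)),
    task = factor(rep(c("AMT", "VMT"), 2)))
  # sum-to-zero coding so Type-III tests are the unweighted-means tests
  mod <- stats::lm(aw$w ~ group, contrasts = list(group = "contr.sum"))
  av <- car::Anova(mod, idata = idata, idesign = ~ focus * task, type = 3)
  s <- summary(av, multivariate = FALSE)
  ut <- s$univariate.tests
  effects <- c(group = "group", focus = "focus", task = "task",
               `group:focus` = "group:focus", `group:task` = "group:task",
               `focus:task` = "focus:task",
               `group:focus:task` = "group:focus:task")
  rows <- match(effects, rownames(ut))
  # unique error strata: between-subject + one per within combination
  err_rows <- match(c("group", "focus", "task", "focus:task"), rownames(ut))
  ss_err_total <- sum(ut[err_rows, "Error SS"])
  out <- data.frame(
    effect = names(effects),
    F = ut[rows, "F value"],
    df1 = ut[rows, "num Df"],
    df2 = ut[rows, "den Df"],
    MSE = ut[rows, "Error SS"] / ut[rows, "den Df"],
    p = ut[rows, "Pr(>F)"],
    ges = ut[rows, "Sum Sq"] / (ut[rows, "Sum Sq"] + ss_err_total),
    gg_epsilon = 1, p_gg = NA_real_, stringsAsFactors = FALSE)
  # GG corrections exist only for >2-level within factors; with 2-level
  # factors sphericity is trivially satisfied and epsilon = 1
  pa <- s$pval.adjustments
  if (!is.null(pa) && nrow(pa)) {
    ok <- is.finite(pa[, "GG eps"]) & rownames(pa) %in% out$effect
    if (any(ok)) {
      i <- match(rownames(pa)[ok], out$effect)
      out$gg_epsilon[i] <- pa[ok, "GG eps"]
      out$p_gg[i] <- pa[ok, "Pr(>F[GG])"]
    }
  }
  out$p_gg[is.na(out$p_gg)] <- out$p
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pairwise follow-up t-tests with Bonferroni correction
#'
#' Within-subject comparisons (focus vs non-focus within each task, AMT vs
#' VMT within each focus level) are paired t-tests; the group comparison
#' within each cell is a two-sample t-test.  Adjusted p is
#' `min(1, m * p)` over the family.
#'
#' @param acc an `accuracy_table`.
#' @param value response column.
#' @return data.frame: `comparison`, `type`, `estimate`, `t`, `df`, `p`,
#'   `p_bonferroni`.
#' @export
pairwise_tests <- function(acc, value = "score") {
  aw <- acc_wide(acc, value)
  keep <- complete.cases(aw$w)
  w <- aw$w[keep, , drop = FALSE]; grp <- aw$group[keep]
  if (nrow(w) < 2) stop("need at least 2 complete subjects")
  res <- list()
  paired_cmp <- list(
    `focus vs nonfocus | AMT` = c("focus.AMT", "nonfocus.AMT"),
    `focus vs nonfocus | VMT` = c("focus.VMT", "nonfocus.VMT"),
    `VMT vs AMT | focus` = c("focus.VMT", "focus.AMT"),
    `VMT vs AMT | nonfocus` = c("nonfocus.VMT", "nonfocus.AMT"))
  for (nm in names(paired_cmp)) {
    a <- w[, paired_cmp[[nm]][1]]; b <- w[, paired_cmp[[nm]][2]]
    dif <- a - b
    if (sd(dif) == 0) {
      res[[nm]] <- data.frame(comparison = nm, type = "paired",
                              estimate = mean(dif), t = 0,
                              df = length(dif) - 1, p = 1)
      next
    }
    tt <- t.test(a, b, paired = TRUE)
    res[[nm]] <- data.frame(comparison = nm, type = "paired",
                            estimate = unname(tt$estimate),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value)
  }
  for (cell in colnames(w)) {
    a <- w[grp == unique(grp)[1], cell]; b <- w[grp != unique(grp)[1], cell]
    if (length(a) < 2 || length(b) < 2) stop("need >= 2 subjects per group")
    nm <- paste0("MT vs NMT | ", cell)
    if (sd(a) == 0 && sd(b) == 0) {
      res[[nm]] <- data.frame(comparison = nm, type = "two-sample",
                              estimate = mean(a) - mean(b), t = 0,
                              df = length(a) + length(b) - 2, p = 1)
      next
    }
    tt <- t.test(a, b)
    res[[nm]] <- data.frame(comparison = nm, type = "two-sample",
                            estimate = unname(diff(rev(tt$estimate))),
                            t = unname(tt$statistic),
                            df = unname(tt$parameter), p = tt$p.value)
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
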