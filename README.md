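# oscidiff

Oscillatory correlates of bimodal attention and working memory: a
simulation and group-difference analysis pipeline for EEG.

## What this package is for

A recurring question in developmental cognitive neuroscience is whether
training (here: musical training in children) changes the neural
oscillations that support attention and working memory. The
experimental design this package models presents a 4 s melody and an
abstract figure simultaneously under four attention conditions —
auditory selective (ASA), visual selective (VSA), divided (DA), and
passive (P) — followed by same/different retrieval probes for each
modality (auditory/visual memory task, AMT/VMT). The analysis asks
where in (sensor × frequency × time) space the oscillatory power that
precedes *correct* retrieval differs between a trained and an untrained
group.

Because no raw data are publicly deposited for such studies, the package
pairs the full analysis chain with a synthetic-data generator that
emulates the experiment with known ground truth, so every statistical
claim of the pipeline is testable against effects it injected itself.
It is aimed at EEG methodologists and students who want a compact,
fully tested reference implementation of this family of analyses.

## The statistics at its core

1. **First level (within subject).** Single-trial power from a 5-cycle
   Morlet transform (1–45 Hz, 5 ms grid), in dB relative to the passive
   pre-stimulus baseline, is modeled at every site by OLS:

   Model 1:
   `Power(f,t) = b1 + b2*ASA + b3*VSA + b4*DA + b5*ASAcAMT + b6*VSAcVMT + b7*DAcAMTandVMT`

   Model 2 adds `b8*ASAcVMT + b9*VSAcAMT`, where e.g. `ASAcAMT` flags
   ASA trials whose auditory probe was later answered correctly. The
   per-subject summary is the mean t-map of the correctness regressors:
   `attended-correct` (b5–b7, Model 1) or `any-correct` (b5–b9,
   Model 2).

2. **Second level (between groups).** A Wilcoxon rank-sum Z at every
   site, thresholded at uncorrected p < .05, clustered over neighboring
   sites (4-connectivity in each sensor's frequency × time chart plus
   cross-sensor links), with cluster mass = summed Z and family-wise
   error controlled by the permutation distribution of the maximum
   |mass| over 1000 group-label permutations.

3. **Behavior.** Correct counts per 20 trials in a 2 (group) × 2
   (attention focus) × 2 (task) mixed ANOVA, Type-III sums of squares,
   generalized eta squared, Greenhouse–Geisser correction, and
   Bonferroni-adjusted pairwise follow-ups.

The methods vignette (`vignettes/methods.Rmd`) documents every model,
default, and design decision.

## Worked example

Simulate the reduced desk-scale experiment (8 channels, 250 Hz, 6
subjects per group, both ground-truth effects carried by the trained
group) and run the whole chain:

```r
library(oscidiff)
cfg <- default_config(reduced = TRUE)
res <- run_pipeline(cfg, seed = 42)
print(res)
#> <pipeline_result>
#>   subjects: 12
#>   attended-correct: 140 cluster(s), 0 with p < .05
#>   any-correct: 126 cluster(s), 1 with p < .05

head(res$cluster_tests[["any-correct"]]$clusters, 3)
#>   cluster sign  mass n_sites p_cluster
#> 1       1    1 166.5      69     0.010
#> 2       2    1  48.8      19     0.490
#> 3       3    1  40.7      17     0.645

an <- res$behavior$anova
an[an$effect %in% c("group", "focus", "task"),
   c("effect", "F", "df1", "df2", "p", "ges")]
#>   effect      F df1 df2        p    ges
#> 1  group  0.956   1  10 0.351318 0.0567
#> 2  focus 21.716   1  10 0.000894 0.2119
#> 3   task 25.600   1  10 0.000492 0.3154
```

Reading the output: the injected +2 dB theta/alpha increase late in the
encoding phase (2.4–2.9 s, trained group, trials followed by correct
retrieval) surfaces as the positive cluster with mass 166.5 and
permutation p = .01 in the `any-correct` contrast, and the within-
subject behavioral effects (focus, task) are clearly significant. At
only six subjects per group the between-group behavioral effect and the
subtler −2 dB alpha modulation around stimulus onset are not reliably
detectable — the methods vignette quantifies this; at the study's group
sizes (17/19) both are.

`run_pipeline(..., out_dir = "out")` additionally writes the trial
table, ANOVA/pairwise CSVs, cluster JSONs, a run manifest, and a
markdown/HTML report. A thin command-line front end over the same
functions lives at `inst/cli/oscidiff.R`
(`simulate-task`, `simulate-eeg`, `behavior`, `run-all`).

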