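# balanceN1

Detecting the cortical signature of naturally occurring postural
instabilities — and predicting it from biomechanics alone.

## The problem

During quiet or perturbed standing, the brain does not wait passively for a
fall: a low-amplitude fronto-central negative EEG potential (the **N1**)
appears 100–250 ms *before* the early biomechanical sign of a corrective
balance response. That early sign is a zero-crossing of the
anterior–posterior center-of-pressure velocity (COPv) following a
large-amplitude COPv excursion. `balanceN1` implements the full analysis
chain for continuous standing-balance experiments with a sway-referenced
support surface (nine 20 s trials, gain order 0, 0.4, 2.0, 0, 0.6, −0.4, 0,
1.0, −1.0):

1. **Biomechanics** — COPv by three-point central difference (no time
   delay); distance to the stability boundary in the direction of motion
   (DTB); time to boundary (TTB = DTB/|COPv|, floored and capped);
   instability events as |COPv| peaks above a subject-specific threshold
   (3 SD of quiet-stance COPv, typically ≈ 6 cm/s) followed by the next
   COPv sign change.
2. **N1 detection** — baseline-correct the cleaned fronto-central
   independent component against its −5..0 s pre-task mean; per event, take
   the deepest local trough at least 2 baseline-SD below baseline within
   −250..−100 ms before the zero-crossing; harvest all other ≥ 2 SD troughs
   as control epochs; clip −300..+100 ms multichannel epochs.
3. **Epoch features** — per epoch, the median of |COPv|, |shear force|,
   |head acceleration| and |TTB| over −300..−50 ms before the center, plus
   Cohen's *d* class contrasts, a Shapiro–Wilk normality screen and the
   six pairwise Pearson correlations (|r| ≥ 0.7 flagged).
4. **Classification** — leave-one-subject-out evaluation of gradient-boosted
   tree ensembles (XGBoost, binary logistic): balanced test set from the
   left-out subject, balanced training pool by undersampling, inner
   stratified 5-fold grid search (depths 2–10, 60–220 rounds, learning rate
   0.001/0.01/0.1), ten repeats per subject; accuracy, sensitivity and
   rank-based AUC; Shapley-value feature importance (exact TreeSHAP, plus
   the package's own double-precision subset-enumeration Shapley values).
5. **Synthetic cohort** — a seeded generator that emulates the task
   (bounded mean-reverting sway whose slow component scales with |gain|,
   lean-triggered instability excursions, N1 troughs injected 100–250 ms
   before each corrective zero-crossing into a 1/f IC trace, distractor
   troughs, coupled shear/head-acceleration channels), so the whole
   pipeline is testable end to end without human data.

## Worked example

```r
library(balanceN1)

cfg <- pipeline_config(master_seed = 42, repeats = 2,
                       feature_sets = c("ttb", "all4"))
res <- run_pipeline(cfg)
print(res)
res$latency_summary
res$contrast[, c("feature", "mean_instability", "mean_control", "cohens_d")]
subset(res$comparison$summary, metric == "accuracy")
res$importance
```

prints (exactly reproducible with this seed):

```
<pipeline_result> seed 42: 883 epochs (297 N1, 586 control), 40 LOSO runs
N1 latency: 170.1 +/- 1.5 ms (mean +/- SE)
  feature mean_instability mean_control cohens_d   p_value
1    COPv            5.954        2.131    1.782  2.37e-94
2      SH            4.521        2.345    1.286  5.06e-51
3      HA            0.393        0.249    0.882  8.70e-27
4     TTB            1.856        7.132   -2.120 5.41e-185
  feature_set   metric  mean     se n_runs
1         ttb accuracy 0.882 0.0129     20
4        all4 accuracy 0.900 0.0131     20
       feature mean_abs_shap direction
1  med_abs_ttb         1.527        -1
2 med_abs_copv         0.866         1
3   med_abs_sh         0.551         1
4   med_abs_ha         0.186         1
```

Reading: the synthetic cohort yields 297 instability and 586 control epochs
(≈ 1:2, 33.6% instability). Detected N1 troughs lead the corrective
zero-crossing by 170 ms on average. COPv, shear and TTB separate the
classes with |d| > 1 (TTB's contrast is negative: *lower* time-to-boundary
predicts instability). The combined four-parameter model beats the best
single feature, and TTB dominates the model's Shapley attribution, with
higher COPv/SH/HA and lower TTB pushing predictions toward the instability
class.

The `simulate → detect → epochs → features → classify → report` chain is
also scriptable: `inst/scripts/run_pipeline.R all --seed 42 --out out/`
writes `runs.csv`, `features.csv`, per-subject event tables,
`comparison.json`, `importance.json` and a Markdown report.

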