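---
title: "Methods: deriving and applying a morphological resistance signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and applying a morphological resistance signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphsig)
```

This vignette documents the statistical model behind `morphsig`, the meaning
and rationale of every default parameter, what the synthetic profile generator
does and does not capture, and the numerical choices that make the results
exactly reproducible.

# 1. The problem

Image-based morphological profiling (Cell Painting) measures hundreds of
texture, intensity, shape and radial-distribution features per cell, median-
aggregated to one profile per well. Drug-resistant clones exhibit a consistent
shift in a subset of features. The task is to find that subset — a *signature*
— while rejecting features whose variation is really driven by technical
covariates (staining batch, incubation time, well cell density) or by the
idiosyncrasies of individual clones, and then to score new wells against the
signature with a classifier that needs no refitting.

# 2. Profile processing

`aggregate_to_wells()` takes per-object (cell) measurements to per-well
**medians** — robust to segmentation outliers, and the standard choice for
well-level profiling. `annotate()` joins the plate map (clone, batch,
incubation time, cell count, resistance label) by plate and well; it refuses
duplicate plate map keys and unmatched wells rather than guessing.

`normalize_zscore()` centers and scales each feature, either globally or per
group (`group_by = "Metadata_Plate"` for per-plate normalization). Constant
features are set to 0 with a warning instead of producing `NaN`. Ranks inside
the final score are computed *within* a profile, so normalization mainly
matters for making features comparable across the panel; for classification
by the sign of the score it also centers each feature's null at 0.

`select_features()` applies the standard profiling quality filters in a fixed,
reported order:

1. `missing` — any `NA`;
2. `low_variance` — variance below `1e-12`, or the frequency ratio of the two
   most common values below `freq_cut = 0.05` (near-constant discretized
   features);
3. `blocklist` — user-supplied names (known-artifact features);
4. `correlation` — one member of every pair with |Pearson r| >
   `corr_threshold = 0.9`. The victim is chosen deterministically: the member
   with the larger mean absolute correlation to all remaining features, ties
   broken by the lexicographically larger name. This makes selection invariant
   to row and column order, which is asserted by tests.
5. `outlier` — any observation more than `outlier_sd = 15` standard deviations
   from the feature mean. Note a structural fact: with one extreme point among
   $n$ values the deviation/SD ratio cannot exceed $\sqrt{n-1}$, so this rule
   only becomes active for datasets with a few hundred wells or more. That is
   intentional — it targets gross single-well artifacts at dataset scale, not
   small-study variation.

Every feature gets exactly one row in the selection report (`kept`,
`removal_rule`, `detail`), mirroring the feature-count narrative that the
pipeline logs after each filter.

# 3. Per-feature covariate models

For each feature $y$ (on the normalized scale), two ordinary least squares
models are fit (`fit_covariate_models()`, `fit_cellcount_models()`):

$$ y = \beta_0 + \beta_r\,\text{resistance} + \beta_b\,\text{batch}
     + \beta_t\,\text{time} + \beta_c\,\text{clone} + \varepsilon $$
$$ y = \beta_0 + \beta_r\,\text{resistance} + \beta_n\,\text{cell count}
     + \varepsilon $$

Clones are *nested* in resistance class, so naive dummy coding of clone makes
the resistance indicator unidentifiable. `morphsig` uses sum-to-zero
(deviation) coding for clone **within each class**: clone columns capture
departures of each clone from its class mean, leaving the class contrast to
the resistance column. The design matrix is checked for full rank via QR.

Post-hoc pairwise comparisons use the **Tukey–Kramer** honestly-significant-
difference test (`tukey_hsd()`):

$$ q_{ij} = \frac{|\bar y_i - \bar y_j|}
                 {\sqrt{\tfrac{\mathrm{MSW}}{2}\left(\tfrac1{n_i}+\tfrac1{n_j}\right)}},
   \qquad p_{ij} = P\!\left(Q_{k,\,N-k} > q_{ij}\right) $$

evaluated with `stats::ptukey`. The test suite validates `ptukey` itself
against an independent double numerical integration of the studentized-range
density (agreement ~1e-13) and the whole table against `TukeyHSD(aov(...))`.
Degenerate groups (MSW = 0) give $p = 1$ for zero differences and $p = 0$
otherwise.

One design decision worth making explicit: resistance,
batch and time comparisons are one-way Tukey tests on the **feature values**,
while clone comparisons run on the **residuals after removing batch and time
effects**. A raw-value clone comparison would re-detect the resistance shift
in every cross-class pair and inflate the within-group variance for the
same-class pairs the exclusion rule actually uses.

All 782 features share one `lm.fit` factorization and vectorized group sums,
so the full default design fits in seconds; the dominant cost is the ~35,000
`ptukey` evaluations.

# 4. Signature derivation

`build_signature()` keeps feature $j$ iff, at the Bonferroni threshold
$t = \alpha/m$ (default $\alpha = 0.05$; $m$ = number of modelled features,
so 782 features give $t = 6.39\times10^{-5}$):

* the resistance comparison has $p < t$ (`not_significant` otherwise);
* **no** batch pair has $p < t$ (`batch`);
* **no** incubation-time pair has $p < t$ (`incubation_time`);
* the cell-count slope has $p \ge t$ (`cell_count`);
* fewer than `min_clone_pairs = 2` sensitive–sensitive clone pairs have
  $p < t$ (`clone_pairs`) — a feature that separates sensitive clones from
  each other tracks clonal identity, not resistance.

The direction is the sign of $\beta_r$ (resistant coded 1): positive → up
set, negative → down set. Every feature receives a ledger row listing *all*
failed rules (none of the rules short-circuits), which is what makes the
decoy-attribution tests possible.

# 5. Scoring: bidirectional mid-rank singscore

`singscore()` ranks the signature features **within one profile** (mid-ranks
for ties, $N = n_{up} + n_{down}$), computes the mean rank of the up set,
min–max normalizes it to $[0,1]$ and shifts by $-0.5$; the down set does the
same on reversed ranks ($N + 1 - r$). The total score is the sum, bounded in
$[-1, 1]$:

* $+1$ exactly when every up feature outranks every down feature;
* $-1$ exactly for the reverse;
* invariant under any strictly monotone transform of the profile (only ranks
  enter), asserted by tests along with antisymmetry and monotonicity.

Because the score is self-contained per profile, it transfers across datasets
without refitting — the property that lets a signature derived on one assay
classify clones in another.

`permutation_null()` shuffles the observed values across the signature
features *within each profile* (default 1000 permutations), pools all permuted
scores and reports the 2.5/97.5 percentiles. `classify_clones()` calls a clone
resistant when its **median** well score is positive, and high-confidence when
the median falls outside the null interval. The within-profile shuffle
preserves each profile's value distribution exactly and needs no
distributional assumptions; its null is centred at 0 by the symmetry of the
rank statistic.

# 6. Evaluation

* `accuracy()` — exact fraction; at the well level the predicted label is the
  sign of the score, clone-level accuracy uses clone medians.
* `average_precision()` — step-interpolated AP over descending unique score
  thresholds (the hand-checkable case `scores = {0.9, 0.8, 0.3, 0.2}`,
  `labels = {1,0,1,0}` gives exactly 5/6).
* `roc_auroc()` — staircase ROC over `c(Inf, unique scores)` with trapezoidal
  area; ties produce diagonal segments, making AUROC identical to the
  Mann–Whitney pair-counting statistic (asserted to 1e-12). The reported
  operating point is the finite threshold closest to 0, matching the sign
  rule.
* `shuffled_baseline()` — permutes resistance labels at the **clone** level
  (all wells of a clone move together), preserving class counts and replicate
  correlation. Shuffling wells instead would leak clone identity and bias the
  baseline optimistic.
* `ks_misclassification()` — per signature feature, two-sample
  Kolmogorov–Smirnov tests comparing misclassified vs high-confidence-correct
  wells within each true class; empty groups are skipped with a record, and a
  Bonferroni column is provided although the p-values are descriptive
  diagnostics.
* `compare_feature_spaces()` — PCA (≤30 components) → k-means
  (`nstart = 25`, k = 2…14) → per-cluster Fisher tests of resistance
  enrichment with Haldane-corrected odds ratios, plus mean silhouette widths;
  used to show the signature space separates classes better than the full or
  a size-matched random feature space.

# 7. The synthetic generator

`simulation_design()` / `simulate_profiles()` produce well-level profiles with
planted, machine-readable ground truth. Defaults: 5 sensitive + 5 resistant
clones × 3 batches (one 96-well plate each, serpentine layout) × 2 incubation
arms × 4 replicate wells = 240 wells; 782 features.

Features are generated **directly on the normalized scale** — each is latent
factor + Gaussian noise with marginal SD `noise_sd = 1` — so every effect size
is in units of residual SD:

* 14 up / 31 down **signal** features: ±`effect_resistance = 1` SD in
  resistant wells. 1 SD is deliberately modest: per-feature *t* ≈ 7–8 at 120
  wells/class, comfortably past the Bonferroni cut but far from trivial.
* 20 **batch decoys**: per-step shift `effect_batch = 1` (batch index centred,
  so 3 batches span 2 SD).
* 20 **time decoys**: analogous for the incubation arms.
* 20 **cell-count decoys**: `cellcount_slope = 0.005` SD/cell on counts drawn
  from a truncated Gaussian (mean 1500, SD 200) — a 1-SD count excursion moves
  the feature by 1 SD.
* 20 **clone decoys**: `effect_clone = 2` SD added to half of the sensitive
  clones (chosen per feature). The default is 2, not 1, by power analysis:
  the clone-pair exclusion needs Tukey-adjusted $p < 6.4\times10^{-5}$ on
  same-class pairs, which at 24 wells/clone requires a studentized range
  $q \gtrsim 7$; a 1-SD shift gives adjusted $p \approx 0.02$ and an
  undetectable decoy, a 2-SD shift gives $q \approx 9.8$.
* Remaining null features are organised into latent-factor **correlation
  blocks** (default 10 blocks of 10, within-block $\rho = 0.6$) via
  $\sqrt{\rho}\,f + \sqrt{1-\rho}\,\epsilon$, mimicking the redundancy of
  texture features that makes the correlation filter meaningful.

Reproducibility: all randomness flows from one design seed through a
documented stream derivation (`derive_seed(seed, stream_name)` — a salted
Lehmer-style hash), so platemap, role assignment and noise are independently
reproducible, and re-running any pipeline stage from its on-disk inputs gives
bit-identical outputs.

**Realism limits.** The generator plants *constant mean shifts*; real
morphological effects are heteroscedastic, feature-correlated with the signal,
and batch effects also scale variances. Plate and batch coincide (one plate
per batch), so per-plate normalization would absorb the planted batch shifts
entirely — which is why the pipeline default is global normalization
(`normalize_by = "all"`) for synthetic runs, with `"plate"` available for real
data where plates subdivide batches. Cell counts are independent of
resistance, whereas real resistant clones often grow at different rates. No
spatial plate effects (edge wells, gradients) are modelled, although the
serpentine layout is in place to dilute them if added.

# 8. Numerical choices

* Exact rank arithmetic: mid-ranks via `rank(ties.method = "average")`; score
  bounds hit ±1 exactly (tested to 1e-12).
* OLS via `lm.fit` (QR); a rank check rejects confounded designs rather than
  silently dropping columns. Cell-count standard errors via
  `chol2inv(chol(X'X))`.
* `ptukey`/`qtukey` from base R, independently validated (see §3).
* Fisher tests via `stats::fisher.test`; odds ratios reported with the
  Haldane 0.5 correction so perfectly separated clusters give a large finite
  value instead of infinity.
* Percentile confidence intervals use `quantile` type 7 (R default)
  consistently.
* All artifacts are plain text (CSV/JSON/YAML); JSON numbers are written with
  `digits = NA` (full precision), enabling checksum-level reproducibility of
  manifest-listed outputs.

# 9. Limitations

* The covariate model is linear with homoscedastic errors; strongly skewed
  features would be better served by rank-based or robust models.
* Bonferroni is deliberately conservative; with many correlated features it
  is far from the false-discovery frontier.
* The clone-pair exclusion only inspects *sensitive* clone pairs by default
  (`clone_pair_classes = "sensitive"`), since resistant clones are expected to
  shift jointly; features tracking a single resistant clone are instead
  penalized through the within-class variance.
* The permutation null treats the signature features of a profile as
  exchangeable under the null; strong within-signature correlation makes the
  interval conservative.
* Synthetic validation demonstrates *correctness of the machinery*, not
  biological performance; the headline numbers of any real study require the
  corresponding real profiles, which this package only ingests.
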