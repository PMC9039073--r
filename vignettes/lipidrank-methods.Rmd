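---
title: "Methods: hierarchical random-forest discovery of discriminative lipids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical random-forest discovery of discriminative lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lipidrank implements a complete case-control lipidomics discovery workflow:
internal-standard normalization, Monte Carlo cross-validated random-forest
(RF) classification and variable-importance ranking, a hierarchical
class-to-species feature selection, and a statistical validation battery.
The motivating application is serum lipidomics of monogenic Parkinson's
disease — discriminating symptomatic SNCA A53T mutation carriers (cases)
from healthy controls on a panel of 530 lipid species grouped into 34 lipid
classes, with 22 cases and 30 controls. Because cohorts of this kind are
small, rare, and rarely deposited, the package ships a synthetic cohort
generator with known ground truth; every stage of the pipeline is exercised
and tested against that generator.

```{r setup, message = FALSE}
library(lipidrank)
```

## Data model

Three tables describe a study:

* an **abundance table** — wide, one row per subject, one numeric column
  per lipid species (or class) on the linear concentration scale; missing
  cells mean "not detected". Units are arbitrary normalized concentration
  units: only relative comparisons between groups are interpreted.
* a **taxonomy** — two columns, `species_id` and `class_id`. Species names
  use the dotted dialect common in shotgun lipidomics (`PC.38.5` for
  PC 38:5), but are treated as opaque identifiers; class membership always
  comes from the taxonomy.
* **subject metadata** — `group` (`case`/`control`), `age` in years, `sex`.

`build_feature_table()` joins these into the modelling design: the binary
outcome, the lipid features, and two covariates — age untransformed and sex
as a female indicator (female = 1, male = 0; the choice is arbitrary but is
stated here and in the direction reports because it fixes the sign of the
sex coefficient). At class level on the default panel the design has 36
variables: 34 classes plus age and sex. The covariates ride along in every
classifier fit so that their (usually low) importance is measured rather
than assumed.

### Class aggregation

The class-level concentration of a subject is the **sum** of the subject's
non-missing member-species concentrations. The literature reports class
concentrations without defining them; summation is the standard lipidomics
convention, and it preserves a useful conservation invariant (per subject,
the class totals and the species totals agree when nothing is dropped),
which the test suite checks. A class value is missing only when every
member species is missing.

### Missing measurements

Species below the detection limit are common in small-cohort LC-MS data.
`handle_missing()` applies the conventional two-step policy: features
missing in more than `drop_frac` of subjects (default 20%) are removed;
remaining gaps are imputed at half the feature's observed minimum — the
usual surrogate for a value known only to lie below the detection limit.
Both knobs are explicit, and `impute = "none"` keeps gaps as `NA` for
workflows that prefer complete-case statistics.

## NOMIS normalization

Raw LC-MS peak intensities carry per-run technical variation (injection
volume, ionization efficiency, instrument drift). The package implements
normalization against multiple spiked internal standards (IS) with optimal
subset selection: on the natural-log scale, each feature is regressed on
the centered log-intensities of a candidate IS subset, and the subset is
scored by the mean leave-one-out squared prediction residual (PRESS/n)
across all features. Every subset up to `max_subset` (default 5) is
scored exhaustively, including the **empty subset**, i.e. no correction.

Selection uses a one-standard-error parsimony rule: among subsets whose
criterion lies within one standard error of the minimum (the SE taken
across the per-feature PRESS values of the best subset), the smallest
subset wins. This matters in the null case — when the standards track no
real technical variation, plain argmin selection can pick a spurious
standard whose noisy coefficients then *add* variation to held-out data;
under the 1-SE rule the no-correction model wins instead, so the method
degrades to the identity on clean data. On drifting data the drift term
dominates the criterion by far and the rule never blocks a real correction;
the acceptance suite checks both behaviors (identity on drift-free
fixtures; per-feature variance strictly reduced for ≥95% of drifting
features, in practice 100%).

`apply_nomis()` subtracts the fitted IS component on the log scale and
returns linear-scale concentrations. The user-facing tables are always
linear-scale; all fitting is done on natural logs internally. The full
audit table of candidate subsets and criteria is kept on the model object.

## Monte Carlo cross-validated random forests

All classification measures are estimated by Monte Carlo cross-validation
(repeated random subsampling without replacement): by default 200
repetitions, each holding out `round(0.2 · n)` subjects for testing (10 of
52), with the training portion split again 80:20 into inner training and
validation sets for hyperparameter tuning. Two details deserve note:

* **Rounding** is half-away-from-zero, so a 20% test fraction of 52
  subjects gives exactly 10.
* **Stratification** by outcome is on by default. With 22 cases against 30
  controls, unstratified 10-subject test sets would occasionally contain a
  single class, making TPR or TNR undefined; stratified sampling keeps
  every set's group proportions within one subject of proportionality.
  `stratify = FALSE` restores literal simple random sampling (the split
  plan then refuses to proceed if any repetition ends up single-class).

Per repetition the hyperparameters are tuned on the inner split by AUC
(ties broken by accuracy, then grid order), the chosen configuration is
refit on the full outer training set, and the held-out test set is scored:
accuracy, true positive rate (sensitivity) and true negative rate
(specificity) at a predicted-probability threshold of 0.5 with `case` as
the positive class, and AUC by the rank (Mann–Whitney) formulation with
ties counted one half — the test suite proves this equal to brute-force
pair counting. The default tuning grid crosses trees {200, 500}, features
per split {√p, p/3} and minimum node size {1, 5}; forests are grown with
impurity-decrease importance (permutation importance is available as an
option). Per-repetition importances are normalized to sum to one and
averaged across repetitions; the aggregate ranking orders variables by mean
normalized importance, breaking ties by mean per-repetition rank and then
name.

All randomness is derived from explicit seeds: the split plan is fixed by
its seed, and each repetition's forest uses a seed derived from the plan
seed plus the repetition index, so a report is exactly reproducible from
its inputs.

## Hierarchical selection: classes, then species

Stage 1 ranks the lipid classes (with covariates) and re-evaluates the
classifier on the top fraction of classes over a scan grid (default 10% to
100% in steps of 10%). Stage 2 selects species by two strategies sharing
one engine:

* **Method 1** ranks all species and evaluates the top *k* species plus age
  and sex for each *k* in the grid (default 5 to 25 in steps of 5).
* **Method 2** first restricts the candidate pool to species whose class
  survived stage 1 — on the default panel with the ten leading classes
  that pool holds 176 of the 530 species — and then proceeds as Method 1.

The published workflow reports specific operating points (30% of classes;
10 species globally; 17 species within the top classes) without stating how
they were chosen; here the choice is made explicit: the scanned size
maximizing mean AUC wins, ties go to the smaller model, and the full scan
table (size against all four metrics) is always part of the result so any
other criterion can be audited after the fact. AUC was chosen as the
selection metric because it is threshold-free and the most stable of the
four at n ≈ 52. Stage 2 runs on fresh split plans with seeds derived from
the master seed (offsets +1 and +2), so species selection is not evaluated
on the resamples that chose the classes.

Method 2's advantage over Method 1 is a large-p phenomenon: with 530
candidate species and ~50 subjects, global importance ranking is noisy
enough to admit false species into small models, while the class-restricted
pool is an order of magnitude smaller and pre-enriched for signal. In
parameter-recovery simulations at the study's dimensions (3 spiked classes,
log-effect 0.8, noise SD 1.0) Method 2's mean AUC matches or exceeds
Method 1's and ~97% of its selected species are truly informative. On
small panels (a few hundred candidates or fewer) both methods saturate and
the difference vanishes — the restriction is not expected to help there.

## Statistical validation

The selected features are then examined with conventional statistics,
reported in the record shape of the published ranked tables:

* **Welch's t test** (unequal variances, Satterthwaite degrees of freedom,
  two-sided) on case versus control concentrations, with a 95% confidence
  interval for the mean difference. The package states its sign convention
  in every report: estimates and CIs are **case − control**. The
  implementation is written from the formulas and is verified against
  `stats::t.test()` on a thousand random instances.
* **Bonferroni correction** per selected family: the per-test threshold is
  α/m (0.05 over 17 species prints as 0.0029).
* **Direction of effect** from ridge-penalized logistic regression on the
  standardized selected features, fitted jointly; positive means higher
  concentration raises the predicted case probability. The ridge penalty is
  chosen by 5-fold cross-validated deviance when not supplied. A penalized
  logistic (not linear) model is used because the quantity being explained
  is a classification probability; ridge keeps coefficients defined under
  the strong collinearity of co-regulated lipids, and an exactly zero
  coefficient is reported as `Indeterminate` rather than silently signed.
* **Univariate logistic regression** per feature (Wald p; perfect
  separation is flagged instead of reported), and **sequential multivariate
  logistic selection** — forward (SFS), backward (SBS) and floating forward
  (SFFS) — driven by likelihood-ratio tests with enter/remove thresholds
  0.05/0.10. Likelihood-ratio rather than Wald criteria drive the steps
  because they are markedly more stable at n ≈ 52; the thresholds are the
  conventional stepwise defaults. All three variants run and are reported
  as separate membership flags, since any of them is a defensible reading
  of "multivariate regression". Every run returns a replayable step log.
* **log2 fold changes** of group means for two-group screens of the
  cell/tissue kind, pairing each fold change with a Welch p-value.

## The synthetic cohort generator

Concentrations are log-normal with additive effects on the natural-log
scale: log-value = class baseline + species baseline + case · (class effect
+ species effect) + noise. Defaults emulate the motivating study's
conditions: 530 species in 34 classes (the ten named leading classes —
PC, NAPS, DG, GB3, Cer, MhCer, BMP, LPS, TG, NAPE — jointly holding 176
species, with the per-class counts a declared fixture since the real
class-size table is not public), 22 cases and 30 controls, log-scale noise
SD 1 (a typical between-subject coefficient of variation for serum lipids),
ages normal (51, 12) truncated to 30–85, sex Bernoulli per group (55%
female in cases, 67% in controls), and a 1% per-cell dropout rate for
sporadic below-detection values. `simulate_raw_peaks()` adds a latent
per-sample technical factor shared between peaks and internal standards,
which is the input fixture for the normalization stage. Every generated
object carries its ground truth (effects, informative ids, parameters,
seed) and identical seeds give bitwise-identical cohorts.

What the generator deliberately does **not** emulate: correlation between
species beyond shared class baselines (real lipid co-regulation is much
richer), heavy-tailed or skewed noise, batch structure beyond a single
latent factor, age- or sex-dependent lipid levels, and any relationship
between missingness and abundance (dropout is uniform, not
intensity-dependent). Passing tests therefore demonstrate that the
machinery is correct and well calibrated under a clean generative model —
not that the published effect sizes are recoverable from real sera.

## Numerical choices and test scale

Tolerances and tie-breaks that matter: AUC ties count one half; tuning ties
fall back to accuracy then grid order; ranking ties fall back to mean rank
then name; scan ties prefer the smaller model; sequential-selection ties
prefer candidate order; zero-variance features are retained in forests
(harmless) but excluded as internal standards (uninformative); a feature
table with missing values is rejected by the classifier stage with a
pointer to `handle_missing()`.

The packaged checks run at reduced but honest scale, chosen once: null
calibration uses 20 cohorts × 50 MCCV repetitions on the full 34-class
design (grand-mean AUC within 0.5 ± 0.1 — per-cohort means at this n have
Monte Carlo spread of ±0.07, which is why the aggregate is the meaningful
check); family-wise error of Bonferroni-thresholded Welch tests uses 1000
null simulations of 34 features; parameter recovery uses 20 cohorts on the
full 530-species panel with 3 spiked classes (log-effect 0.8, noise 1.0),
30-repetition class scans and 25-repetition species scans with a
single-configuration forest grid (300 trees, √p, node size 5). Production
analyses should use the 200-repetition default and the full tuning grid;
none of the package's logic depends on the scale.

## Limitations

The pipeline estimates discrimination, not effect size or causality;
variable-importance rankings are relative to the candidate set and are not
stable under strong collinearity (ridge directions are reported jointly for
exactly that reason); Monte Carlo cross-validation at n = 52 has
substantial variance, which is the reason every headline number is an
average over many repetitions and every selection result carries its scan
table; and the Bonferroni correction is deliberately conservative — with
34 simultaneous class tests, real but modest shifts will often fail it, as
they did in the motivating study.
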