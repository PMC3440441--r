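---
title: "Methods: forced-classification optimal-scaling PCA and double cross-validated PLS-DA for RA subtype discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forced-classification optimal-scaling PCA and double cross-validated PLS-DA for RA subtype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rheumatoid-arthritis patients are clinically heterogeneous. One practiced
way of stratifying them, from Chinese medicine, assigns each patient to a
*Cold* or a *Heat* phenotype. `coldheat` implements a complete,
reproducible pipeline that asks whether such a binary expert label is
reflected in measurable data of three very different kinds:

1. a symptom questionnaire — 57 items scored 1–7 (ordinal) or nominally;
2. routine clinical chemistry — continuous blood measurements;
3. untargeted LC-MS metabolomics of urine and plasma — intensity tables of
   hundreds to thousands of features.

Because the patient-level data of the motivating study were never
deposited, the package ships a seeded synthetic-cohort generator that
emulates the study design, so every stage of the pipeline is exercised and
tested end to end without any download. All statements below about what
the pipeline achieves are statements the test suite and the acceptance
script compute.

## Forced-classification nonlinear PCA with optimal scaling

### Model

Categorical PCA assigns each category $c$ of variable $j$ a numeric
quantification $v_{jc}$, producing a transformed variable
$q_j$ (mean 0, sum of squares $n$), and fits principal components to the
transformed data. With one component the model minimises

$$\sigma = \sum_j w_j \, \lVert x\, a_j - q_j a_j \rVert^2
 \quad\Longleftrightarrow\quad
 \text{maximise } \textstyle\sum_j w_j a_j^2,$$

over object scores $x$ ($\bar x = 0$, $x^\top x = n$), loadings
$a_j = q_j^\top x / n$ and feasible quantifications. The *variance
accounted for* of a variable is $\mathrm{VAF}_j = a_j^2$; the total VAF is
their (weighted) mean. The *analysis level* of a variable fixes the
feasible set of its quantification:

| level | constraint | typical use |
|---|---|---|
| nominal | none | unordered categories |
| ordinal | monotone nondecreasing | severity scales |
| spline-nominal | quadratic B-spline with 1–2 interior knots | smooth, possibly nonmonotone |
| spline-ordinal | monotone spline (nonnegative coefficients on a cumulated basis) | smooth and monotone |
| numeric | linear in the codes | interval measurements |

These sets are nested (numeric ⊂ spline-ordinal ⊂ spline-nominal ⊂
nominal), so total VAF can only grow as constraints are relaxed — the
pipeline's level-comparison step uses exactly this property to detect
nonmonotone clinical relationships: if a spline-nominal transformation
accounts for substantially more variance than a spline-ordinal one, some
variable relates to the component non-monotonically (in the motivating
study, mean corpuscular hemoglobin concentration behaved this way: both
high and low values associated with one class).

*Forced classification* adds the binary class label as one more (nominal)
variable with a very large weight, 1000 by default. The first component is
then forced to align with the class split and the object scores cluster
into two subclouds. The fit escalates the weight (doubling, capped) until
the two classes' score intervals are disjoint, and pins the sign so that
Heat scores are positive. The headline "total VAF" of such a model is
reported over the substantive variables only (`total_vaf_substantive`);
the class indicator's VAF is ~1 by construction and would dominate a
weighted summary.

### Alternating least squares

`fit_nlpca()` alternates three exact partial minimisations:

1. **Quantifications.** For each variable the unconstrained optimum is the
   vector of category means of the current component (frequency-weighted);
   it is then projected onto the level's feasible set: weighted
   pool-adjacent-violators (PAVA) for ordinal, weighted least squares onto
   the spline span for spline-nominal, nonnegative least squares on a
   cumulated B-spline basis (free intercept) for spline-ordinal. For the
   monotone sets both orientations are tried and the better one kept; the
   stored quantification is always nondecreasing, with the loading's sign
   carrying the direction.
2. **Loadings.** $a_j = q_j^\top x / n$ after renormalising $q_j$.
3. **Object scores.** $x \propto \sum_j w_j a_j q_j$, centered and
   rescaled to $x^\top x = n$ (for $>1$ dimension, an orthogonal
   Procrustes update via SVD).

Each step solves its subproblem exactly, so the loss is nonincreasing and
total VAF nondecreasing — asserted after every iteration (violations
beyond $10^{-9}$, i.e. beyond floating-point noise, raise a warning).
Convergence is declared when the VAF gain drops below `tol` ($10^{-8}$ by
default; property tests that compare against classical PCA tighten this to
$10^{-12}$ because ALS converges linearly and the gap to the optimum is of
the order of the stopping tolerance). Initial object scores are seeded
random normal vectors, orthonormalised; with the numeric level the
algorithm is then exactly a power iteration on the correlation matrix,
which is the oracle equivalence the tests assert at $10^{-8}$.

Degenerate variables (a quantification collapsing to a constant) get
$q_j = 0$, $a_j = 0$ and stay in the model without contributing;
single-category variables are rejected — the preprocessing contract
removes them first.

### Prediction for held-out subjects

The study protocol predicts left-out patients from a fitted model but does
not say how; the rule here is documented as the package's own choice.
A new subject's category codes are mapped through the trained
quantifications (unseen codes: linear interpolation between neighbouring
observed categories for ordered levels, clamped at the ends; the modal
category's value for nominal), the component score is the weighted
least-squares estimate over the non-class variables,
$\hat x = \sum_j' w_j a_j q_j / \sum_j' w_j a_j^2$, and the predicted class
is the one whose trained class-quantification is nearer on the component,
ties to Cold. Subjects missing more than half their variables are refused
(`NA`).

## The questionnaire/clinical protocol

The published sequence, reproduced by `nlpca_protocol()`:

1. merge scoring categories observed fewer than 7 times (ordinal: into the
   adjacent category with the nearer code, ties toward the lower code;
   nominal: into a pooled "other" category), then drop variables left with
   a single category — on the emulated design this reproduces the
   published 57 → 42 item reduction;
2. bin each clinical variable uniformly into 19 categories over its
   observed range (half-open interior edges, rightmost closed);
3. choose the clinical analysis level by comparing total VAF across
   numeric, spline-ordinal and spline-nominal fits and knot counts;
4. select variables with VAF strictly greater than 0.20 and refit;
5. estimate the classification error by stratified leave-two-out CV: folds
   are random Cold/Heat pairs (odd leftovers form a final fold), the model
   is refit on the remaining 37 subjects per fold, and the held-out pair is
   predicted — every subject exactly once;
6. test significance by permuting labels (class sizes preserved) and
   re-running the *full* protocol — including selection — per permutation;
   $p = (1 + \#\{\text{null} \le \text{obs}\})/(B + 1)$.

Two deliberate design points. Selection happens once, on all subjects,
*before* CV — that is the protocol the study describes, and it is
optimistically biased; `select_in_cv = TRUE` redoes selection inside every
training fold for an unbiased estimate. And because the permutation re-runs
selection under the null, the null CV errors sit *below* 50% (the same
optimism), which keeps the comparison with the observed error fair. The
plain permuted-label CV error, without selection, centers on 50% — the
baseline the study quotes — and the tests assert both facts.

## PLS-DA with double cross-validation and jack-knife elimination

For the LC-MS tables the class is coded $-1$ (Cold) / $+1$ (Heat) and a
single-response PLS regression (NIPALS, deterministic, no iteration needed
for one response) predicts it; the predicted class is the sign of the
fitted response, 0 to Cold. At full rank PLS reproduces ordinary least
squares — an oracle identity the tests assert on small matrices.

* **Double CV** (`double_cv()`): stratified leave-two-out folds in both
  loops. The study says "tenfold" once but describes leave-two-out in both
  loops and has n ≈ 28; leave-two-out pairs are implemented as primary.
  The inner loop picks the latent-variable count $A$ minimising inner
  misclassification (ties to smaller $A$); the outer model is refit at the
  chosen $A$ and predicts its held-out pair. Column scaling (urine: mean
  centering; plasma: autoscaling) is recomputed inside every training fold
  and applied to the held-out samples, so no information leaks; the study
  scaled once globally, which `scale_mode = "none"` on a pre-scaled matrix
  reproduces.
* **Jack-knife elimination** (`jackknife_select()`): the regression vector
  is collected from each outer training fold; a feature's SE is the SD of
  its coefficient across folds, taken by default *relative to its mean
  coefficient*. A feature is eliminated when its coefficient cannot be
  told from zero across segments — the jack-knife criterion used with PLS
  in practice. (Thresholding the raw SE instead, available as
  `criterion = "absolute"`, preferentially removes the largest and most
  discriminating coefficients, whose absolute fold-to-fold variation is
  biggest; in simulation it fails to recover planted discriminators.)
  Thresholds walk the descending quantiles (1.00, 0.95, …, 0.50) of the
  criterion's distribution — no numeric schedule is prescribed — removing
  features above threshold and re-running the double CV. The elimination
  stops paying off when the error starts to increase; the full trace is
  recorded regardless, and the step with the minimum error (first on ties)
  is chosen. Retained counts are nonincreasing by construction (nested
  threshold sets over the initial criterion values).
* **Permutation test** (`permutation_test_plsda()`): 250 label shuffles by
  default; significance when the observed error beats the 5th percentile
  of the null errors, p reported with the add-one correction.

## Metabolite-level reporting

* `log2_ratio()` — $\log_2$ of the ratio of class-mean intensities, Cold
  over Heat, arithmetic means by default ("average levels"; geometric
  behind a flag).
* `flag_acylcarnitines()` — flags features with a fragment at precursor
  mass − 59.0747 Da (±0.005 Da, a high-resolution default), the neutral
  loss diagnostic for acylcarnitines, and checks that retention time rises
  with precursor mass over the flagged set (longer acyl chains are less
  polar) via Spearman correlation.
* `symptom_positive_summary()` — scores above 1 count as positive; rows
  report the percentage of subjects with exactly 0, ≥1, ≥2 and all 3
  positive symptoms per class (the published table's "0" row is
  *exactly zero* — its 0 and ≥1 rows sum to 100 within each class, which
  fixes the reading), with a tie-corrected Mann-Whitney U per symptom.
* `ttest_from_summary()` — pooled-variance two-tailed t-test from printed
  group summaries. From the published characteristics table only the age
  row (51±13 vs 54±11, p = 0.44) is printed precisely enough to reproduce
  numerically; the other rows are rounded to 1–2 significant figures and
  verify only as "not significant".

## What the synthetic cohort emulates — and what it does not

The generator (`cohort_config()` defaults) encodes the study conditions:
20 + 19 subjects; 57 items of which 15 carry no variation and a set of
sparse items force the category-merging path; ~40 clinical variables with
monotone mean shifts and nonmonotone (tail-enrichment) class relations;
urine 14 + 14 and plasma 11 + 14 study samples with 1000 features each.
Questionnaire items come from a proportional-odds (ordered logit) model —
the natural generative model for 1–7 severity scales, which the study does
not specify. The nonmonotone clinical relation is encoded as both tails
enriched in Heat with Cold central, matching the reported
"high as well as low" pattern. LC-MS intensities are log-normal; zeros are
left-censoring at a detection limit placed at the `missing_rate` quantile
(the pipeline treats zeros as non-detects, so the generator produces
them as such); pooled-QC injections are the cohort mean profile with 3%
noise and a multiplicative injection-order drift. QC frequency and batch
layout are free parameters, as the study does not state them.

Planted class effects use the published 2log Cold/Heat ratios of the top
discriminators. Each of the 20 ratios is planted on three features, with
informative features drawn from the upper intensity range: real
discriminating compounds contribute several correlated, confidently
detected features (the study's final urine model kept 793), and an
unrealistically sparse 20-of-1000 independent signal would give the
mean-centered-raw pipeline no power at n = 14/class, misrepresenting the
study conditions these defaults exist to emulate.

What passing tests on this cohort do **not** show: the generator draws
independent features (no correlation structure beyond the planted
effects), has no batch effects beyond a linear drift, no isotope/adduct
patterns beyond the single stored fragment mass, and its questionnaire
items are conditionally independent given the class. Real data violate all
of these, so the reported error rates characterise the pipeline's
machinery, not expected clinical performance; the study's own headline
numbers (total VAF ≈ 21%, CV error 15%, urine 14%, plasma 28%) depend on
the undeposited patient data and are deliberately not targets.

## Numerical choices and problem sizes

* ALS: `tol = 1e-8` on the VAF gain, `maxit = 500`; seeded random-normal
  initialisation; knots at frequency-weighted quantiles of the category
  distribution (equally spaced fallback on collision); requested knot
  counts are reduced with a warning when categories are too few — the same
  fallback the study applied when moving from two knots to one.
* PAVA pools by weighted means; direction ties prefer the increasing fit.
* Prediction tie (score equidistant) goes to Cold; PLS response exactly 0
  goes to Cold.
* Zero replacement is per feature (half the feature's smallest nonzero
  value); the study's "smallest measured value" could also be read
  globally, available via `per_feature = FALSE`.
* The presence rule keeps a feature supported by *at least one* class
  (matching the wording "in one class"); `rule = "all-classes"` gives the
  stricter variant.
* QC outlier rule: > 4 MADs from the component median on either of the
  first two PCs — the package's own rule, the study gives none.
* Simulation sizes in the default test run: calibration of the permutation
  tests uses 25 (NLPCA) and 20 (PLS-DA) null cohorts × 19 permutations;
  jack-knife recovery uses 20 seeds of the 5-informative/195-noise design;
  the analysis scripts and the acceptance script run the full study-scale
  configuration (39 subjects; 28 samples × 1000 features; 250
  permutations).

## Known limitations

* Only the one-component (forced-classification) solution is thoroughly
  exercised; multi-component solutions with rotation are out of scope.
* Missing data are handled at prediction time only; the fit requires
  complete category codes.
* The normalisation convention is variable-principal. If exact loadings
  from other optimal-scaling software ever need reproduction, that
  software's normalisation option must match.
* The permutation test permutes labels before variable selection
  (conservative); whether the study permuted before or after is not
  stated.
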