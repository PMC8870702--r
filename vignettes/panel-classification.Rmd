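---
title: "Classifying adrenocortical tumors with miRNA panels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adrenocortical tumors with miRNA panels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrenomir)
```

## The problem

Distinguishing adrenocortical carcinoma (ACC) from adrenocortical adenoma
(ACA) on histology is difficult even for expert pathologists, and biopsy of
adrenal masses is discouraged in routine practice. Tissue miRNA expression
offers a molecular adjunct: several miRNAs are consistently up- or
down-regulated in malignant adrenocortical tissue. No single miRNA is a
reliable marker on its own, which motivates searching for small *panels* of
miRNAs whose joint expression pattern discriminates ACC from ACA.

`adrenomir` implements that search and its validation as a reproducible
pipeline over RT-qPCR cycle-threshold (Ct) data:

1. **delta-Ct normalization** of raw triplicate Ct values against two
   controls;
2. **random-forest importance ranking** of the markers;
3. an **exhaustive combinatorial search** over 2-4-miRNA panels scored by
   repeated learner-tester neural-network cross-validation;
4. **majority-vote ensemble classification** of unknown samples;
5. **diagnostic evaluation** (sensitivity, specificity, PPV, NPV, ROC/AUC).

A synthetic Ct-table generator reproduces the study design (cohort sizes,
effect directions, triplicates, censored wells), so the whole pipeline runs
and is tested without any patient data.

## Normalization model

qPCR reports the cycle at which a target's amplification crosses threshold;
under the doubling assumption one cycle equals one log2 unit of abundance,
with *lower* Ct meaning *higher* expression. For sample $s$ and target $a$:

$$\Delta Ct(s,a) = Ct(s,a) - \sqrt{Ct_{RNU48}(s)\cdot Ct_{cel\text{-}miR\text{-}39}(s)},$$

and the stored expression value is $-\Delta Ct(s,a)$, so that "up-regulated
in ACC" corresponds to larger values. The reference combines an intrinsic
housekeeping control (RNU48, within-sample normalization) and an exogenous
spike-in (cel-miR-39, extraction efficiency). We take the *geometric mean
of the two control Ct values* literally; common qPCR normalization software
instead averages Cq values arithmetically, so `normalize_delta_ct()`
exposes `control_summary = "arithmetic"` as a switch. The two differ by
well under 0.1 cycles at realistic control Cts and the choice does not
change any qualitative result.

Triplicate wells are collapsed by their mean (median by config); a
(sample, assay) pair is missing only when all replicates are unmeasurable.
The default missing-value rule is **feature omission**: an assay with at
least one unmeasurable summary in the analysis set is dropped entirely.
This is the conservative rule for down-regulated markers whose true
abundance falls below the detection limit — imputing them would
manufacture the very signal being tested. The alternative
(`censor_fill`) imputes at the detection floor
$-(Ct_{max} - \text{control ref})$ and is used in tests where a fully
observed matrix is required. Whether omission should act per-cohort or
per-comparison is genuinely open; we apply it per analysis set (the matrix
being normalized), which is the strictest reading.

## The classifier and the panel search

The classifier is a single-hidden-layer feed-forward network: logistic
hidden units, softmax output, trained by full-batch gradient descent with
momentum 0.9 on multinomial cross-entropy plus an L2 penalty on connection
weights. Defaults: 3 hidden units, weight decay 0.01, learning rate 0.2,
200 epochs, initial weights Uniform(-0.5, 0.5). These are conventional
small-network settings for low-dimensional standardized inputs; with 2-4
features and ~27 learners a wider or deeper network only adds variance.
Three deliberate choices:

- **Standardization lives inside the model** and is fitted on the learner
  set only, so no information leaks from held-out testers; a zero-variance
  learner feature gets scale 1 rather than an error.
- **Biases are exempt from weight decay**, so in the
  heavy-regularization limit predictions tend to the learner-set class
  frequencies rather than to the uniform distribution.
- **A fixed epoch budget, no early stopping**: training is a deterministic
  function of the data and the seed, which is what makes 10,000-iteration
  ensembles exactly reproducible. Rows are canonically pre-sorted by
  sample id so listing order cannot perturb the fit.

Panel capability is measured by the study's scheme: per repetition, 9
learners and 1 tester per group are drawn (stratified, never a pooled 10%),
the network is retrained from a fresh initialization, and the testers are
classified; **classification capability** is the mean per-repetition tester
accuracy over 1000 repetitions. (With one tester per group the alternative
pooled-accuracy aggregation is identical; it is available by config for
larger tester counts.) Both the three-class analysis (ACA/ACC/NAC) and the
two-class tumors-only analysis run on the same matrix via
`group_mode`. Combinations reaching 90% capability are selected.
Enumeration covers all subsets of sizes 2-4 — 2,500 for 16 markers, 246
for the refined 9-marker panel — exhaustively; no greedy selection.

## Ensemble validation and the majority vote

An unknown sample is classified `n_iterations` times (study value 10,000).
What varies across iterations is not specified by the original description
beyond its "90-10%" language, so the default (`subsample_90`) draws a
stratified 90% learner subset of the labeled ACA/ACC discovery samples
*and* a fresh initialization per iteration; `full_refit` (all knowns,
initialization-only randomness) is the alternative. Training uses the
discovery ACA/ACC samples only — final calls are binary, and growing the
labeled pool with already-called unknowns would let early mistakes
propagate. The final call is the class with strictly more than 50% of the
votes; an exact tie is an explicit `INDETERMINATE` state, which the
confusion matrix counts separately and never in its four cells. Per-sample
seed streams are derived from the sample id, so cohort order cannot change
any individual vote.

## Diagnostic evaluation

ACC is the positive ("patient") class, ACA the control; sensitivity
$tp/(tp+fn)$, specificity $tn/(tn+fp)$, PPV, NPV, with any
zero-denominator metric flagged `NA` rather than silently zeroed. (The
original prose defines false positives in the reverse direction —
"benign instead of malignant"; we keep the standard epidemiological
convention and expose `positive` as an argument, so both orientations are
one call away.) The ROC curve sweeps every distinct vote fraction as a
threshold; AUC is the trapezoid integral, which the tests verify equals
the tie-corrected Mann-Whitney statistic exactly.

## What the generator emulates — and what it does not

`default_synthetic_spec()` encodes the study design: 16 target miRNAs with
their literature effect directions, RNU48 + cel-miR-39 controls,
triplicates, discovery 10/10/10, validation 22 ACA / 21 ACC with withheld
labels. Values neither stated by the design nor measurable from public
data are the generator's free parameters, chosen once as field-realistic:

- **effect_log2 = 2** (a four-fold change between ACC and ACA on the
  affected markers) and **aca_vs_nac_log2 = 1** in the same direction, so
  expression runs monotonically normal → benign → malignant;
- **biological_sd = 0.75 cycles**, **replicate_sd = 0.25 cycles** —
  typical between-sample and triplicate variability for FFPE-derived
  RT-qPCR; controls get a third of the biological variability so
  normalization is genuinely exercised, not a no-op;
- **baseline Cts**: controls 22/24 cycles, candidate-panel targets 26-30,
  and the weakly expressed down-regulated markers outside the candidate
  panels (e.g. miR-7, miR-205, miR-431, miR-511) at 33-36 cycles so that
  their down-shift in tumors crosses the **38-cycle censoring ceiling** in
  occasional wells — reproducing why such markers end up omitted and the
  validation panel shrinks to 9 miRNAs;
- censoring acts per replicate, the way instruments report
  "Undetermined" wells.

The generator does **not** emulate: amplification-efficiency differences
between assays (plain delta-Ct assumes perfect doubling), inter-plate or
batch effects, FFPE degradation gradients, correlated co-regulation among
miRNAs (features are independent given the group), or label noise in the
histological reference standard. Passing tests therefore demonstrate that
the *pipeline* recovers what the generative model puts in — effect
recovery, chance-level behavior under the null, seed-exact
reproducibility — not that the specific published panels would replicate
in new tissue. Real per-sample data can be substituted at any stage
boundary (`read_ct_table()`, `read_expr_matrix()`).

## Numerical and degenerate-input conventions

- Seeds: a single master seed fans out per stage, repetition and sample via
  `child_seed()` (a hash of the stage name, kept below $2^{31}$), so every
  stage is independently reproducible and unknown-sample results are
  order-invariant.
- Combination members are kept in the field's natural order
  (`hsa-miR-9` before `hsa-miR-195`); selection ties break
  lexicographically by label, importance ties by assay name.
- The softmax is computed with max-subtraction; probabilities sum to 1
  within 1e-9.
- Degenerate inputs fail loudly: single-class training labels, arity
  mismatches, unknown samples with a masked panel assay, samples missing a
  control summary, and Ct values outside $(0, ct_{max}]$ are all named
  errors.

## Problem sizes used in the checked analyses

The bundled analysis scripts and tests run the search at 200-1000
repetitions and the ensemble at 500-2000 iterations (10,000 in the
vote-stability property test). At 500 iterations a vote fraction has
standard error $\le \sqrt{0.25/500} \approx 0.022$, already far below the
0.5 decision threshold for any confidently classified sample; the larger
study-scale counts change reported percentages by well under one point.
These sizes are the package's own default study conditions for its
synthetic experiments.

## Known limitations

- Exact numeric reproduction of any originally reported per-model
  percentages is not possible without the underlying per-sample expression
  values and the exact network configuration used, neither of which is
  publicly specified. The bundled `synthetic_*_expression.csv` fixtures are
  generator output shipped in the expected per-sample layout, and are
  labelled synthetic everywhere they appear.
- The three-class forest ranking and the search's three-class mode assume
  NAC samples are available; with tumors only, use
  `group_mode = "two_class"` and two-class labels throughout.
- Capability estimates at 200 repetitions carry a binomial standard error
  of roughly 1 percentage point near 90%; selection at the 90% threshold
  is correspondingly soft for borderline panels.
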