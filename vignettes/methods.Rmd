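---
title: "Methods: claims-based case finding for ATTR-CM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based case finding for ATTR-CM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attrclaims)
```

## The problem

Transthyretin amyloid cardiomyopathy (ATTR-CM) has no ICD-10 code of its
own. In reimbursement claims it appears only indirectly: amyloidosis
codes (E85 and subcodes), cardiac codes (heart failure,
cardiomyopathies, conduction disease), associated conditions (carpal
tunnel syndrome, chronic kidney disease), and the diagnostic procedures
that confirm it (bone scintigraphy, cardiac MRI, heart biopsy). A
claims-based phenotype therefore has three layers: rebuild each
patient's longitudinal record across databases that share no
identifier; apply a rule cascade that labels the patients most likely
to have a confirmed diagnosis (*reference*) and a wider pool with
compatible workup (*potential*); and train a classifier on the
reference pattern to flag which potential patients look like
under-recognized cases (*like* vs *non*).

`attrclaims` implements the whole chain on synthetic claims whose
latent disease status is known, so every stage can be scored against a
ground truth — something no real claims extract allows.

## The rule sets

`attr_ruleset()` ships the expert-validated code lists. Hereditary
amyloidosis is E85.0–E85.2; wild-type/other amyloidosis is E85 and
E85.3–E85.9; the cardiac list is split into the 11-code *required*
sub-list (I50.0, I50.1, I50.9, I11.0, I42.0, I42.1, I42.2, I35.0,
I44.1, I44.2, I42.5) that anchors the reference definition and the full
21-code *related* list (adding cardiomegaly, further conduction blocks,
ventricular tachycardia, atrial flutter/fibrillation, aortic stenosis,
carpal tunnel syndrome and chronic kidney disease codes) that drives
wild-type cohort entry. Patients bearing blood-cancer, end-stage renal
disease or cerebral amyloid angiopathy codes are excluded outright, as
these conditions mimic or overlap other amyloidoses.

Matching is insensitive to dots and dashes (claims files omit them):
`I500` equals `I50.0`. The bare stem `E85` matches only claims coded
exactly `E85` — the subcodes are listed separately and carry their own
meanings.

The procedure tiers reflect diagnostic specificity. *Mandatory*
procedures are the amyloidosis-specific investigations: heart biopsy,
the three bone-scintigraphy codes, cardiac MRI. *Secondary* procedures
are supportive cardiology workup: ECG, echocardiography, natriuretic
peptides, troponin, carpal-tunnel release, tenosynovectomy,
pacemaker/valve implants. The authoritative published split of these
tiers is not available in full, so the tiers here are assembled from
the published treatment/procedure code lists and are fully
config-overridable; analyses sensitive to the split should treat it as
a tunable input. *Treatment* codes (tafamidis 06.04.54.006-0,
heart/liver transplant, heart-failure treatment codes) feed the
resource-utilization reports only.

### The cascade

Per disease form, after exclusions and the quality filter:

* **Index date** — earliest claim bearing a cohort-qualifying code:
  hereditary codes for the hATTR cohort; wild-type *or any
  cardiac-related* code for the wtATTR cohort. The wild-type choice
  follows the cohort-entry definition (age ≥ 50 *at the first
  qualifying claim*, which may be cardiac); a wild-type journey whose
  first cardiac claim precedes its first amyloidosis claim is anchored
  at the cardiac claim.
* **Reference** — age at index ≥ the gate (18 y hereditary, 50 y
  wild-type), at least one amyloidosis claim of the cohort's form, and
  at least one claim from the required cardiac sub-list.
* **Potential** (evaluated only below reference) — wild-type route (a):
  cardiac-related claim + ≥1 secondary + ≥1 mandatory procedure;
  wild-type route (b): wild-type amyloidosis claim + ≥1 mandatory or
  secondary procedure; hereditary: amyloidosis claim + ≥1 mandatory or
  secondary procedure. The age gate applies as above.
* Everything else kept is **out of cohort**.

Ages use the Julian year (365.25 days). The ≥50%-missingness quality
rule needs a denominator the published description does not give; here
it is the 11 claim data fields (all but the record id), averaged over a
journey's claims, so structurally absent fields (no length of stay on
outpatient claims) count as missing — a deliberate, crude mirror of how
such filters behave on raw extracts.

## Record linkage

The linkage is deliberately deterministic: ordered blocking passes with
an agreement-fraction score, not a Fellegi–Sunter weight model — the
published account names the quasi-identifiers (date of birth, city,
ZIP) and a multi-step design but no weights, and a deterministic design
is reproducible and directly testable. Outpatient records carrying the
encrypted patient key are pre-clustered before any pass. Each pass
compares only records agreeing exactly on its blocking keys; candidate
pairs score the fraction of comparison fields agreeing (missing counts
as disagreement) and pairs at or above `min_agreement` merge by
transitive closure. Records matched in an earlier pass sit out later
passes. The defaults are (1) exact date of birth + sex + municipality +
ZIP; (2) blocking on date of birth + sex + municipality and (3) on date
of birth + sex + ZIP, each requiring 0.75 agreement over the remaining
fields — conservative thresholds that with two residual comparison
fields demand full agreement; analysts wanting typo tolerance lower
`min_agreement` to 0.5, as the linkage tests demonstrate. Cleaning
precedes linkage: records with unparseable or inverted dates or the
planted low-quality flag are set aside (about 5% under the default
noise model).

Quality is scored as pairwise precision/recall of co-assignment against
the latent truth: with zero identifier noise both are exactly 1; under
the default noise precision stays at 1 while recall drops to ~0.8,
i.e., the conservative passes under-merge rather than over-merge.

## The classifier

The supervised layer learns reference vs negative. The published design
never defines the negative class; here negatives are kept journeys
bearing cardiac-related codes that meet neither the reference nor the
potential criteria, subsampled to 3 negatives per positive (both
config-overridable). This is the only label source available inside a
claims extract, and its main bias is known: negatives differ from
reference mostly by the absence of amyloidosis codes, so the model
leans on exactly the codes the cascade used. That is faithful to the
original design, and it is why the evaluation below plants latent
truth.

Features are per-code claim counts over the study ICD and procedure
vocabularies, age at index (at first claim for patients without one),
state of residence (one-hot), hospitalization and outpatient visit
counts, and total length of stay. Splits are patient-level, stratified
by label, 60/20/20 train/validation/test by largest remainder, so a
100-patient input yields exactly 60/20/20. Four candidate families —
ridge-penalized logistic regression (`glmnet`, λ ∈ {0.001, 0.01, 0.1}),
radial SVM (`e1071`, cost ∈ {0.5, 2, 8}), gradient-boosted trees
(`xgboost`, depth ∈ {2, 4}, 60 rounds, η = 0.3) and random forest
(`ranger`, 300 trees, mtry ∈ {√p, p/3}) — are each tuned by stratified
K-fold cross-validation (K = 5; the published account leaves K open) on
the training partition, refitted, and scored on validation. The winner
has the highest validation accuracy (the headline metric of the
original analysis), ties broken by higher validation sensitivity and
then by the fixed family order above; the test partition is touched
only by `evaluate_model()`. Potential patients at predicted probability
≥ 0.5 (configurable) are labeled *like*. Confusion metrics with a zero
denominator are reported as `NA`, never coerced to 0 or 1.

## The synthetic generator

The generator emulates the *structure* of SIH/SIA extracts over the
2015-01-01–2021-12-30 study window, not their empirical joint
distributions, which are unpublished. Latent classes and their default
mixture — hATTR-CM 3%, wtATTR-CM 8%, other cardiac 40%, background
46%, excluded-condition 3% — were chosen once so that every cascade
branch and both classifier labels are populated at a few thousand
patients; the disease shares are far above real prevalence by design
(a case-finding testbed, not an incidence model). Each patient draws a
claim count `1 + Poisson(5)`, claim dates uniform in the window (no
seasonal or per-class admission intensity), setting inpatient with
probability 0.4, and codes from class-conditional categorical
emissions; excluded-condition patients are guaranteed at least one
exclusion code. Ages at window start are uniform per class (hereditary
25–85, wild-type 52–92), keeping each class inside its cohort age gate
with margin. Identifier noise: each linking field independently blanked
(2%) or given a single-digit substitution typo (2%), and 5% of records
flagged low quality, mirroring the reported share discarded before
linkage.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: code co-occurrence and
comorbidity structure (codes are conditionally independent given the
class), care pathways and visit timing, regional coding practice,
duplicate claims, and real DATASUS field layouts. Results on synthetic
data validate the *machinery*, not real-world performance.

### The like-case recovery experiment

A planted-truth check of the final layer: wild-type patients whose
claims follow the reference emission profile but who happen to lack a
required cardiac claim land in the potential pool; the model should
call them *like*. Recovery is only a meaningful expectation when the
disease-code signal is strong enough to see, so the experiment fixes
the expected share of a planted patient's claims bearing wild-type
amyloidosis codes (`recovery_emission()`, default 0.52; 0.5 is the
documented threshold below which recovery degrades). At 2,000 patients
the selected model recovers planted cases with sensitivity above 0.85
and specificity above 0.70 across seeds. Recovery is assessed per
cohort: a hereditary-latent patient inside the wild-type pool is a
correct *non* for the wild-type model.

## Reporting conventions

* Percentages are always recomputable from their printed counts (±0.01,
  rounding only); cross-tabulations carry a Total column.
* Quantiles (medians, IQRs) use the linear-interpolation convention
  (R type 7) everywhere, fixed for cross-implementation
  reproducibility.
* PPPY = events / follow-up years; follow-up runs from the first
  cohort-qualifying claim to the last claim of any kind. Patients with
  zero follow-up are excluded from PPPY medians and reported as a
  separate count (`n_zero_fup`) — division by zero is signalled, never
  silently dropped or zeroed. Resource tables report PPPY as median
  (IQR).
* The hospitalization-rate denominator ("per 100,000") is a
  configuration input (`reporting$population_size`, defaulting to the
  synthetic population size): the quantity is only meaningful relative
  to a declared population.
* Top-procedure rankings count unique patients (five echocardiograms
  for one patient count once), ties broken by code order.
* State-of-residence tables are emitted for completeness; their values
  are purely data-dependent.

## Determinism and problem sizes

Every stochastic step derives its seed from one global seed
(`derive_seed()`), so `run_pipeline()` with an identical configuration
reproduces byte-identical CSV and JSON artifacts; the manifest isolates
timings. The test-suite problem sizes are the package's choices for a
desk-scale run: linkage and recovery properties at 2,000 patients, the
cascade-vs-brute-force oracle at several hundred sampled journeys of ≤5
claims over the 30-code vocabulary (exhaustive enumeration of that
space is combinatorial and adds nothing beyond branch coverage), metric
identities at 10,000 random confusion matrices, and the demo pipeline
at 5,000 patients.

## Known limitations

* The linkage defaults under-merge noisy records by construction;
  recall under heavy noise is a property of the configured thresholds,
  not a bound of the method.
* The negative class is a proxy; on real data the reference rule
  itself is an imperfect label, and nothing in the synthetic evaluation
  measures that label noise.
* The mandatory/secondary procedure split is a best-effort
  reconstruction; results downstream of `label_potential()` shift if
  the tiers are redrawn.
* Emission defaults are pragmatic, not estimates of any real joint
  code distribution; prevalence-like outputs on synthetic data have no
  epidemiological meaning.
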