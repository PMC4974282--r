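---
title: "Combined PET/CT interpretation for distant-metastasis screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined PET/CT interpretation for distant-metastasis screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscreen)
```

## The screening problem

Patients with head and neck squamous cell carcinoma (HNSCC) who carry
high-risk factors for dissemination — three or more nodal metastases,
bilateral nodes, a node of 6 cm or larger, low jugular nodes, recurrence, or
a second primary tumor — are screened for distant metastases before radical
treatment, because established distant disease shifts the intent from
curative to palliative. Two modalities are read side by side: whole-body
FDG-PET, which detects metabolically active lesions anywhere but is blind
below its spatial resolution limit (about 5 mm), and contrast-enhanced chest
CT, which resolves small pulmonary nodules well but is frequently
indeterminate about their nature. `dmscreen` implements the decision rule
that merges the two reports into one call, the follow-up-based reference
standard used to judge that call, the associated accuracy and ROC
statistics, and the cohort reconstruction and simulation machinery used to
validate all of it.

## The combined interpretation rule

Each modality report enters as a binary call for distant metastases. The
combined call produced by `classify_pair()` is

* **positive** if PET is positive — unconditionally. A visually evident
  FDG-avid lesion has a high probability of malignancy, so a negative or
  benign-looking CT correlate does not override it;
* **positive** if PET is negative but CT reports a suspicious pulmonary
  lesion with a diameter strictly below 5 mm. Such a lesion is below the
  PET detection limit, so PET's negativity carries no information and the
  outcome is predicted by CT alone;
* **negative** if PET is negative and the smallest suspicious CT lesion is
  5 mm or larger — at that size PET would be expected to see a metastasis,
  so its silence discounts the CT finding;
* **negative** when both modalities are negative.

Three design choices deserve a note. First, the PET-positive branch is
unconditional: a location-dependent refinement for PET-positive/CT-negative
findings has been suggested but never specified operationally, and both
discordant configurations of that type in the validation cohort (a rib-site
finding and a 6-mm lung lesion read as benign on CT) were true positives, so
the simplification is adopted as the normative rule. Second, the size cut is
strict (`< 5 mm` fires the CT branch; exactly 5 mm does not). Third, when CT
reports several suspicious lesions the *minimum* diameter drives the branch:
any sub-limit lesion is by construction invisible to PET, and one confirmed
metastasis makes the patient metastatic. Likert scores are never consulted
by the combined rule — the rule operates on the binary clinical reports, and
the ordinal scores feed only the ROC analysis.

## Reference standard and analysis sets

Truth is adjudicated from the diagnostic work-up at screening plus twelve
months of clinical follow-up (`dm_truth()`): a patient is truth-positive if
distant metastases were established at screening or manifested within the
window. The window is represented by a pair of booleans rather than event
times because no finer granularity is used anywhere downstream.

Two restrictions produce the analysis sets:

* `evaluable_set()` removes patients who developed a second primary tumor
  *during follow-up* together with distant lesions — imaging cannot
  attribute those lesions to the index tumor or the new primary, so neither
  a false-negative nor a true-negative classification would be defensible.
* `locoregional_set()` further retains only patients with locoregional
  control, because metastases that appear after a locoregional recurrence
  may have been reseeded rather than missed by screening; this stratified
  subset isolates the screening question proper.

Patients whose screening found a second primary tumor but no distant
metastases are truth-negative with both DM calls negative and Likert 0: the
positive report concerns the second primary, not a distant metastasis. This
includes the screening-detected second primary with disseminated disease,
whose lung and bone lesions are attributed to the second (lung) primary —
the only reading under which every published cross-tabulated count balances.

## Accuracy statistics

`accuracy_profile()` reports sensitivity, specificity, PPV, NPV and overall
accuracy, each as a binomial proportion with an exact Clopper–Pearson
interval computed by inverting the binomial tail probabilities (the
beta-quantile form; `clopper_pearson()`). Exact intervals are conservative —
their coverage is at least nominal for every true proportion — which the
test suite verifies by direct summation over the binomial distribution
rather than by simulation. A metric with a zero denominator (sensitivity in
an all-negative cohort) is reported as undefined, never as an error, and
renders as an em-dash.

Rendering follows the conventions of the reference report: point estimates
as integer percentages rounded *half away from zero* (92.5 prints as 93,
87.5 as 88 — base R's round-half-even would disagree), and CI bounds to the
nearest integer percent. When comparing rendered bounds against the
published tables a tolerance of one percentage point is applied, because the
published rounding of extreme upper bounds is internally inconsistent
(a bound of 99.92 % appears both as 99 and as 100); whether that software
rounded or truncated is unknowable, and reverse-engineering it would add no
scientific content.

## ROC analysis over ordinal scores

Every lesion carries a five-point Likert suspicion score (1 definitely
benign … 5 definitely malignant), with 0 as the below-scale sentinel for
patients with no lesion suspicious for distant metastasis; the patient-level
score is the maximum over lesions. `empirical_roc()` evaluates the curve at
thresholds "score ≥ t" for t = 0…6 — the standard convention for ordinal
reader studies, with higher scores more suspicious — and integrates by the
trapezoidal rule, which for this step curve equals the two-sample
Mann–Whitney statistic with ties counted half. The test suite holds the
estimator to that identity by brute-force pair counting, and to invariance
under strictly increasing relabelling of the scores.

Inference uses the paired placement-value estimator (the DeLong approach):
each positive's placement among the negatives and vice versa yields the AUC
variance and, because both modalities score the same patients, the
covariance needed to test the AUC difference. Two-sided normal tests are
reported against the null AUC of 0.5 and for the paired difference. The
"Q-point" is implemented as the maximiser of Youden's J over the operating
points, with ties broken toward higher sensitivity: in screening for
distant disease a missed metastasis leads to futile radical treatment,
whereas a false positive only triggers confirmatory work-up, so sensitivity
is the more valuable of the two when they trade off exactly.

The published AUCs (0.84 for CT, 0.78 for PET) and Q-points are **not**
reproducible from the reconstructed cohort, because per-patient Likert
scores were never published; the scores in the fixture satisfy the handful
of patient-level facts that were stated and are otherwise reconstruction
artifacts. The ROC machinery is therefore validated by oracle equivalence
and by parameter recovery from `simulate_paired_scores()`, which calibrates
the latent separation (by root-finding on the exact discretised pair
probability) so that the true AUC of the emitted six-level ordinal scores
equals the requested target; the published AUC values are used as the
recovery targets.

## The reconstructed 47-patient cohort

`build_paper_fixture()` rebuilds the validation cohort from the
cross-tabulated counts in the published results narrative. Those counts pin
the analysis down completely: 47 patients; 8 screen-detected
distant-metastasis patients (4 positive on both modalities, 2 PET-only —
one rib-site, one with a 6-mm CT lesion read as benign — and 2 CT-only with
multiple 4-mm lesions); one 15-mm CT false positive; 3 screening second
primaries imaged on both modalities but scored 0 for distant metastases; 4
double-negative patients whose metastases manifested during follow-up; 2
follow-up second primaries with lung lesions of ambiguous origin (the two
exclusions that give the evaluable n = 45); and 5 patients without
locoregional control, exactly one of them a double-negative
distant-metastasis patient (giving n = 40). Attributes that no printed
count pins down — which risk factors co-occur, which site goes with which
patient — are assigned by a fixed canonical order, never randomly, so the
fixture is byte-stable; the risk-factor and site assignments satisfy the
published marginals only, which is all that can be known. One published
count is internally inconsistent (the both-negative group is stated once in
a way implying 35 patients and once as 36; only 35 is consistent with the
12-patient positive union), and the validator therefore checks the event
counts within that group rather than its size. The five patients without
locoregional control are made screen-negative, the only configuration
consistent with both accuracy tables simultaneously.

`validate_fixture()` re-derives more than forty constraints from any cohort
and reports expected versus observed for each, so a single flipped call or
misplaced flag is caught.

## The simulator

`simulate_cohort()` emulates the screening setting for property-based
testing: truth flags drawn at 26 % distant-metastasis and 11 %
second-primary prevalence (the validation cohort's rates); pulmonary lesion
diameters from a two-component lognormal mixture truncated at the 5-mm
limit (modes near 3.5 mm and 12 mm — the analysis only needs mass on both
sides of the cut-off, and small pulmonary metastases cluster just below
resolution limits while evident ones are centimetre-scale); 10 % of
metastatic index lesions outside the chest CT field; CT detection of
pulmonary lesions at a size-independent rate and PET detection by size band
(zero below 5 mm). The per-band and per-site rates default to values whose
*implied marginal* sensitivity is 0.50 for each modality, with specificity
0.97 (CT) and 1.00 (PET) — the validation study's operating point;
`implied_accuracy()` returns those marginals exactly, and large-sample
empirical estimates must recover them. CT false positives are drawn at
supra-limit sizes (like the 15-mm case), which is why the combined rule's
implied specificity equals PET's. Likert scores are emitted from per-truth
distributions over 1–5 for recorded lesions.

The simulator deliberately does not emulate reader correlation between
modalities, time-to-event structure, lesion counts beyond a multiplicity
flag, or site-specific metastatic patterns; passing tests therefore show
that the estimators and the decision rule behave correctly under the stated
generative structure, not that real readers achieve these operating
characteristics.

## Numerical choices and problem sizes

* Exact-interval agreement with the independent bisection oracle is held to
  10⁻⁹ over all numerators and denominators up to 60 (the scale of every
  table cell, with headroom).
* Large-sample checks use cohorts of 4 000–5 000 patients and paired-score
  samples of 4 000–5 000, sizes at which binomial and AUC standard errors
  are a few tenths of a percentage point — small against the tolerances
  being checked — while the full suite still runs in well under a minute.
* Simulated lesion diameters are rounded to 0.1 mm (the precision a report
  would state) with rounding never allowed to cross the 5-mm limit, so a
  lesion's size band and its recorded size never disagree.
* Degenerate inputs fail loudly and specifically: a positive CT call with
  no sized lesion is a contract error (the size branch cannot be
  evaluated), single-class truth makes the ROC undefined, and an empty
  analysis set aborts the accuracy run.

## Limitations

The package consumes reader calls, not images; everything upstream of the
binary call and the Likert score (scanner protocols, SUV thresholds,
interobserver variability) is out of scope. The reference standard
inherits the limits of a 12-month window: late metastases count as absent,
and the ambiguous-origin exclusion removes exactly the patients in whom
screening performance cannot be defined. The reconstructed cohort supports
the accuracy surface exactly but the ROC surface only structurally, as
discussed above.
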