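---
title: "Methods: EHR phenotyping of cancer site and metastatic status"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHR phenotyping of cancer site and metastatic status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncophen)
```

## The phenotyping problem

Large embedded studies in oncology need two clinical characteristics for
every patient — cancer site and metastatic status — but rarely have the
budget for chart review at cohort scale. Both must instead be derived from
routine EHR data, and every available source is imperfect in a different
way: diagnosis codes are abundant but noisy and often name several cancers
per patient; tumor registries are accurate at diagnosis but cover only part
of a health system's population and are not updated for progression;
treatment-plan goals are informative when present but frequently absent;
medication evidence applies only to sites with recognized
incurable-indication drugs; and free-text notes state metastatic spread
plainly but require assertion-aware text processing. `oncophen` implements
one classifier per source, plus the agreement machinery to quantify how much
the definitions disagree — because with no gold standard, inter-method
agreement *is* the primary quality evidence.

## Site assignment

Diagnosis events are first filtered to a closed calendar window (both
endpoints inclusive — the natural reading of a study window defined in whole
dates) and problem-list entries marked deleted are removed, since deletion
indicates data entry error. Remaining codes map through an all-cancers
grouper to 12 site categories; codes resolving to non-site cancer
categories (metastatic, benign, uncertain behavior, unspecified, lymph-node
disease, other solid tumor with or without distant spread) are excluded
from site counting, as are unknown codes.

Three assignment methods trade sensitivity against specificity:

* **A** keeps every coded category;
* **B** keeps the single category with a strict majority of events
  (`multiple` if none, `nonspecific` if the patient has no valid category);
* **C** keeps the two most frequent categories.

Three numerical choices here were genuinely open and are worth recording:

* **">50%" is strict.** A category holding exactly half the events is not a
  majority; an even two-way split must be reachable as `multiple`, otherwise
  that label could never occur for two-category patients.
* **The counting unit is diagnosis events**, not distinct codes or distinct
  days. Cohorts of this kind accumulate tens of coded events per patient,
  and repetition frequency is exactly the signal the majority rule exploits.
  A `unit = "codes"` switch is provided for sensitivity analyses, as is the
  question of whether duplicate same-day codes should collapse (they do not
  by default).
* **Method C's tie for the second slot** breaks by higher count, then
  earlier first-diagnosis date (an earlier-established cancer is the better
  claim), then site name. Any deterministic, auditable rule would do; this
  one is recorded so results are reproducible run to run.

The methods nest by construction — B-positives ⊆ C-positives ⊆ A-positives
per site — which the test suite asserts on every synthetic cohort. Nesting
has a useful corollary: per-site positive *counts* under the three methods
determine every pairwise 2×2 agreement table exactly
(`reconstruct_nested_tables()`), so published marginal counts are enough to
recompute kappa values without patient-level data. On the packaged reference
counts from a 50,559-patient cohort this reproduces all 36 printed pairwise
kappas to ±0.01, and the three-method Fleiss' kappa for 11 of 12 sites; the
remaining site (other skin cancers, the site with by far the weakest
single-method overlap: 860 vs 6,905 positives) reconstructs to 0.495 where
0.50 was printed, indicating the real assignments depart microscopically
from perfect nesting there. We report the reconstruction and do not patch
it.

## Metastasis classifiers

Each classifier returns `yes`, `no`, or `missing`, where missing means the
source contains no data for that patient and is never imputed:

* **Codes** (`call_icd`): any distant-site code (C77–C79 families plus
  disseminated C80.0) inside the window; regional lymph-node codes
  (C77.0–C77.3 by default, configurable) do not qualify, because regional
  nodal involvement is not distant spread. Never missing — a cancer
  diagnosis is an inclusion criterion, so every patient has code data. The
  packaged family-level code set is a documented, user-replaceable default;
  institutional lists vary.
* **Text** (`nlp_*`): see below. Also never missing; notes are processed
  for the whole cohort and a note-less patient has, by the existential
  summary, no qualifying mention — hence `no`, not `missing`.
* **Registry** (`call_registry`): distant disease at diagnosis; absent
  patients are missing, and a registry `no` is *kept* as no even when later
  sources disagree — stage at diagnosis is a different quantity from
  ever-metastatic, and conflating them is precisely the error the agreement
  analysis should expose.
* **Treatment plan** (`call_treatment_plan`): yes if any goal is Palliative
  or Control (case-insensitive); goals present but all curative-type is no;
  no plan *or* no stated goal is missing, since a plan without a goal
  carries no signal either way.
* **Medications** (`call_medications`): yes if an ordered drug indicates
  incurable disease of a site the patient actually carries (any-category
  site assignment intersected with the sites the drug map covers); patients
  without medication data are missing.
* **Phase I trial** (`call_phase1`): yes for a phase-I-clinic encounter
  whose description contains "Trial" (case-sensitive by default, matching
  how such descriptions are capitalized; a switch relaxes this). The
  absence of trial participation says nothing about metastasis, so the
  classifier never returns `no` — only yes or missing.

**Adjudication** is deliberately conservative: `metastatic` only when codes
and text agree, `not_metastatic` when both say no, `uncertain` otherwise.
Both inputs must be yes/no; feeding a missing call is a programming error
and raises one.

## The text engine

The engine is a transparent rule system with the standard three-attribute
assertion contract: mentions of metastasis terms are found by
case-insensitive lexicon matching on token boundaries (longest match first,
so "metastatic disease" beats "metastatic"; substring hits like "metabolic"
are impossible), then each mention's certainty (positive / negative /
possible), temporality (current / historical), and experiencer (patient /
other) is set by cue phrases within a fixed scope window — 6 tokens by
default, cut by sentence boundaries and scope terminators such as "but".
This fixed-window, cue-list design is the standard desk-scale realization
of assertion classification; it does no parsing and no learning, and the
lexicon, cue lists, and window all live in a YAML-serializable rules object
(`default_assertion_rules()`) so they can be re-engineered per institution.

The patient-level summary is existential: one positive, current,
patient-referring mention anywhere makes the patient `yes`. "Possible"
mentions count as no by default — an uncertain radiology impression should
not, alone, label a patient metastatic — with `possible_as_yes = TRUE`
available, since the opposite convention is defensible for
sensitivity-first use.

## Agreement and balance statistics

Cohen's kappa uses the textbook cell form; pairwise comparisons of
tri-state calls first drop patients where either call is missing and report
`n_used` (`pairwise_kappa_with_missing()`). Degenerate tables with expected
agreement 1 raise a typed error (`oncophen_undefined_kappa`) rather than
returning a number: silently returning `NaN` or 0 would poison downstream
medians. Three-method site agreement is Fleiss' kappa over the nested vote
histogram — with two raters Fleiss' pooled-margin chance correction is
Scott's pi, *not* Cohen's kappa, and the test suite pins that distinction
on a fixed example so the two are never conflated.

Standardized mean differences use the pooled-SD forms: for proportions
`|p1 − p2| / sqrt([p1(1−p1) + p2(1−p2)]/2)`, and for k-category variables
the Mahalanobis generalization over k−1 categories with a pseudo-inverse,
which makes the statistic invariant to the dropped category (checked
numerically). SMD is occasionally described loosely as a difference divided
by a standard *error*; the pooled-SD form is the one that makes the
statistic sample-size-free, is the standard balance diagnostic, and is the
form under which the published reference values (0.77 for portal use, 0.12
for the age distribution) reproduce exactly. Imbalance flags use the
conventional 0.20 (small) and 0.50 (moderate) thresholds.

Display rounding is half-up (0.535 → 0.54) to one decimal for percentages
and two for kappa/SMD, and happens only in the renderers; every internal
computation keeps full precision.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage has known ground
truth. Per patient it draws: true sites (one site for 66%, two for 25%,
three for 9% — matching the multiplicity mix of the reference cohort;
mixture proportional to the reference any-category counts, extra sites
drawn without replacement); a true metastatic state (prevalence 0.40, a
round figure between the ~33% both-classifier and ~44% single-classifier
positive rates observed in practice); and each classifier's tri-state call
conditionally on truth at configured sensitivity / specificity /
missingness. Default missingness mirrors the coverage pattern of the
reference cohort: 0 for codes and text, 0.522 for the registry, 0.690 for
treatment-plan goals, 0.038 for medications. The emitted records then
*realize* those calls exactly — distant-site codes for code-positive
patients (with deleted problem-list met codes and regional-node codes as
distractors that must not trigger), palliative/control goals, indicator
drugs matched to a true site, phase-I encounters, and templated notes whose
mention modifier (positive / negated / possible / historical / family /
none) matches the text call. A medication `yes` drawn for a patient whose
sites have no indicator drug is unrealizable and downgraded to `no`; the
truth table records realized calls.

Classifiers are conditionally independent given truth by default; an
`icd_nlp_correlation` Gaussian-copula knob introduces the positive error
correlation real code/text classifiers exhibit, which lets tests probe how
agreement statistics respond to dependence. Tests verify (a) that the
generated calls recover the configured operating-point arithmetic within 3
standard errors at n = 50,000, (b) that the empirical code–text kappa at
n = 20,000 matches the closed-form kappa for two conditionally independent
raters within 3 delta-method Monte-Carlo standard errors, and (c) that the
full classifier stack recovers the generator's realized truth calls
exactly on a 300-patient cohort. Pipeline-level tests run at 150–400
patients; these sizes keep the default suite under a minute while leaving
every statistical tolerance comfortably non-trivial.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: clinical language beyond the fixed templates (real
negation and family-history constructions are far more varied, so the text
engine's perfect template recall is an upper bound, not a performance
claim); realistic care trajectories or date structure; correlation between
site and metastatic prevalence; and coding idiosyncrasies of any particular
institution's grouper.

## Known limitations

* The packaged grouper, metastasis code set, and medication map are curated
  synthetic stand-ins — institutional tables differ and should replace them
  in any real deployment; all three are plain TSV/YAML and user-loadable.
* The text engine is deliberately desk-scale: no section segmentation, no
  machine learning, no staging knowledge base.
* Kappa confidence intervals and weighted kappa are out of scope, as are
  reweighting adjustments for registry coverage.
* Nested reconstruction assumes exact nesting; real assignments can violate
  it microscopically (the skin-site three-method value above), and the
  reconstruction then approximates rather than reproduces the patient-level
  statistic.
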