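---
title: "Inferring OUD severity from annotated clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring OUD severity from annotated clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oudseverity)
library(dplyr)
```

## The problem

Opioid use disorder (OUD) is a DSM-5 diagnosis graded by the number of
diagnostic criteria a patient endorses out of 11 (craving, tolerance,
withdrawal, hazardous use, role failure, and so on): 0–1 criteria means no
OUD, 2–3 mild, 4–5 moderate, and 6 or more severe. Structured EHR fields
under-document OUD, so clinical *notes* are the richest available signal —
but exploiting them requires reliably labelled text. The workflow this
package supports annotates full sentences of clinical notes with classes
from a fixed schema (e.g. *opioid craving*, *withdrawal*, *psychiatric
condition*), maps the annotated classes onto DSM-5 criteria through a
configured "crosswalk", and infers a per-patient severity score and
category. Around that core it provides the evaluation apparatus such a
study needs: interannotator agreement with discordance lists for
adjudication, severity distributions and positive predictive values (PPVs)
by cohort, and documentation-pattern analytics describing *where* in the
chart the relevant information lives.

## The data model

A corpus is Patient → Encounter → Note → Sentence → Annotation. Encounters
carry a *position* relative to an index encounter (the first observed OUD
diagnosis, or the most recent opioid analgesic order): `historic`, `index`,
or `new`. Notes belong to one of 11 types across 4 encounter settings (ED,
ED-to-inpatient, outpatient, inpatient). Sentences may carry annotations
from multiple annotator layers; the adjudicated consensus layer is named
`"gold"`. Sentence text is optional throughout, so corpora can be fully
de-identified.

Two counting conventions coexist and are deliberately kept apart:

* an **annotated sentence** counts once no matter how many classes it
  bears (`count_annotated_sentences()`, `note_yield()`);
* a **class-frequency event** counts each (sentence, class) assignment, so
  a two-class sentence contributes two events (`annotation_table()` rows,
  `frequency_matrix()` cells).

The first reconciles per-group sentence totals; the second is what
class-frequency heatmaps and co-occurrence statistics are built from.

## The crosswalk and the severity score

The crosswalk is configuration, not code (`inst/extdata/crosswalk.yaml`):
27 classes, 18 of which score, 12 of which carry attributes such as
`temporality ∈ {current, historic}`. Each scoring class maps to a set of
criterion ids in 1..11; the per-patient endorsed set is the union over the
*distinct* classes annotated anywhere in the chart, so duplicated
documentation never inflates the score, and

```
score = |endorsed criteria|,  category = none/mild/moderate/severe by 0–1/2–3/4–5/≥6.
```

The shipped mapping is provisional: it assigns each scoring class a
face-valid criterion (craving→4, tolerance→10, withdrawal→11, drug
seeking→3, vocational consequences→5, opioid-related medical issues→9,
overdose-related classes→8, …) and is expected to be replaced by a
site-specific chart-review-derived mapping where one exists. Every
aggregate the package is validated against depends only on severity
*categories*, not on which particular criterion a class grants.

Three deliberate choices:

* **Severe starts at 6.** A count of 6 must belong to a band, and DSM-5
  places it in "severe"; the band edge is an explicit constant.
* **Forced severity is an override, not a criterion grant.** Documented
  medication treatment for OUD (`OUD treatment`) forces
  `category = "severe"` and sets `forced = TRUE`, leaving the numeric
  score interpretable as a criterion count.
* **Attributes do not change scoring by default.** Whether a *historic*
  mention should endorse a criterion is genuinely unsettled; the config
  syntax supports restricting any mapping to particular attribute values
  (`restrict:`), and the default grants regardless.

```{r severity-example}
cw <- default_crosswalk()
crosswalk_counts(cw)
score_patient(c("opioid craving", "withdrawal", "opioid tolerance"), cw)
score_patient(c("daily tobacco use", "OUD treatment"), cw)
```

## Evaluation: distributions and PPVs

`severity_distribution()` tabulates scored patients into categories per
study group or per index-encounter reason; the index-reason stratification
excludes the control group, which is order-anchored by design and would
otherwise dilute the contrast. `ppv()` computes the positive predictive
value for detecting moderate-or-severe OUD (score ≥ 4 or forced severe)
with either the annotated-patients denominator or the conservative
all-sampled denominator; `pooled_ppv()` sums numerators and denominators
across non-control strata before dividing. PPVs are rounded half-up to two
decimals — the convention of the reported values — and undefined ratios are
flagged, never reported as 0. The strict reading of the positivity rule as
"score strictly greater than 4" is available via
`ppv_table(strict_gt4 = TRUE)`; it differs only for patients at exactly
score 4 and does not reproduce the reference PPV set.

The package ships the reference study's published margins as fixture
constructors (`reference_severity_counts()`,
`reference_annotation_counts()`, `reference_note_yield_counts()`) together
with corpus builders that realize them exactly. The severity fixture's
cross-classification of group × index reason × category is the unique
assignment consistent with both printed margins. Running the scorer over
`reference_severity_corpus()` reproduces the published PPV set (0.50/0.40
CP-RX, 0.90 OUD-TX, 0.71 pooled, 0.84/0.08 by index reason):

```{r ppv-example}
scores <- score_corpus(reference_severity_corpus(), cw)$scores
dist <- severity_distribution(scores, "group", study_design())
ppv(dist, "annotated")
pooled_ppv(dist, "annotated")
```

## Interannotator agreement

The unit of agreement is the (sentence, class) pair — one multi-label
assignment — and batches follow the annotation workflow, one note type per
batch. No chance-corrected coefficient is offered: with an open class set
and multi-label sentences there is no defensible marginal distribution for
a kappa. Instead two set statistics are reported per batch: positive
(Jaccard) percent agreement `100·|A∩B|/|A∪B|` (default) and F1/Dice
`100·2|A∩B|/(|A|+|B|)`; both are 100 when neither annotator produced a
unit, and Jaccard ≤ Dice always. A `strict_attributes` mode extends the
unit with attribute values, which reproduces the observed sensitivity of
agreement to *current*-vs-*historic* attribute discordance.
`discordance_report()` lists the symmetric difference for adjudication.

## Documentation-pattern analytics

`frequency_matrix()` cross-tabulates class events over one of three closed
axes (11 note types, 4 settings, 3 positions), zero-filling absent levels
so matrices are always conformable. `note_yield()` reports, per note type,
the number of notes, the proportion with at least one annotated sentence,
and the mean/SD annotated sentences per annotated note (computed over
annotated notes only; undefined statistics are `NA`). `pair_correlation()`
correlates class frequency profiles across note types — on raw counts,
with Spearman offered because counts span orders of magnitude across
classes — and flags zero-variance profiles as undefined rather than
zeroing them. `patient_cooccurrence()` counts patients carrying both
classes of a pair; the diagonal is the per-class patient count.

## The synthetic-corpus generator

No real clinical corpus can be distributed, so the generator produces
corpora with the study's statistical structure and *known* per-patient
ground truth. Its mechanism:

1. **Design**: five groups (CP-RX, CP-nonRX, OUD-DX, OUD-TX, Control),
   default 20 patients each; per-group probability that a patient's notes
   contain annotatable content (0.80, 0.90, 0.95, 1.00, 0.45 — the observed
   16/20, 18/20, 19/20, 20/20, 9/20); per-group index-reason mix (0.50,
   0.78, 1, 1, 0).
2. **Latent severity**: a zero-inflated, 1..11-truncated Poisson criterion
   count per annotatable patient (defaults per group: zero-inflation
   0.50/0.40/0.16/0.05/1.00 and rate 7/7.5/7/8/–, chosen once so expected
   category mixes approximate the reference severity table), criteria drawn
   uniformly; OUD-TX patients additionally document OUD treatment with
   probability 0.85 (OUD-DX 0.05), forcing the severe category.
3. **Covering-set class selection**: each latent criterion is realized by a
   singleton-mapped scoring class, plus optional extra classes whose
   criteria lie *inside* the latent set — so the emitted chart's score
   equals the latent count exactly, which is what makes ground truth
   recoverable. Controls receive only non-scoring classes, hence always
   score 0.
4. **Noise classes**: the non-scoring classes (history of substance
   misuse 0.60, psychiatric condition 0.45, daily tobacco use 0.35, …) are
   drawn independently per patient; the broad co-occurrence they induce
   with everything else comes from this shared mechanism, not an explicit
   copula.
5. **Chart layout**: annotatable patients get historic/index/new
   encounters; settings, per-setting note-type mixtures, and 1–2 notes per
   encounter follow configured mixtures; annotated-sentence counts per note
   are `1 + NegBin(mu = m−1, size = 1.2)` with per-note-type mean `m`
   defaulting to the observed yields (progress 9.3, H&P 7.3, …). The
   shifted negative binomial is used as the positive-count model because
   its mean is exactly `m`, making the parameter-recovery property
   well-defined. Class events are placed on sentences with index-heavy
   position mass (0.20/0.55/0.25), every chosen class is guaranteed at
   least one sentence, and sentences may carry a second label with
   probability 0.1.
6. **Degradation knobs**: note `dropout` (scores can then only fall below
   truth, never overshoot) and an optional two-annotator layer (A1 = gold;
   A2 with unit-miss and relabel rates) used solely to exercise the
   agreement module.

What the generator does *not* emulate: clinical language (sentence text is
absent), temporal dynamics within a chart, correlation between note-type
choice and severity, and annotator biases beyond symmetric miss/relabel.
Passing the round-trip tests therefore demonstrates the *pipeline's*
correctness — that scoring inverts generation under the crosswalk — not
that the scorer is valid on real notes; the fixture-based PPV
reproductions are the evidence the framework computes the published
quantities from the published counts.

```{r sim-example}
sim <- simulate_corpus(calibrated_sim_config(), cw, seed = 42)
sim$corpus
merged <- inner_join(score_corpus(sim$corpus, cw)$scores, sim$truth,
                     by = "patient_id")
mean(as.character(merged$category) == as.character(merged$true_category))
```

## Numerical and degenerate-input conventions

* PPV rounding is half-up (away from zero) at 2 decimals; base R's
  round-half-even would misreport boundary values.
* Zero denominators and zero-variance correlations are `NA` plus a flag,
  never silently 0.
* Agreement over two empty unit sets is 100 (nothing to disagree about).
* An out-of-range or non-integer score is an error, not a clamp.
* `simulate_corpus()` requires an explicit seed and restores the caller's
  RNG state; identical seeds give byte-identical corpora.

## Problem sizes used in the test suite

Unit and property tests run on toy schemas (5 classes, enumerable by brute
force) and corpora of tens of patients; the round-trip acceptance check
simulates 200 patients per group (1000 total), which recovers 100% of
ground-truth categories at dropout 0 and verifies the configured
annotatable fractions and per-note-type sentence means within 3 Monte-Carlo
standard errors. These sizes were chosen as the smallest at which the
Monte-Carlo checks are sharp.

## Known limitations

* The shipped crosswalk mapping is provisional; sites should substitute a
  chart-review-derived one (the YAML format and validator make that a
  data change).
* Severity is a whole-chart summary; per-encounter trajectories and
  criterion down-weighting are out of scope.
* No sensitivity/NPV: the sampling design contains no gold-standard
  negatives beyond the control group.
* The IAA statistics are percent-agreement measures; they are not
  comparable to kappa values from single-label tasks.
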