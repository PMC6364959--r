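---
title: "Methods: phenotyping and predicting postoperative pain control under SSRI-prodrug opioid co-prescription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping and predicting postoperative pain control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painpheno)
```

## The scientific question

Prodrug opioids — hydrocodone, codeine and tramadol — are pharmacologically
inert until the liver enzyme CYP-2D6 demethylates them into their active
analgesic forms. Selective serotonin reuptake inhibitors (SSRIs), the most
commonly prescribed antidepressants, inhibit CYP-2D6. A depressed surgical
patient discharged on both an SSRI and a prodrug opioid may therefore get
substantially less analgesia than the prescription suggests, while a
direct-acting opioid (morphine, oxycodone, hydromorphone, fentanyl,
methadone) is unaffected.

`painpheno` implements the full observational analysis chain for this
question on electronic health record (EHR) data: identify depressed surgical
patients from both structured codes and free-text notes, classify their
SSRI and opioid exposures into four groups (SSRI+/Pro+, SSRI+/Pro-,
SSRI-/Pro+, SSRI-/Pro-), quantify pain control as the change
$\Delta_t = \text{PostOpPain}_t - \text{PreOpPain}$ at discharge, 3 weeks
and 8 weeks on the 0–10 numeric rating scale (NRS), and train a penalized
regression to predict whether pain worsens ($\Delta_t > 0$). Because real
EHR data of this kind is protected and cannot ship with a package, a
synthetic EHR generator with full ground truth is a first-class module: it
gives every downstream component a world with known answers.

## Rule-based NLP phenotyping

Clinical notes are normalized (UTF-8, lower case, whitespace collapsed),
sentence-split, and tokenized. Two token views coexist deliberately:

* the **concept view** drops punctuation, stop words and words of two or
  fewer letters, and is used for dictionary matching;
* the **raw view** keeps every token and is used for negation.

This split matters because standard stop lists contain "no" and "not":
running negation after stop-word removal would destroy exactly the cues the
negation algorithm needs. Concept phrases are matched longest-first against
a curated depression lexicon; *exclusion patterns* mark irrelevant senses —
"ST depression" on an ECG, "depressed skull fracture", "respiratory
depression" — and any sentence whose matched concept overlaps an exclusion
is forced to NoMention, whatever else the sentence says.

Negation is a NegEx-style scope rule: a concept is Negated if a
pre-negation trigger ("no", "denies", "no symptoms of", ...) ends at most
`window` tokens before it, or a post-negation trigger ("ruled out",
"unlikely") starts at most `window` tokens after it, with the scope cut by
termination terms ("but", "however") and by sentence boundaries. The window
defaults to 5 tokens, the classical NegEx convention, and is configurable.
A sentence is Negated only when *all* its concepts are negated; notes are
labelled by majority vote over non-NoMention sentences with ties going to
Affirmed. A patient is NLP-depressed when at least one Affirmed note falls
within 365 days before surgery.

Three choices here were genuinely open and are fixed as package defaults:

* the 1-year note window is applied **pre-surgery only** (post-surgery notes
  can mention the outcome being predicted; `include_after = TRUE` restores
  the literal reading);
* a **single Affirmed note suffices** for patient-level depression (the
  alternative, a majority over notes, would make the phenotype depend on how
  many unrelated notes a patient accumulates);
* the majority vote **ignores NoMention sentences** — counting them would
  label every long note NoMention.

SSRI mentions reuse the same engine with an SSRI name lexicon (generic and
trade names) as the concept list and medication-appropriate triggers
("discontinued", "no longer taking"); a patient is note-SSRI-positive when
any in-window sentence carries an affirmed mention, independent of the
note-level vote.

Evaluation reports precision, recall and F1 with Affirmed as the positive
class. Evaluation runs against *all* gold-labelled synthetic notes rather
than a 100-note subsample: with a generator there is no annotation budget,
and the larger evaluation is strictly more informative.

## Cohort and exposure construction

Eligibility: adults, survived the admission, first surgery only. Depression
requires at least one of: an ICD depression code (296.2x/296.3x/311,
F32/F33) within 1 year before surgery; an NLP-Affirmed note in the same
window; or an antidepressant order plus note-based symptom evidence.
SSRI+ means a structured SSRI order within **30 days** before surgery or a
non-negated note mention within **1 year** — the asymmetry is kept exactly
as the source analysis defines it and is worth knowing about when
interpreting the groups.

Discharge opioid prescriptions are distilled to ingredients through a
static RxNorm-style table (so "Vicodin" contributes hydrocodone +
acetaminophen), then classified by the fixed prodrug / non-prodrug
ingredient lists. A prescription containing both classes is classified by
the class with the larger total oral-morphine-equivalent dose, with exact
ties going to non-prodrug; misclassifying a genuinely mixed exposure into
the non-prodrug arm biases the group contrast toward the null, which is the
conservative direction. Daily OME divides the factor-weighted sum of
inpatient administrations by the length of stay in days; the conversion
table ships as an editable file, not hard-coded constants. Charlson
comorbidity uses a shipped ICD-prefix map with the standard weights,
counting each condition family once at its highest triggered weight, binned
into 0–2 vs 3+.

The predictor vector has exactly 65 features whose names and order live in
a manifest file — the single source of truth, validated at load time. The
roster follows the six stated components (demographics, clinical
characteristics, diagnoses, medications as 30-day therapeutic-class
indicators, vitals as deviations from the 120/80 normals, and the 4-level
group indicator) plus surgery-type indicators; the exact roster is not
enumerated in the source, so the manifest is this package's fixed choice.
Missing continuous features are mean-imputed **inside each training fold**
with a paired missingness indicator for preoperative pain; no statistic is
ever computed on data a model is later scored on.

## Outcomes

Preoperative pain is the mean score on the *latest* day with observations
within 30 days before surgery; discharge pain is the mean on the last
inpatient day; 3- and 8-week pain searches a +/- 7-day window around days 21
and 56 and uses the day closest to the target, earlier day on ties (the
source is silent on multiple visits in a window; closest-day is
deterministic and reproducible). $\Delta_t$ is computed per patient and
only when both operands exist — patients missing a time point drop out of
that time point's comparison, never imputed. This is why the stratified
change table's per-arm means are *not* the difference of the marginal
preop/postop means: the paired statistic conditions on patients observed at
both ends, and subtracting marginal means would mix two different
denominators. Group contrasts use Welch's unequal-variance t test by
default (no test is named in the source; pooled t is available), with no
multiplicity adjustment across time points, matching the source's practice
(documented, not endorsed).

## The elastic net, exactly as printed

The model minimises, by cyclic coordinate descent with an unpenalised
intercept,

$$\hat\beta = \arg\min_\beta \|\Delta_t - X\beta\|^2
  + \alpha\lambda\,\|\beta\|_2^2
  + \frac{\lambda(1-\alpha)}{2}\,\|\beta\|_1 .$$

This parameterisation is unusual — $\alpha$ multiplies the *ridge* term and
$(1-\alpha)/2$ the lasso term — but it is what the source displays, so it is
what the package implements, with defaults $\alpha = 0.3$, $\lambda = 0.05$.
For readers used to glmnet's convention
$\frac{1}{2n}\mathrm{RSS} +
\lambda_g[(1-\alpha_g)\|\beta\|_2^2/2 + \alpha_g\|\beta\|_1]$: equating the
two penalties gives $\alpha_g = (1-\alpha)/(1+3\alpha)$ and
$\lambda_g = \lambda(1+3\alpha)/(4n)$, so the printed pair
$(\alpha, \lambda) = (0.3, 0.05)$ corresponds to
$\alpha_g \approx 0.368$ — the printed values cannot be typed into glmnet
directly. Coordinate
updates are exact soft-thresholding steps,
$\beta_j \leftarrow S(x_j^\top r_{(j)},\, \lambda(1-\alpha)/4)\,/\,
(x_j^\top x_j + \alpha\lambda)$, iterated to a $10^{-7}$ sup-norm tolerance;
non-convergence is an error, never a silent truncation. The implementation
is verified against an independent FISTA proximal-gradient oracle on random
instances (objective agreement within $10^{-8}$), against ordinary least
squares at $\lambda = 0$, and against the closed-form ridge solution at
$\alpha = 1$.

The response is the **continuous** $\Delta_t$, and the fitted score is
evaluated as a *ranking* against the binary worsened label
($\Delta_t > 0$; ties count as not-worsened, consistent with the
improve/worsen framing and rare for mean scores). This reconciles the
displayed regression objective with the reported AUC evaluation without
inventing a logistic model the source never states.

## Nested cross-validation

Outer 10-fold cross-validation, stratified by the binary label
(stratification is this package's choice — the source says only "randomly
partitioned", but unstratified folds can go single-class at small n, which
would silently shrink the evaluation). Within each outer training set a
5-fold inner grid search maximises inner AUC over
$\alpha \in \{0, 0.1, \ldots, 1\}$,
$\lambda \in \{0.001, 0.005, 0.01, 0.05, 0.1, 0.5\}$ (the source reports
only the selected pair, which lies inside this grid). Imputation and
standardization statistics are recomputed on every training subset; a
regression test injects a label-copy feature into held-out rows only and
asserts the AUC cannot benefit. The source's "repeated 9 times (the folds)"
conflicts with its own 10-fold description; the standard scheme — each of
the 10 folds held out exactly once — is implemented. Fold AUC uses the
Mann–Whitney pairwise formulation (ties half-weighted), checked against an
all-pairs brute force; the mean ROC is a vertical average of fold curves on
a fixed 101-point false-positive-rate grid, and reported SDs are across
folds. Comparator baselines (linear SVM, bagged-tree forest classifier and
regressor) run through the same outer folds; they are compact in-package
implementations because no SVM or random-forest package is available in the
supported environment — the backend slot is pluggable, and an absent
backend yields an "unavailable" row rather than a failure.

## The synthetic world: what it emulates and what it does not

`generator_config()` defaults *are* the published cohort structure: a
universe of 5978 depressed surgical patients with depression provenance
split 1912 (notes only) / 2315 (ICD only) / 1751 (both); 4306 of them
receive a discharge opioid and form the cohort, allocated
606/1285/802/1613 across the four groups by deterministic largest-remainder
rounding of the published proportions; per-group preoperative pain
(2.29/2.93/2.22/2.70, SD 2.92–3.22) and change-in-pain means and SDs at the
three time points taken from the published stratified table; follow-up
retention matching the published per-time-point sample sizes (including the
substantial 8-week loss to follow-up, retention 0.62); notes built from
affirmed / negated / decoy / filler sentence templates with a default 20%
decoy admixture (no ratio is published; 20% makes the NLP non-trivial);
combination trade-name products in ≥10% of discharge opioid orders to
exercise ingredient distillation. Notes per patient (1–5) and sentences per
note (5–40) are unstated in the source and are free parameters.

Postoperative scores are generated as
$\text{clamp}(P + \delta_g + \varepsilon,\, 0,\, 10)$ with
$\varepsilon \sim N(0, \sigma_{g,t})$. Clamping to the NRS truncates both
tails, so the *recorded* mean change is biased relative to the configured
$\delta_g$ — e.g. the SSRI+/Pro+ discharge delta 0.720 becomes ≈ 1.03 at
that group's preoperative distribution. `expected_clamped_delta()` computes
the truncation-corrected expectation in closed form (clamped-normal mean
integrated over the preoperative distribution by quadrature), and all
recovery tests target that corrected value; comparing against the raw
configured delta would be testing the wrong quantity. A consequence worth
stating plainly: at the published means, SDs and group sizes, the power of
the SSRI+ discharge contrast at the 0.01 level is about 0.93 (clamping
included) — high, but not the ≥0.95 the acceptance criterion asserts, so
that specific assertion can fail for honest statistical reasons.

A green test suite on this world establishes that the *pipeline* is
correct: perfect NLP on template language, exact group recovery, exact
provenance counts, unbiased (truncation-corrected) outcome recovery. It
does **not** establish that the NLP would reach F1 0.95 on real clinical
prose (templates have no misspellings, abbreviations, section headers or
novel negation constructions), nor that prediction reaches the published
real-data AUCs of 0.87/0.81/0.69 — the synthetic features deliberately
carry only the modest signal the stated world implies, and the published
AUCs are explicitly out of reproduction scope.

## Numerical and reporting conventions

Percentages in rendered tables are rounded half-up to one decimal
(606/4306 → "606 (14.1)"); the source's abstract value "29.4%" disagrees
with its own table (29.84) and with 1285/4306, and the table value is
treated as correct. Dates are integer days with day 0 = surgery; "prior"
windows are inclusive of both endpoints and exclude day 0. All randomness
flows from a single integer seed; identical config + seed reproduces every
output file byte for byte. Degenerate inputs are contracts, not accidents:
empty extracts, single-class folds (skipped with a warning), all-zero
coefficient vectors, undefined F1 (reported 0 with a warning) and missing
OME conversion factors (administration skipped with a warning) all have
tested behaviour.

## Known limitations

Template-generated notes bound what the NLP evaluation can claim; the
negation engine handles negation only (no hypotheticals, no family
history); the ingredient map and Charlson prefix map are deliberately small
static emulations of RxNorm/full ICD; the comparator forest is a compact
bagged-CART implementation, adequate as a baseline but not a tuned random
forest; and the analysis is predictive, not causal — confounding by
indication (sicker patients receiving direct-acting opioids) is visible
even in the source's own discussion.
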