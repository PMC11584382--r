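---
title: "Methods behind the bapt package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the bapt package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bapt)
```

This vignette is the package's own account of its science: the model and its
assumptions, every tunable parameter with its default and provenance, the
numerical conventions, the genuinely open design choices and how they were
decided, and the limits of what a green test establishes.

## 1. The instrument and its assumptions

The instrument is an additive multi-criteria points system over five patient
attributes: impact of potentially reversible comorbidities (9 levels),
duration of type 2 diabetes (3), BMI category (4), age group (3) and surgical
risk (3) — a state space of 9×3×4×3×3 = 972 hypothetical patients. Additivity
(no interactions between criteria) and within-criterion monotonicity (levels
are ordered worst to best) are *assumptions of the instrument*, not findings:
monotonicity is therefore imposed as a non-strict LP constraint rather than
elicited, and strictness between levels comes only from judged or
dominance-implied pairs.

The canonical rounded points are shipped as constants
(`bapt_instrument()`), **not** recomputed by rounding the elicited means: the
instrument's clinical reference group deliberately adjusted several values
away from nearest-integer rounding (BMI 40–<45: 8.63 → 10, not 9;
BMI 45–<50: 11.58 → 13; age 30–49: 8.76 → 10; risk 2–3 factors: 11.34 → 10).
`draft_rounding()` reproduces nearest-integer drafts and flags exactly these
divergences. The printed instrument, not the arithmetic draft, is the
instrument.

### Category boundary conventions

The published band labels leave boundary placement open; the package fixes
them once:

* diabetes duration: `<4` is `[0, 4)`, `4–8` is `[4, 8]`, `>8` is `(8, ∞)`;
* BMI: half-open `[35, 40)`, `[40, 45)`, `[45, 50)`, `[50, ∞)` — the top band
  is printed "> 50" but the surgical-risk factor is "BMI ≥ 50", and ≥ 50 is
  adopted for **both** so a single BMI value cannot sit in the top band
  without also carrying the risk factor;
* age: `[18, 30)`, `[30, 50)`, `[50, ∞)`; the 45+ risk factor uses exact age,
  so a patient in the 30–49 band may or may not carry it. Patients under 18
  are ineligible; if scored under `force = TRUE` they use the youngest band.

One source inconsistency was decided rather than resolved: the narrative
description says four age and three BMI levels while the scoring table shows
three and four (the 972-state product is identical either way). The scoring
table's layout is adopted.

## 2. Eligibility and the 2–98 range

Eligibility (`check_eligibility()`): age 18–65, BMI > 35 kg/m², HbA1c > 7 %
*despite treatment* (operationalised as the `on_treatment` flag — no
medication-list parsing), at least one reversible comorbidity, no ASA class
IV, no contraindication flag. `contraindication_flags` is an extensible
escape hatch because the full exclusion list exists only in a figure not
fully transcribed in the source text.

The instrument's raw points span 0–100, yet the published achievable range is
2–98. The package reconstructs this as a consequence of cross-criterion
consistency couplings: hypertension counts in both the comorbidity score and
the risk-factor tally; BMI ≥ 50 fills the top BMI band *and* a risk factor;
age drives its band *and* the 45+ factor; eligibility forces ≥ 1 comorbidity
(worth ≥ 2 points). `score_range()` proves min 2 / max 98 by brute force over
a representative profile grid (ages 25/40/47/55, BMIs 37/42/47/55, both
sexes, PE flag, durations 2/6/10, all 255 non-empty comorbidity subsets) and
0–100 with couplings disabled. This reconstruction is an inference — the
source does not say how 2–98 was computed — and the enumeration ships as a
test rather than a claim.

## 3. The elicitation (PAPRIKA-style adaptive DCE)

`preference_store()` holds a weak-preference relation over all 972 states,
pre-seeded with Pareto dominance and kept transitively closed (incremental
closure in C++) after every accepted judgement. Candidate questions are the
24 786 unordered state pairs that differ on exactly two criteria with neither
state dominating — the only pairs worth asking.

**Ceteris-paribus generalisation.** Under additivity, the answer to a
two-criterion trade-off cannot depend on the criteria held fixed, so a
judgement is replicated across every background (provenance
`"transitivity"`). This is the heart of the method: plain state-level
transitivity cannot carry an answer from one background to another, and
without the replication a session would need thousands of questions instead
of ~150. A `generalise = FALSE` store gives the plain-transitivity behaviour
for comparison.

**Question selection.** The production heuristic behind the original
instrument is proprietary. The package's documented, swappable replacement
works at the trade-off *pattern* level (a pattern = the pair of two-criterion
level swaps, background-free): among undecided patterns, pick the one sharing
a partial state with the most other undecided patterns on the same criterion
pair — a greedy proxy for how many open comparisons the answer can reach
through transitivity — with lexicographic tie-breaks. Simulated sessions on
the canonical instrument ask ~140–165 questions (0.6 % of the candidate
pairs; the original tool reports a mean of 24 with its proprietary ordering,
treated as an order-of-magnitude reference only).

**Indifference.** Whether the original respondents could declare indifference
is not stated ("forced to choose" suggests not); both modes are provided.
`simulate_respondent(..., forced = TRUE)` reproduces forced choice (ties go
to the first state); the LP accepts either.

**Consistency.** A verdict contradicting anything judged or implied raises an
error identifying a chain of prior relations (BFS over base edges); nothing
is silently absorbed. Sessions are fully deterministic given instrument and
respondent, so a seed enters only through simulated truth weights.

## 4. Weight derivation (max-margin LP)

Per respondent: variables `v[c][l] ≥ 0`, worst level fixed at 0, non-strict
monotonicity, best levels summing to 100; each strict judgement contributes
`Σv(a) ≥ Σv(b) + δ`, each indifference an equality; maximise the shared
margin δ, then break ties among optima by minimising `Σv` (smallest
representation, deterministic). `δ ≤ 0` at optimum means the judgement set is
inconsistent and is reported as such — infeasibility is never silent. A
post-solve check re-verifies every judgement at slack ≥ δ (strict) or
exactly (indifference) with tolerance 1e-6. With no strict judgements the
margin is defined as 0 and any monotone normalised solution is returned.

The solver is a small dense two-phase simplex (Dantzig pivoting with
deterministic tie-breaks, switching to Bland's rule after 50(m+n) iterations
to guarantee termination; tolerance 1e-9). No LP library is required.

**What derivation can and cannot recover.** Every ordering a respondent can
express — all two-criterion comparisons — is reproduced exactly by the
derived weights (tested across seeds). The *full* ordering of all 972 states
is, however, not identifiable from two-criterion questions alone: those
questions pin down the pairwise comparisons of level-interval values across
criteria, but not the sign of sums of three or more intervals. Two weight
vectors consistent with the complete elicitable information can order
multi-criterion pairs differently, so remaining ambiguity is reported rather
than resolved (the package deliberately does not invent >2-criterion
questions). Exact full-order recovery *is* guaranteed — and tested — for
two-criterion instruments, where every state pair is elicitable.

## 5. Comorbidity rescaling and aggregation

The elicitation treats comorbidity impact as one nine-level attribute;
scoring needs additive per-condition points. `rescale_comorbidities()`
multiplies each condition's mean weight by `max(means)/sum(means)`, so the
rescaled values sum to the criterion weight. This rule is reverse-engineered:
it reproduces all eight published normalised values to ±0.01 and is therefore
adopted as canonical; whether the original analysis performed it inside or
outside the elicitation software is unknowable from the source.
`aggregate_weights()` is a plain per-level mean / sample SD across
respondents (nine clinicians in the original panel).

## 6. The synthetic cohort: a stated world

`synth_config()` defaults are the published referral-cohort marginals: age
52 ± 8.7 (truncated 18–65), 57.1 % female, BMI 46.1 ± 7.0 (> 35),
HbA1c 8.77 ± 1.5 (> 7), hypertension 86.3 %, dyslipidaemia 85.2 %, sleep
apnoea 66.0 %. Prevalences not reported as headline numbers were computed
from the published per-bin counts (joint pain 0.555, NASH 0.123, renal
impairment 0.075, reproductive issues 0.209; duration mix 0.116/0.281/0.603);
albuminuria and PE risk are unreported and set once to 0.15 and 0.10 as
plausible clinic values. Two couplings mirror reported gradients:
hypertension mildly increases with age (logit slope 0.3 per age SD) and
diabetes duration shortens with youth (slope 1.2). Indigenous status
(21.9 %) is a passthrough column, unused by the score.

Outcome defaults come from published anchors: percent weight loss
N(23, 9) **independent of score** (the "20–25 % across all scores" finding);
percent HbA1c improvement `−5.8 + 0.696 × score + N(0, 12)` (fitted once
through the two printed anchor bins: ≈11.8 % at score ≈25, ≈46.4 % at ≈75);
oral-medication discontinuation `logit⁻¹(−2.2 + 0.05 × score)` (≈48 %
overall, rising with score); insulin discontinuation Bernoulli(0.7)
independent of score; AQoL-4D change N(0.058, 0.277) below score 40 and
N(0.174, 0.235) at 40+; comorbidity status unchanged/improved/resolved at
0.20/0.45/0.35 independent of score; adverse events Poisson(0.15),
score-independent (the instrument was poor at predicting them). All
continuous draws are truncated by rejection with a hard cap and an error —
never silent resampling beyond the cap. Everything is deterministic given
the seed (outcomes use `seed + 1`).

**What a green pipeline test establishes — and what it does not.** The
generator encodes the qualitative signature of the pilot evaluation (flat
weight loss, rising HbA1c improvement, oral-medication discontinuation and
remission with score, larger AQoL gains above 40). A green end-to-end test
therefore shows the *pipeline* detects a signature that is present; it is not
evidence about the clinical cohort, whose record-level data are
government-held. The generator draws comorbidities independently (given the
age coupling), has no measurement error, no loss to follow-up, no procedure
mix, and its parameters are set, not estimated by likelihood.

## 7. Analysis conventions

* Stratification uses the published integer bins 10–19 … 70–79, inclusive at
  both ends; out-of-range scores are counted and flagged, never silently
  dropped.
* Across bins: classic one-way ANOVA (equal-variance F) for interval
  variables, Pearson chi-square for categorical ones; both match the stated
  analysis toolkit. The source does not name the two-group test behind its
  cut-point p-values: Welch's t-test (means) and Pearson chi-square without
  continuity correction (proportions) are adopted, both pure functions of the
  table.
* Cut-point groups are `[min, c)` vs `[c, ∞)` for c in 50/55/60 years and
  40/45/50 kg/m², matching "18–49 vs 50 and over".
* Remission: HbA1c strictly below 6.5 % *and* no insulin *and* no oral
  agents; any missing field makes the record indeterminate and excluded from
  denominators with a count.
* The AQoL minimum important difference of 0.06 is compared with ≥ at the
  boundary (the source states no convention).
* Missing follow-up is handled by complete-case analysis with explicit
  exclusion counts; no multiple-testing correction is applied (none was in
  the source analysis).
* Published group-level HbA1c improvements do not recompute exactly from the
  rounded group means (rounded 8.2 → 7.3 gives ≈11.0 %, printed 11.8 %),
  implying unrounded patient-level inputs; such values are treated as
  qualitative anchors only.

## 8. Known limitations

* The question-selection heuristic is a documented stand-in for a proprietary
  one; question *counts* are not comparable, only the elicited information.
* Full-state rank ambiguity after a complete session is intrinsic to
  two-criterion questioning (section 4); the max-margin point is one
  defensible representative of the feasible set, not the only one.
* The 2–98 range proof enumerates representative ages/BMIs/durations per
  band, which suffices because points are piecewise constant within bands.
* The synthetic world is a testbed, not a calibrated model of any clinic.
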