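---
title: "Methods: rule-based phenotyping of PWUD hospitalizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based phenotyping of PWUD hospitalizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The phenotyping problem

Hospitalizations of people who use drugs (PWUD — here: cocaine,
methamphetamine, fentanyl, heroin; excluding alcohol and cannabis) are
poorly captured by billing codes alone: ICD codes are specific but
insensitive, because drug use is often recorded only in the social-history
prose of the chart. `pwudcohort` implements a four-domain rule set over an
encounter's electronic record, flagging the encounter for cohort inclusion
when **any** domain fires:

* **B — biomarkers.** A positive urine toxicology for any of opiate,
  fentanyl, oxycodone, methadone, cocaine, amphetamine, or suboxone; or a
  positive hepatitis C antibody **conjoined** with a positive or
  quantifiable HCV viral load. The antibody alone is not enough — resolved
  past infection carries no information about current use.
* **D — diagnosis codes.** ICD-10 codes in the families F11, F14, F15,
  T400–T406, T436, or B18.2, and six ICD-9 hepatitis C codes. ICD-10
  matching is by dot-stripped prefix (`F11.20` and `T40.2X1A` qualify);
  ICD-9 matching is dot-stripped exact equality. Inactivated and historical
  diagnoses count the same as active ones.
* **M — medications for opioid use disorder.** Sublingual buprenorphine or
  oral methadone in outpatient medication reconciliation, given during the
  hospitalization, or prescribed at discharge. Oral methadone is dispensed
  through licensed programs rather than discharge prescriptions, so a
  methadone/discharge-prescription record is accepted but marked anomalous
  in its evidence string.
* **N — note text.** Keyword detection over every note of the encounter
  (nursing, physician, discharge summary, emergency) against a curated
  lexicon of 26 drug names, route abbreviations, and substance-use phrases,
  tolerant of single-typo misspellings.

The unit of analysis is the hospitalization encounter, not the patient:
each admission is a separate opportunity for treatment initiation, so
repeat admissions are deliberately not deduplicated.

Included encounters are partitioned into the 15 non-empty Venn cells of
\{B,D,M,N\}. Two cells anchor the disparity analysis: the **highly
documented** group (`BDMN`, all four domains) and the **minimally
documented** group (`N` only — the encounters a code-based definition would
have missed entirely).

## The keyword matcher

The matcher is lexicon-driven and span-producing: every detection is an
auditable `(offset, matched text, lexicon entry, distance)` record, so a
reviewer can trace each N flag to the exact characters that triggered it.

**Tokenization.** Tokens are maximal runs of letters and digits; all
punctuation and whitespace are boundaries. Offsets are 0-based, half-open,
character-indexed into the original text. Matching is case-insensitive by
default, since the curated lexicon mixes `FENTANYL` and `heroin`.

**Distance metric.** Approximate matching uses the optimal string alignment
(restricted Damerau–Levenshtein) distance: unit-cost substitutions,
insertions, deletions, and adjacent transpositions. Transpositions are
first-class because they dominate clinical typos (`herion`); plain
Levenshtein would price that error at 2 and miss it under a budget of 1.
The default budget `max_distance = 1` accepts exactly one typo. The kernel
is compiled (Rcpp), with a pure-R dynamic-programming oracle kept in the
test suite for cross-validation.

**Short-token rule.** Entries whose longest token has four or fewer
characters (`IVDU`, `IVDA`, `SUD`, `OUD`, `PWID`) are matched exactly only,
and fuzzy matching applies only to tokens of at least
`min_token_len_for_fuzzy = 5` characters. One edit on a 3–4-letter acronym
reaches far too much of the vocabulary (`SUD` ↦ `sun`, `sad`, ...);
the word-boundary rule already prevents `SUD` from firing inside
"sudden".

**Phrases.** Multi-word entries match consecutive token runs, each word
under the same exact/fuzzy rule, with any punctuation or whitespace as
separator — so `injection-drug  use` matches `injection drug use`. A span's
distance is the maximum per-word distance, which keeps every reported
distance within the configured budget. For a single entry, overlapping
candidate spans are resolved lowest-distance first, then leftmost, then
longest; overlapping matches of *different* entries are all reported.

**Deliberate non-goals.** No negation or uncertainty handling ("denies
IVDU" still fires N), no section segmentation, no semantic models, and no
exclusion contexts for `Methadone`/`suboxone`/`FENTANYL` prescription
mentions. These mirror the presence-only design whose precision cost is
exactly what the chart-review PPV quantifies.

## Evaluation statistics

**PPV.** Chart review of a sampled subcohort is the gold standard;
`ppv()` reports confirmed/reviewed with an exact Clopper–Pearson 95%
interval and whole-percent rounding half away from zero (53/99 → 54%).
Review samples are simple random samples without replacement, drawn
deterministically from a seed; the defaults review 10% of the D-only cell
and 35% of the N-only cell.

**Odds ratios.** 2×2 tables have fixed orientation — rows: exposure level
of interest then reference; columns: outcome group 1 then group 2 — so
`or = (a·d)/(b·c)`, with the Woolf interval
`exp(log or ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d))`. Woolf was chosen because
it reproduces the published intervals for both benchmark tables to the
displayed precision. With exactly one zero cell the Haldane–Anscombe 0.5
correction is applied to all cells and flagged; opposing zeros in a cross
pattern are an error, not a number. Outcome is coded as membership in the
highly documented (BDMN) group; reference exposures are the minoritized
race/ethnicity group and the 1st–2nd SVI quartiles (quartile 1 = most
vulnerable).

**Adjusted models.** `fit_logistic()` is a maximum-likelihood binomial
logit fit (IRLS via `stats::glm`; relative convergence 1e-8, at most 100
iterations) with Wald intervals `exp(β ± 1.96·SE)`. Rows with missing
covariates are dropped and counted — missing SVI is handled by listwise
deletion, with the excluded count reported, rather than by a missing
category. Perfect separation is surfaced as a warning and a `converged =
FALSE` flag with estimates still returned. The disparity report fits
BDMN-vs-N-only membership on race, SVI (3rd–4th vs 1st–2nd), age, and sex,
so the race aOR is adjusted for age, sex, and SVI and the SVI aOR for age,
sex, and race, from one model.

On a 2×2-expanded dataset the logistic MLE equals the closed-form
cross-product odds ratio; the test suite checks this equivalence to 1e-6,
keeping the regression and the contingency-table routes mutually
validating.

## The synthetic EMR generator

No deposited encounter data exist for this design, so the generator is a
first-class module: it emulates the *marginal* structure of the study
cohort and attaches a ground-truth `truth_pwud` label that downstream
stages never see.

Defaults encode the study conditions: 4548 encounters; age ~ N(47.9,
13.8²) years; 62.4% male; 34.8% racially/ethnically minoritized; SVI
quartiles 45.5%/54.5% low/high with 0.4% missing (to force the
missing-data path); length of stay ~ N(38.7, 26.3²) days truncated at 0;
94.5% English-speaking. Signal channels are Bernoulli draws conditional on
`truth_pwud`: per-analyte toxicology positivity, HCV antibody and viral
load, qualifying-code assignment (0.55 vs 0.10), MOUD records (0.35 vs
0.02), and keyword mentions in notes (0.75 vs 0.06). The non-PWUD
components are the false-signal rates; they are loose calibrations chosen
once so that **every** Venn cell is populated at the default size — cell
counts and synthetic PPVs are emergent, not targets, and per-analyte rates
conditional on cohort route are not reported quantities anywhere, so they
were set to plausible magnitudes and left alone.

Notes are assembled from a sentence-template bank per note type. Planted
keywords appear as standalone tokens, perturbed by exactly one edit
(uniform over substitution/insertion/deletion/adjacent transposition) with
probability `misspelling_rate` — only for fuzzy-eligible keywords, since a
misspelled exact-only acronym is by construction undetectable and would
conflate generator noise with matcher behavior. Non-PWUD encounters can
carry two kinds of decoys: *denial-phrased* true keywords ("Patient denies
heroin.") that do fire N — the realistic false-positive mode of a
presence-only matcher — and *distractor* sentences (e.g. "sudden",
prescribed amphetamine for attention deficit disorder) that are verified,
token by token against the lexicon under the distance oracle, never to
match. The generator does **not** attempt clinically realistic prose,
PHI-like identifiers, repeat patients, or correlations between
demographics and drug-use signals (race/SVI/age/sex are independent of
`truth_pwud` by default); passing tests therefore demonstrate the
pipeline's arithmetic and detection logic, not performance on real charts.

A separate simulator, `simulate_disparity_cohort()`, generates
covariates with the study's marginal rates and draws high-documentation
membership from a logistic model with chosen coefficients. The published
adjusted odds ratios (2.07 for White/non-Hispanic; 1.41 for SVI 3rd–4th)
cannot be recomputed without the original individual-level records — as is
true of the cohort totals (4548; 958 D-only; 734 B-only) — so the adjusted
model is validated by parameter recovery instead: across 20 seeds at
n = 20,000 the recovered odds ratios must land within 5% of the generating
values log 2.0 and log 1.4. This is stated as a limitation, not
approximated away.

## Numerical and design choices

* Distances are computed on case-folded tokens; the lexicon is ASCII, and
  offsets always index the original (unfolded) text.
* `max_distance` is capped at 2: beyond that the acceptance band swallows
  whole short words.
* The review-sample size accepts either a fraction (`round(f · cell)`) or
  an absolute n, since study reports mix both forms.
* Venn cell keys are canonical subset strings in fixed B, D, M, N order;
  the empty subset is excluded from the partition by construction, and a
  conservation check (Σ cell sizes = total included) runs on every build.
* PPV percent rounding is half-away-from-zero, not banker's rounding —
  `round()` in R would turn 53.5% into 54% only by accident of floating
  point.
* The ICD-9 hepatitis C code occasionally typeset as `0.70.41` is read as
  the standard `070.41`, consistent with its siblings; the shipped code
  table documents this in a header comment.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  so cohorts, notes, samples, and simulations are bit-reproducible, and
  run summaries record lexicon version, schema version, and seeds.

## Problem sizes used in validation

The shipped tests exercise: the distance kernel against an independent DP
oracle on 10,000 random string pairs (length ≤ 10, 4-letter alphabet);
recall of every lexicon entry planted verbatim and of every fuzzy-eligible
entry under forced misspelling (5 replicates each); 1,000 distractor notes
for the `SUD`/"sudden" boundary property; marginal recovery at n = 10,000
(4 standard errors); full pipeline runs at n = 4,548 (partition shape) and
n = 300–800 (determinism, PPV brute-force relabeling); and 20 × n = 20,000
parameter-recovery fits. These sizes were chosen to make sampling error
negligible relative to each tolerance.

## Known limitations

Negation, temporality ("remote history of"), and clinician-specific
shorthand are out of scope; the matcher's precision on real charts is an
empirical question that only chart review can answer. The generator's
independence assumptions mean synthetic disparity estimates are null by
construction unless effects are injected via the logistic simulator.
Methadone prescribed for pain (e.g. sickle cell disease) is
indistinguishable from OUD treatment in this data model and is knowingly
misclassified, matching the rule set's real-world failure mode.
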