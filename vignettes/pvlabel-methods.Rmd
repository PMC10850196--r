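---
title: "Methods: predicting safety label changes from spontaneous reports"
author: "pvlabel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting safety label changes from spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`pvlabel` turns a spontaneous adverse-drug-reaction reporting database into
a supervised learning problem: will a given (suspected drug, adverse
reaction) pair have the reaction added to the drug's package insert as a
clinically significant adverse reaction (CSAR)? This vignette documents the
statistical machinery, the assumptions behind each stage, the defaults and
why they were chosen, and what the synthetic benchmark does and does not
establish about real data.

# Data model and cleaning

A report database has four normalized tables keyed by `case_id`: DEMO (one
row per case: demographics, quarter received, number of reports received
for the case), DRUG (one row per drug entry, with role `suspected` /
`concomitant` / `interacting`, start date, over-the-counter flag, action
taken, rechallenge status), REAC (one row per reported reaction: MedDRA
preferred term, onset date, outcome) and HIST (medical history). The unit
of cleaning and counting is the case × reaction record; all tabulation uses
suspected-role drug entries only.

Three exclusion rules are applied in order:

1. **Pre-administration onsets** — a record is removed when its onset date
   strictly precedes the earliest start date among the case's suspected
   drugs. When either date is missing the record is retained: exclusion
   requires positive evidence of the anomaly, and dropping undated records
   would also bias the missingness features.
2. **Duplicates** — of records sharing (case id, preferred term, onset
   date), one is kept. Rows are canonically sorted before deduplication so
   the retained set is invariant to input order. Report versions are
   modeled as a per-case count (the `version` column), so all rows of a
   duplicate set carry the same version and keeping any one of them is
   equivalent to keeping the most recent follow-up.
3. **Over-the-counter drugs** — records of cases whose suspected drug is an
   OTC product are removed.

The exclusion log satisfies `excluded + retained = input` exactly, and
`clean_reports()` is idempotent; both properties are tested.

# Preferred-term grouping

Reactions are tabulated per target disease, not per raw preferred term: the
packaged `grouping.csv` maps 144 preferred terms onto 75 target diseases
(e.g. "Blood potassium increased" and "Hyperkaliemia" both count toward
hyperkaliemia). Matching is exact after case-folding and whitespace
normalization — label names and MedDRA terms are controlled vocabulary, so
fuzzy matching would only add false merges. A term may belong to at most
one disease; the loader rejects violations. The file is an editable
two-column CSV so users can extend the grouping; standardized MedDRA query
(SMQ) expansion is out of scope because SMQ content is licensed.

# Disproportionality statistics

For a pair at a cutoff quarter, patients (unique case ids among reports
received on or before the cutoff) are cross-classified into the 2×2 table
(a, b, c, d). A patient counts toward the drug margin if the drug appears
among their suspected entries and toward the disease margin if any of their
reported terms maps to the disease; the four cells partition all cases with
at least one retained reaction and one suspected drug.

The statistics are

- `ROR = ad/bc`, with Wald interval
  `exp(ln ROR ± z·sqrt(1/a + 1/b + 1/c + 1/d))`;
- `PRR = a(b+d)/(b(a+c))`, with Wald interval
  `exp(ln PRR ± z·sqrt(1/a − 1/(a+c) + 1/b − 1/(b+d)))`;
- Yates-corrected χ²
  `N(|ad−bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))`, floored at 0 when
  `|ad−bc| ≤ N/2` (the same capping `stats::chisq.test` applies, which the
  tests use as an independent oracle);
- Index A = `100·a/(a+c)` and Index B = `100·a/(a+b)`.

Numerical conventions: a zero denominator makes the statistic *undefined*,
which is a value (`NA`), never an exception — screening pipelines meet
sparse tables constantly. Logs are natural. The confidence level defaults
to 0.95 (`z = 1.959964`). There is no continuity correction by default
because the plain formulas have none; `haldane = TRUE` adds the
conventional 0.5 to every cell for users who want finite estimates on
sparse tables. The conventional signal rule flags a pair when `a ≥ 3`,
`χ² ≥ 4` and `PRR ≥ 2`; an undefined statistic fails its threshold. The
"cumulative number of reports" in the rule is cell `a` — unique patients —
consistent with the patient-level tabulation used everywhere else.

# Cohort construction

**Positives.** Every package-insert revision whose reason is domestic case
accumulation, whose announcement falls inside the analysis period, and
whose disease is covered by the grouping becomes one positive pair. Its
feature cutoff ("as-of quarter") is the announcement minus two quarters
(configurable `lag`): revisions are announced weeks to months after the
underlying investigation begins, so the reporting stream that predicts them
is the earlier one. Revisions for non-domestic reasons exclude the pair
from both classes; revision diseases with no grouping entry are dropped
with a warning.

**Negatives.** Pairs with at least one retained report of the disease
during the period and no listing of that disease on the drug's insert at
period end.

**Matched index dates.** Each negative's as-of quarter is sampled, with a
seed, from the positives' as-of quarters. The obvious alternative — give
every negative the period's final quarter — turned out to be a structural
leak: with a single shared cutoff all negatives of a disease share one
margin denominator, so their feature vectors collapse onto a small set of
exactly duplicated points, and a flexible classifier learns to recognize
positives as "computed at a different cutoff" rather than by any reporting
signal. In a benchmark with planted null labels (no elevated reporting at
all) that artifact alone yielded test MCC above 0.9. Sampling the
negatives' cutoffs from the positives' distribution is the matched
index-date device standard in case-control pharmacoepidemiology and removes
the artifact completely (null MCC ≈ 0). `negative_as_of = "final"` restores
the single-cutoff behavior for comparison.

An open question we resolved permissively: a drug revised for disease X may
still contribute negative pairs for other diseases — each pair is treated
as an independent observation.

# Features

The 34 features per pair (`feature_names()`) use only reports received on
or before the pair's as-of quarter; the no-leakage property — mutating or
deleting every later report leaves the vector bit-identical — is tested
directly. Conventions the source data leaves open:

- "New patients from k quarters ago" counts patients first received exactly
  in quarter `as_of − (k − 1)`; the four windows are disjoint single
  quarters.
- "Quarters since first report" is inclusive of both the first report's
  quarter and the as-of quarter; mean patients per quarter divides the
  cumulative patient count by it.
- Days to onset is `onset − suspected-drug start` in whole days, per
  patient the earliest such interval; negative values cannot occur after
  cleaning.
- "Missing values per case" counts empty entries among sex, age band,
  weight band, onset date, drug start date, outcome (unknown counts as
  missing) and medical history — the fields a case-quality reviewer would
  check.
- "Reports per case" is the mean of the per-case version count.

Pairs whose cases all lack usable dates have missing onset summaries; these
are imputed with the median time-to-onset of the same disease on *other*
drugs (per-drug medians at the pair's cutoff, median across donor drugs).
If no donor exists the value stays missing and is encoded as 0, with a
flag, before modeling. Undefined disproportionality values are likewise
encoded as 0 (the log scale's null) with the `dispro_undefined` flag.

**Transforms.** Standardization (default for the RBF-SVM, whose kernel
distances are scale-sensitive) and a quantile transform (training ranks
mapped monotonically onto [0, 1], held-out values by interpolation;
constant features map to 0 / 0.5) are fitted on training folds only and
applied frozen — fitting inside each cross-validation fold, never on test
data.

# Models and evaluation

The estimator surface is deliberately thin: an RBF-kernel SVM (`e1071`),
gradient boosting (`xgboost`) and random forests (`ranger`) behind one
`model_spec()`. The package's own contributions are the selection and
scoring machinery:

- **MCC** as the headline metric — positives are ~1% of pairs, and MCC is
  0 for any degenerate predictor. Any zero factor under the root gives 0 by
  convention; the tests verify MCC against its identity as the Pearson
  correlation of the binary label vectors over every confusion table with
  up to 12 observations.
- **Stratified 7:3 split** and **stratified k-fold cross-validation** with
  k = 5 (a standard choice for cohorts with a few hundred positives; the
  fold seed is shared across feature subsets so comparisons are paired).
- **Exhaustive feature selection**: every subset of the requested sizes is
  scored by cross-validated mean MCC under an explicit subset budget; ties
  break toward smaller subsets, then alphabetical order, making the result
  deterministic. The full 2³⁴ enumeration is infeasible by design; the
  pipeline default enumerates sizes 1–2 over ten candidate features
  (counts, recency, coverage and disproportionality summaries), which is
  the regime the selection typically lands in anyway.
- **Hyperparameter search**: seeded random search, log-uniform over
  C ∈ [0.01, 3000] and gamma ∈ [0.001, 1000], scored by cross-validated
  MCC. Random search is the reproducible, dependency-free member of the
  successive-halving/Bayesian family the operation allows for.
- **Permutation importance** (mean metric drop over seeded column
  permutations) and a **decision-threshold sweep** whose default grid pairs
  the conventional 0.5 with 0.1 — with heavy imbalance the true negatives'
  predicted probabilities concentrate near 0, so lowering the threshold
  trades precision for recall without refitting.

Precision and recall are defined as 0 when their denominator is empty, so
degenerate folds produce finite metrics. A fold that would lack a class is
an error suggesting a smaller k, not a silent skip.

# The synthetic benchmark

`generate_database()` emulates the structures the pipeline must survive:
Poisson report arrival per pair-quarter (the simplest count process
consistent with gradual accumulation), staggered drug market entry,
per-field missingness, death / rechallenge / discontinuation flags,
gamma-distributed onset delays (shape 1.5, scale 20 — median around three
weeks, a long right tail), follow-up versions (1 + Poisson(0.5)), duplicate
rows, OTC drugs and pre-administration onsets. Planted pairs report at
`rate_multiplier` × baseline during the `ramp_quarters` quarters ending at
their revision and appear exactly once in the revision log with a domestic
reason.

Default study conditions, chosen once as the regime the method targets: a
baseline of 0.25 reports per pair-quarter (a sporadic background pair
accrues a case a year); multiplier 16 with an 8-quarter ramp (an emerging
clinically significant reaction reaches a few cases per quarter — the
strong-signal regime in which label changes actually happen); launches
staggered over the first two-thirds of the period; 20% missing dates
(matching the missingness the onset-day imputation exists for).

The standard recovery benchmark (`planted_benchmark_config()`) plants 30
positive pairs among 45 drugs × 50 diseases (2,250 pairs) over 36 quarters
and demands held-out test MCC ≥ 0.8 from the full pipeline; the companion
null run (multiplier 1: revisions logged, reporting unchanged) must score
near 0. The null is as important as the planted run — it is the control
that the measured accuracy comes from reporting signal rather than cohort
geometry (see the matched index dates above).

**What passing does not show.** The simulator draws pair-quarter counts
independently given rates; real reporting has drug-level correlation,
secular trends, stimulated-reporting waves after publicity, and labels
changed for reasons the database never sees. The benchmark therefore
validates the *machinery* — counting, leakage discipline, selection,
scoring — not the achievable accuracy on any real database.

**Calibration check.** Under proportional reporting (drug exposure and
event independent; true odds ratio 1), the 95% ROR Wald interval's coverage
is estimated over 2,000 replicate databases of 4,000 cases with
P(drug) = P(event) = 0.15 — cell sizes deep enough in the asymptotic regime
that the nominal level is attainable; observed coverage sits within three
binomial standard errors of 0.95.

# Problem sizes

Unit tests run on databases of a few hundred to a few thousand reports;
the brute-force oracles (contingency recount, per-report feature recount,
all 2×2 tables with N ≤ 12) are exact. The end-to-end benchmark and the
calibration check run in about ten seconds and one second respectively on
one CPU; the whole suite takes under a minute.

# Limitations

- The packaged grouping covers the 75 target diseases it ships with;
  unlisted label wordings need manual grouping before use.
- The two-quarter lag is a fixed approximation of a variable
  administrative delay.
- Negatives require at least one report of a listed target disease, so the
  model predicts "no label change among screened pairs", not "no label
  change ever".
- Real-database parsing (encodings, dialects of the public JADER export)
  is out of scope; the loader expects the documented CSV schema.
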