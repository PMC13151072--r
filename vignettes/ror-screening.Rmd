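---
title: "Reporting odds ratio screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporting odds ratio screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvror)
```

# The analysis

Spontaneous adverse-event reporting databases are passive collections of
suspected adverse drug reaction case reports. A report names one patient,
one or more drugs, and one or more adverse events coded as MedDRA
preferred terms (PTs), each of which belongs to exactly one primary system
organ class (SOC). Because nobody knows how many patients actually took
each drug, incidence cannot be estimated; what can be estimated is
*reporting disproportionality* — whether an event appears in an index
drug's reports more often than the rest of the database predicts.

`pvror` computes the reporting odds ratio. The counting unit throughout is
the **report** (case): a report contributes at most once to a term's
count, however many of its reactions resolve to that term, but may
contribute to several different terms. For a term, with `a`/`b` index
reports with/without the term and `c`/`d` comparator reports:

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
  \mathrm{SE}(\ln \mathrm{ROR}) = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},$$

with a log-symmetric Wald interval
$\exp(\ln\mathrm{ROR} \pm z\,\mathrm{SE})$. Two comparator designs are
supported: **all other drugs** (the comparator arm is every report not in
the index cohort, so the arms partition the database) and **head-to-head**
(the comparator is another drug's cohort; reports naming both drugs are
excluded from both arms to keep the 2×2 margins disjoint — the count
excluded is logged).

Inference on each tested term uses the exact two-sided Fisher test: the
sum of hypergeometric point probabilities, over all tables with the
observed margins, not exceeding the observed table's probability (relative
tie tolerance 1e-7). The full support is enumerated at any margin size —
the support never exceeds the smaller row total, so exactness is cheap
even against a database-sized comparator — and no normal-theory
approximation is ever substituted.

## Decision rules

* **Minimum-case rule.** A term is tested only when either arm has *more
  than* `min_cases` reports (default 3, strict inequality — the literal
  reading of "more than three cases"). An empty arm suppresses testing
  outright, whatever the other arm holds, since there is nothing to
  compare. Untested terms are reported as `not_tested`, never dropped.
* **Signal classification.** Versus all other drugs a signal requires
  ROR > 1 with the lower 95% bound above 1 (the EudraVigilance-style
  lower-bound criterion). Head-to-head the rule is symmetric: a CI
  entirely above 1 flags the index drug, entirely below 1 flags the
  comparator.
* **No multiplicity adjustment** is applied, matching standard practice in
  this type of screening; the volcano output makes the unadjusted p-values
  visible so reviewers can triage.

# Numerical choices

* **Continuity correction.** 0.5 is added to *all four* cells *only when
  some cell is zero* (Haldane–Anscombe). Unconditional correction was
  rejected because it fails to reproduce published estimates recomputed
  from recovered tables, while the conditional rule reproduces them
  exactly; the `corrected` flag records which estimates used it.
* **z = 1.959964**, the 97.5th normal percentile to the precision commonly
  used by statistical software, rather than 1.96; the difference is below
  reporting precision.
* **Rounding.** Reported tables round half away from zero to 2 decimals
  (percentages to 1 decimal), matching how such results are printed.
  Full precision is kept internally; rounding happens only at the output
  boundary and in comparisons against printed values.
* **Ties and determinism.** Screens sort by descending ROR among tested
  terms with lexicographic tie-breaks; rankings by report count break ties
  the same way. Identical inputs give byte-identical outputs.
* **Degenerate inputs.** Empty cohorts produce warnings and empty (or
  all-`not_tested`) screens, not errors; a fully empty 2×2 table is an
  error; degenerate Fisher margins return p = 1 by convention, logged.

# Data handling policies

Report versioning in JADER-style exports re-submits a case under the same
identifier with an incremented sequence number. The loader keeps the
highest sequence per case (ties: last row read) — the conventional choice
where the source is silent — and counts dropped versions in the load
report. Drug and reaction rows whose case id has no demographic record
(orphans) are excluded and counted, as are duplicate (case, PT) pairs.
All names — drugs, PTs, SOCs — are matched after NFKC normalization,
trimming and case-folding, so case variants coincide.

Report dates carry year–month precision. Window filtering is a closed
interval at that precision; reports with unknown dates are *retained* by
default (and counted), because partial dates are common in real exports,
with `strict = TRUE` available to drop them. Cohort matching defaults to
`any_role` rather than suspected-drug-only, since restriction to suspected
drugs is a stated, configurable analysis choice rather than a universal
convention.

PTs missing from the term map are excluded from SOC-level screens with a
warning but stay in PT-level screens: real exports contain coding lags,
and failing the whole run on one unmapped term would be worse than an
explicit warning.

# Inverse recovery of published tables

Published analyses print ROR [95% CI] but rarely the underlying counts.
Because both the point estimate and the interval are smooth injective-ish
functions of `(a, c)` at fixed margins, an exhaustive search over integer
pairs whose recomputed, rounded values equal the printed ones usually
identifies the table uniquely — `recover_table()` implements this with no
heuristics (soundness: every candidate re-verifies; completeness: the
whole stated space is scanned). For database-scale comparator margins the
`c` range scanned per `a` is derived deterministically by inverting the
point estimate at the edges of its rounding interval, which covers every
`c` able to round to the printed value.

One quirk surfaced in validation: for two recovered tables the published
upper bound sits one unit of the last printed decimal above the Wald value
(consistent with the source software rounding the normal quantile
differently), while the point estimate and lower bound match exactly. The
`slack` parameter (in units of the last printed decimal, default 0)
exists for exactly this situation; the package does not alter its own
formula to chase another implementation's last digit.

# The synthetic generator

`synthetic_config()` defaults describe the study conditions the package is
validated under: an index drug marketed from April 2018 with 323 reports,
a comparator launched June 2021 with 753 reports (unequal reporting
windows are therefore part of the emulation), 997,321 background reports
(998,397 in total), an extraction window of April 2018 – July 2025, a
38-PT / 14-SOC catalogue with background reporting odds of 0.1–5%, and
demographic distributions typical of an elderly oncology population
(about two thirds aged ≥ 70, a modest male excess, physicians reporting
~88%).

Each case draws each catalogue term independently with probability
`odds/(1+odds)`; a planted (drug, term) effect multiplies the background
odds by `target_ror`, which makes the *population* head-to-head ROR equal
`target_ror` exactly — the property the parameter-recovery tests rely on.
Cases whose draws produce no event simply have no reaction rows; forcing a
filler event would bias the planted odds. The generator is deterministic
given its seed and restores the caller's RNG state.

What the generator does **not** emulate: within-case correlation between
events, masking/competition bias, duplicate submissions, drug-name
misspellings, or reporting-rate drift over calendar time. Passing tests
therefore demonstrate correctness of the counting and estimation
machinery under independence, not robustness to those real-data
phenomena.

## Validation problem sizes

Parameter recovery uses 500 replicates at cohort sizes 2,000 vs 2,000
with background odds 0.05 and a planted ROR of 3 (expected cells ≈ 261
and 95, comfortably in the Wald regime): the 95% CI covers the true value
in 93–97% of replicates and the mean log-ROR bias stays below 0.05. Null
calibration repeats 500 screens of 10 null terms and requires at most 5%
of tested terms flagged (the one-sided lower-bound criterion at 95%
implies ≈ 2.5% expected). The Fisher implementation is checked against
full binomial-coefficient enumeration for every table with margins up to
30 (≈ 246,000 tables) and against an independent implementation on random
and database-scale tables.

# Known limitations

* The ROR is a reporting-pattern statistic; nothing here estimates
  incidence, risk, or causality, and crude (unstratified, unadjusted)
  estimation is the only mode offered.
* One published PT value in the validation set admits *no* integer table
  consistent with its printed interval at the stated margins under either
  correction policy; it was evidently computed on different denominators
  and is excluded from the reference fixtures rather than approximated.
* Only PT and primary-SOC levels are supported — no LLT/HLT/HLGT
  hierarchy, and no medical-history table.
* Proportional reporting ratios and Bayesian disproportionality methods
  (IC, EBGM) are deliberately out of scope.
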