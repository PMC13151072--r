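# pvror

Reporting odds ratio (ROR) signal screening for spontaneous adverse-event
report databases in the JADER table layout.

## What this is for

Spontaneous reporting databases — JADER in Japan, FAERS in the US — collect
suspected adverse drug event (AE) case reports, each linking one patient to
one or more drugs and one or more MedDRA-coded events. No exposure
denominators exist, so the only available statistics compare *reporting
patterns*: is event *E* reported disproportionately often with drug *X*?
`pvror` implements that analysis end to end for researchers and
pharmacovigilance pharmacists:

* read, link and deduplicate the three JADER-layout case tables
  (demographics / drug / reaction), with orphan detection and versioned
  re-submission handling;
* map preferred terms (PTs) to their unique primary system organ class
  (SOC) from a user-supplied mapping table (MedDRA is licensed and is not
  shipped);
* build 2×2 report-count tables for an index drug against **all other
  drugs** (classical disproportionality) or against a **named comparator**
  (head-to-head profile comparison), at PT and SOC level;
* estimate RORs with Wald 95% confidence intervals, exact two-sided Fisher
  p-values, a minimum-case rule, and EudraVigilance-style signal
  classification;
* reconstruct the integer contingency tables behind *published* ROR/CI
  values (inverse recovery), and generate synthetic report databases with
  planted effects for validation.

## The statistic

For a term, with `a`/`b` index-cohort reports with/without the term and
`c`/`d` comparator reports with/without it:

```
ROR = (a/b) / (c/d)
SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)
95% CI = exp(ln ROR ± 1.959964 · SE)
```

If any cell is zero, 0.5 is added to all four cells (Haldane–Anscombe
correction) before estimation; tables without zeros are left uncorrected.
Versus all other drugs, a signal requires ROR > 1 with the lower CI bound
above 1; head-to-head, a CI entirely above 1 flags the index drug and
entirely below 1 flags the comparator. Terms are tested only when either
arm has more than three reports. The ROR describes reporting
disproportion, not incidence or risk.

## Worked example

Reconstruct a published head-to-head estimate — ROR 7.17 [1.93–26.64] for
an SOC with index/comparator cohort sizes 323 and 753 — and verify it:

```r
library(pvror)
recover_table(7.17, 1.93, 26.64, n_index = 323, n_comparator = 753)
#>   a c      ror   ci_low  ci_high
#> 1 9 3 7.165605 1.927117 26.64389

compute_ror(contingency_table(9, 314, 3, 750))
#> ROR 7.17 [1.93-26.64]
fisher_exact_two_sided(contingency_table(9, 314, 3, 750))
#> [1] 0.001603774
```

The exhaustive search finds exactly one integer table consistent with the
printed values: 9 of 323 index reports and 3 of 753 comparator reports.
Recomputing on that table reproduces the published estimate to 2 decimals,
and the exact Fisher test confirms the imbalance (p ≈ 0.0016).

A full screening run on a synthetic database with two planted signals:

```r
cfg <- synthetic_config(seed = 42, n_background_cases = 20000,
  index_drug = list(name = "druga", n_cases = 400, launch_date = "2018-04"),
  comparator_drug = list(name = "drugb", n_cases = 800, launch_date = "2021-06"),
  planted_effects = data.frame(
    drug_name = "druga",
    pt_name = c("Atrial fibrillation", "Tumour lysis syndrome"),
    target_ror = c(8, 6)))
dir <- tempfile(); write_synthetic(generate_reports(cfg), dir)

ds <- read_jader(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                 file.path(dir, "reac.csv"))
ds <- filter_period(ds, "2018-04", "2025-07")
screen <- run_screen(ds, cohort_spec("druga"), comparator_spec("all_other_drugs"),
                     level = "pt")
head(as.data.frame(screen)[, c("term","a","c","ror","ci_low","ci_high","fisher_p","signal")], 5)
#>                    term  a   c  ror ci_low ci_high fisher_p       signal
#> 1 tumour lysis syndrome  7  40 9.24  4.116   20.76 2.65e-05 index_signal
#> 2   atrial fibrillation 13 100 6.95  3.868   12.50 2.21e-07 index_signal
#> 3           neutropenia  9 164 2.90  1.470    5.71 5.71e-03 index_signal
#> 4             pneumonia 11 216 2.69  1.458    4.98 4.05e-03 index_signal
#> 5              cataract  2  41 2.54  0.613   10.56 1.95e-01         none
```

Both planted terms top the screen at roughly their planted odds
multipliers. Two background terms are also flagged — screening applies no
multiple-testing adjustment (none is customary in this analysis), so chance
findings are expected and must be triaged clinically.

`volcano_coords()` and `rank_top_terms()` turn a screen into plot-ready
coordinates and top-term listings; `cmd_run()` drives the whole pipeline
from a configuration and writes signals/demographics CSVs plus a run
manifest, and `inst/cli/pvror.R` wraps it for shell use.

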