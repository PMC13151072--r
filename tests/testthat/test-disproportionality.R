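test_that("continuity correction fires only on zero cells", {
  z <- apply_continuity_correction(contingency_table(0, 10, 5, 95))
  expect_true(z$corrected)
  expect_equal(unname(z$cells), c(0.5, 10.5, 5.5, 95.5))
  nz <- apply_continuity_correction(contingency_table(11, 312, 1, 752))
  expect_false(nz$corrected)
  expect_equal(unname(nz$cells), c(11, 312, 1, 752))
  expect_false(apply_continuity_correction(contingency_table(1, 1, 1, 1))$corrected)
})

test_that("ROR point estimates and Wald intervals match frozen references", {
  # uncorrected table whose estimate matches the published 26.51 [3.41-...]
  est <- compute_ror(contingency_table(11, 312, 1, 752))
  expect_equal(round_half_up(est$ror, 2), 26.51)
  expect_equal(round_half_up(est$ci_low, 2), 3.41)
  expect_false(est$corrected)
  # balanced table: identity, CI symmetric about 1 on the log scale
  e1 <- compute_ror(contingency_table(5, 5, 5, 5))
  expect_equal(e1$ror, 1)
  expect_equal(e1$ci_low * e1$ci_high, 1, tolerance = 1e-12)
  # corrected estimate computed by hand: (0.5/10.5)/(5.5/95.5)
  e2 <- compute_ror(contingency_table(0, 10, 5, 95))
  expect_true(e2$corrected)
  expect_equal(e2$ror, (0.5 / 10.5) / (5.5 / 95.5), tolerance = 1e-12)
  expect_equal(round_half_up(e2$ror, 4), 0.8268)
  # published head-to-head SOC value
  e3 <- compute_ror(contingency_table(9, 314, 3, 750))
  expect_equal(round_half_up(e3$ror, 2), 7.17)
  expect_equal(round_half_up(e3$ci_low, 2), 1.93)
  expect_equal(round_half_up(e3$ci_high, 2), 26.64)
  expect_error(compute_ror(contingency_table(0, 0, 0, 0)), "undefined")
})

test_that("estimate invariants hold over random tables", {
  set.seed(101)
  for (i in 1:200) {
    a <- sample(0:30, 1); b <- sample(0:30, 1)
    c <- sample(0:30, 1); d <- sample(0:30, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + b + c + d) == 0) next
    tab <- contingency_table(a, b, c, d)
    est <- compute_ror(tab)
    expect_equal(est$corrected, min(a, b, c, d) == 0)
    expect_lte(est$ci_low, est$ror)
    expect_gte(est$ci_high, est$ror)
    # log-symmetry of the Wald interval
    expect_equal(est$ci_low * est$ci_high, est$ror^2,
                 tolerance = 1e-9)
    if (min(a, b, c, d) > 0) {
      # reciprocity: swapping arms inverts the estimate
      rev <- compute_ror(contingency_table(c, d, a, b))
      expect_equal(est$ror * rev$ror, 1, tolerance = 1e-12)
      # monotonicity in the index event count
      up <- compute_ror(contingency_table(a + 1, b, c, d))
      expect_gt(up$ror, est$ror)
    }
  }
})

test_that("Fisher p-values match enumeration references and conventions", {
  expect_equal(fisher_exact_two_sided(contingency_table(1, 1, 1, 1)), 1)
  # hand enumeration: P(a=3) = P(a=0) = 1/20, two-sided 2/20
  expect_equal(fisher_exact_two_sided(contingency_table(3, 0, 0, 3)), 0.1)
  # enumeration over C(20,10) = 184756: 2*(1 + 100 + 2025)/184756
  expect_equal(fisher_exact_two_sided(contingency_table(2, 8, 8, 2)),
               2 * (1 + 100 + 2025) / 184756, tolerance = 1e-9)
  expect_message(p <- fisher_exact_two_sided(contingency_table(0, 5, 0, 5)),
                 "degenerate")
  expect_equal(p, 1)
})

test_that("Fisher p agrees with stats::fisher.test and is symmetric", {
  set.seed(202)
  for (i in 1:60) {
    a <- sample(0:25, 1); b <- sample(0:25, 1)
    c <- sample(0:25, 1); d <- sample(0:25, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    p <- fisher_exact_two_sided(contingency_table(a, b, c, d))
    ref <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
    expect_equal(p, min(ref, 1), tolerance = 1e-9)
    expect_equal(p, fisher_exact_two_sided(contingency_table(c, d, a, b)))
    expect_equal(p, fisher_exact_two_sided(contingency_table(b, a, d, c)))
  }
  # large-margin exactness, no normal approximation
  big <- fisher_exact_two_sided(contingency_table(9, 314, 2668, 995406))
  ref <- stats::fisher.test(matrix(c(9, 2668, 314, 995406), 2))$p.value
  expect_equal(big, ref, tolerance = 1e-9)
})

test_that("the minimum-case rule reads 'more than three' strictly, per arm", {
  expect_true(min_case_rule(contingency_table(11, 312, 1, 752)))
  expect_false(min_case_rule(contingency_table(2, 8, 2, 8)))
  expect_false(min_case_rule(contingency_table(3, 7, 3, 7)))
  expect_true(min_case_rule(contingency_table(0, 10, 4, 6)))
  expect_true(min_case_rule(contingency_table(2, 8, 2, 8), threshold = 1))
})

test_that("signal classification follows the two significance definitions", {
  est <- function(ror, lo, hi)
    structure(list(ror = ror, ci_low = lo, ci_high = hi), class = "ror_estimate")
  expect_equal(classify_signal(est(2.09, 1.33, 3.28), "all_other_drugs"),
               "index_signal")
  expect_equal(classify_signal(est(0.41, 0.28, 0.60), "head_to_head"),
               "comparator_signal")
  # against all drugs only an elevated lower bound counts
  expect_equal(classify_signal(est(0.41, 0.28, 0.60), "all_other_drugs"),
               "none")
  expect_equal(classify_signal(est(1.5, 0.9, 2.5), "head_to_head"), "none")
  expect_equal(classify_signal(est(1.5, 0.9, 2.5), "all_other_drugs"), "none")
})

test_that("screens flag exactly the planted strong signal", {
  cfg <- synthetic_config(seed = 5, n_background_cases = 4000,
    index_drug = list(name = "druga", n_cases = 1500, launch_date = "2019-01"),
    comparator_drug = list(name = "drugb", n_cases = 1500, launch_date = "2021-06"),
    pt_catalog = data.frame(
      pt_name = c("Nausea", "Pyrexia", "Rash", "Anaemia"),
      soc_name = c("Gastrointestinal disorders", "General disorders",
                   "Skin disorders", "Blood disorders"),
      background_odds = c(0.05, 0.05, 0.05, 0.05)),
    planted_effects = data.frame(drug_name = "druga", pt_name = "Nausea",
                                 target_ror = 20))
  gen <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  p <- write_case_tables(gen$tables, dir)
  ds <- read_jader(p["demo"], p["drug"], p["reac"])
  s <- run_screen(ds, cohort_spec("druga"), comparator_spec("all_other_drugs"),
                  level = "pt")
  flagged <- s$term[s$signal == "index_signal"]
  expect_equal(flagged, "nausea")
  expect_equal(s$term[1], "nausea")  # sorted by descending ROR
  # deterministic given identical inputs
  s2 <- run_screen(ds, cohort_spec("druga"), comparator_spec("all_other_drugs"),
                   level = "pt")
  expect_identical(as.data.frame(s), as.data.frame(s2))
})

test_that("an empty index cohort yields only untested results", {
  tabs <- fixture_from_tables(data.frame(term = "Pyrexia", a = 2, c = 5), 10, 20)
  dir <- withr::local_tempdir()
  p <- write_case_tables(tabs, dir)
  ds <- read_jader(p["demo"], p["drug"], p["reac"])
  expect_warning(
    s <- run_screen(ds, cohort_spec("absent"), comparator_spec("all_other_drugs"),
                    level = "pt"),
    "no cases")
  expect_true(all(s$signal == "not_tested"))
  expect_true(all(!s$tested))
})
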