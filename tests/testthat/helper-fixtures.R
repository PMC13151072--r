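# Shared fixtures and independent oracles for the test suite.

# Write three raw data frames as CSVs and return the paths.
write_raw_tables <- function(demo, drug, reac, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  write_case_tables(list(demo = demo, drug = drug, reac = reac), dir)
}

mini_demo <- function(case_id, report_seq = 1L, sex = "male",
                      age_category = "60s", report_date = "2022-01",
                      reporter_type = "physician") {
  data.frame(case_id = case_id, report_seq = report_seq, sex = sex,
             age_category = age_category, report_date = report_date,
             reporter_type = reporter_type, stringsAsFactors = FALSE)
}

mini_drug <- function(case_id, drug_name, role = "suspected") {
  data.frame(case_id = case_id, drug_name = drug_name, role = role,
             stringsAsFactors = FALSE)
}

mini_reac <- function(case_id, pt_name) {
  data.frame(case_id = case_id, pt_name = pt_name, stringsAsFactors = FALSE)
}

# Independent two-sided Fisher oracle: explicit binomial-coefficient
# enumeration over the support, no dhyper.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  pmf <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
}

# Marginal counts of the 323-report index cohort used as the demographics
# reference (an elderly, male-skewed, physician-reported population).
index_cohort_margins <- function() {
  list(
    sex = c(male = 200L, female = 115L, unknown = 8L),
    age = c("30s" = 6L, "40s" = 14L, "50s" = 30L, "60s" = 55L,
            "70s" = 120L, "80s" = 80L, "90s" = 9L, unknown = 9L),
    year = c("2018" = 62L, "2019" = 99L, "2020" = 40L, "2021" = 26L,
             "2022" = 60L, "2023" = 24L, "2024" = 11L, "2025" = 1L),
    reporter = c(physician = 283L, pharmacist = 23L,
                 other_health_professional = 9L, consumer = 1L, others = 7L))
}

# Published head-to-head estimates (margins 323 vs 753) with the integer
# tables the inverse-recovery oracle reconstructs for them. `fields` lists
# which printed values identify the table uniquely at zero slack; for the
# other bounds the source software's last digit differs by one ulp.
published_head_to_head <- function() {
  list(
    list(term = "Atrial fibrillation", ror = 26.51, lo = 3.41, hi = 206.24,
         a = 11, c = 1, fields = c("point", "ci_low")),
    list(term = "Cardiac disorders", ror = 3.48, lo = 1.74, hi = 6.99,
         a = 20, c = 14, fields = c("point", "ci_low", "ci_high")),
    list(term = "Nervous system disorders", ror = 6.92, lo = 2.70, hi = 17.71,
         a = 17, c = 6, fields = c("point", "ci_low", "ci_high")),
    list(term = "Immune system disorders", ror = 7.17, lo = 1.93, hi = 26.64,
         a = 9, c = 3, fields = c("point", "ci_low", "ci_high")),
    list(term = "Tumour lysis syndrome", ror = 22.16, lo = 5.11, hi = 96.09,
         a = 18, c = 2, fields = c("point", "ci_low", "ci_high")),
    list(term = "Liver disorder", ror = 4.78, lo = 1.62, hi = 14.10,
         a = 10, c = 5, fields = c("point", "ci_low", "ci_high")),
    list(term = "Neuropathy peripheral", ror = 11.82, lo = 1.38, hi = 101.62,
         a = 5, c = 1, fields = c("point", "ci_low")))
}

# Published versus-all-other-drugs estimates (margins 323 vs 998,074).
published_vs_all <- function() {
  list(
    list(term = "Immune system disorders", ror = 10.69, lo = 5.51, hi = 20.77,
         a = 9, c = 2668),
    list(term = "Eye disorders", ror = 6.56, lo = 2.10, hi = 20.48,
         a = 3, c = 1424))
}
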