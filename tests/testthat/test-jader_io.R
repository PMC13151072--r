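test_that("case tables parse, with unknown-preserving category coercion", {
  demo <- mini_demo(c("A", "B"), sex = c("male", "hermaphrodite"),
                    age_category = c("70s", "not a bin"),
                    reporter_type = c("physician", ""))
  paths <- write_raw_tables(demo, mini_drug("A", "Romidepsin "),
                            mini_reac(c("A", "B"), c("Pyrexia", "Nausea")))
  raw <- read_case_tables(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(raw$demo$sex, c("male", "unknown"))
  expect_equal(raw$demo$age_category, c("70s", "unknown"))
  expect_equal(raw$demo$reporter_type, c("physician", "unknown"))
  expect_equal(raw$drug$drug_name, "romidepsin")  # trimmed + case-folded
  expect_equal(nrow(raw$demo), 2)
})

test_that("missing files and missing required columns are distinct errors", {
  paths <- write_raw_tables(mini_demo("A"), mini_drug("A", "x"),
                            mini_reac("A", "Pyrexia"))
  expect_error(read_case_tables("/nonexistent.csv", paths["drug"], paths["reac"]),
               "not found")
  bad <- data.frame(not_case_id = "A", report_seq = 1)
  bad_path <- file.path(dirname(paths["demo"]), "bad_demo.csv")
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_case_tables(bad_path, paths["drug"], paths["reac"]),
               "case_id")
})

test_that("orphan drug and reaction rows are excluded and counted", {
  paths <- write_raw_tables(mini_demo("A"),
                            mini_drug(c("A", "GHOST"), c("x", "y")),
                            mini_reac(c("A", "PHANTOM"), c("Pyrexia", "Nausea")))
  ds <- read_jader(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(ds$load_report$n_orphan_drug, 1)
  expect_equal(ds$load_report$n_orphan_reac, 1)
  expect_equal(nrow(ds$drugs), 1)
  expect_equal(nrow(ds$reactions), 1)
})

test_that("version dedup keeps the highest report_seq; linkage is idempotent", {
  demo <- mini_demo(c("X", "X", "Y"), report_seq = c(2L, 1L, 1L),
                    sex = c("female", "male", "male"))
  paths <- write_raw_tables(demo, mini_drug("X", "d"), mini_reac("X", "Pyrexia"))
  raw <- read_case_tables(paths["demo"], paths["drug"], paths["reac"])
  ds <- link_and_dedup(raw)
  expect_equal(nrow(ds$cases), 2)
  expect_equal(ds$cases$sex[ds$cases$case_id == "X"], "female")  # seq 2 wins
  expect_equal(ds$load_report$n_versions_dropped, 1)
  # applying the dedup again changes nothing
  ds2 <- link_and_dedup(list(demo = ds$cases, drug = ds$drugs,
                             reac = ds$reactions, provenance = NULL))
  expect_equal(ds2$cases, ds$cases)
  expect_equal(ds2$reactions, ds$reactions)
})

test_that("duplicate (case, PT) pairs collapse, including case variants", {
  paths <- write_raw_tables(
    mini_demo("X"), mini_drug("X", "d"),
    mini_reac(c("X", "X", "X"), c("Pyrexia", "PYREXIA", "Nausea")))
  ds <- read_jader(paths["demo"], paths["drug"], paths["reac"])
  expect_equal(sort(ds$reactions$pt_name), c("nausea", "pyrexia"))
  expect_equal(ds$load_report$n_duplicate_reactions, 1)
})

test_that("unique (case, PT) pair counts match a brute-force census", {
  set.seed(42)
  n <- 5
  ids <- LETTERS[1:n]
  reac <- mini_reac(sample(ids, 20, TRUE),
                    sample(c("Pyrexia", "Nausea", "Rash"), 20, TRUE))
  paths <- write_raw_tables(mini_demo(ids), mini_drug(ids, "d"), reac)
  ds <- read_jader(paths["demo"], paths["drug"], paths["reac"])
  brute <- nrow(unique(data.frame(i = reac$case_id, p = tolower(reac$pt_name))))
  expect_equal(nrow(ds$cases), n)
  expect_equal(nrow(ds$reactions), brute)
})

test_that("filter_period is a closed interval at month precision", {
  demo <- mini_demo(c("A", "B", "C", "D"),
                    report_date = c("2018-03", "2018-04", "2025-07", ""))
  paths <- write_raw_tables(demo, mini_drug("A", "d"), mini_reac("A", "Pyrexia"))
  ds <- read_jader(paths["demo"], paths["drug"], paths["reac"])
  f <- filter_period(ds, "2018-04", "2025-07")
  expect_setequal(f$cases$case_id, c("B", "C", "D"))  # unknown date kept
  fs <- filter_period(ds, "2018-04", "2025-07", strict = TRUE)
  expect_setequal(fs$cases$case_id, c("B", "C"))
  expect_error(filter_period(ds, "2020-01", "2019-01"), "inverted")
})

test_that("filter_period matches a brute-force count and is idempotent", {
  set.seed(7)
  n <- 100
  months <- sprintf("20%02d-%02d", sample(15:25, n, TRUE),
                    sample(1:12, n, TRUE))
  paths <- write_raw_tables(mini_demo(sprintf("C%03d", 1:n), report_date = months),
                            mini_drug("C001", "d"), mini_reac("C001", "Pyrexia"))
  ds <- read_jader(paths["demo"], paths["drug"], paths["reac"])
  f <- filter_period(ds, "2018-04", "2022-12")
  yr <- as.integer(substr(months, 1, 4)); mo <- as.integer(substr(months, 6, 7))
  idx <- yr * 12 + mo - 1
  brute <- sum(idx >= 2018 * 12 + 3 & idx <= 2022 * 12 + 11)
  expect_equal(nrow(f$cases), brute)
  f2 <- filter_period(f, "2018-04", "2022-12")
  expect_equal(f2$cases, f$cases)
})

test_that("generator output round-trips through the reader exactly", {
  cfg <- synthetic_config(seed = 11, n_background_cases = 60,
    index_drug = list(name = "druga", n_cases = 25, launch_date = "2019-01"),
    comparator_drug = list(name = "drugb", n_cases = 40, launch_date = "2021-06"))
  gen <- generate_reports(cfg)
  dir <- withr::local_tempdir()
  write_synthetic(gen, dir)
  ds <- read_jader(file.path(dir, "demo.csv"), file.path(dir, "drug.csv"),
                   file.path(dir, "reac.csv"))
  expect_equal(nrow(ds$cases), 125)
  expect_equal(nrow(ds$reactions), nrow(gen$tables$reac))
  expect_equal(ds$load_report$n_orphan_drug, 0)
})
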