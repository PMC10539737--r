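specs2 <- bin2("a", "b")

test_that("factor specs enforce level and truthy invariants", {
  expect_error(factor_spec("x", c("yes", "yes")), "unique")
  expect_error(factor_spec("x", c("a", "b", "c", "d")), "2 or 3 levels")
  expect_error(factor_spec("x", c("false", "true"),
                           truthy_levels = c("false", "true")),
               "strict subset")
  dx <- diagnosis_factor("depression")
  expect_identical(dx$levels, c("none", "subthreshold", "full-threshold"))
  expect_identical(dx$truthy_levels, c("subthreshold", "full-threshold"))
})

test_that("cohort construction rejects unknown labels and duplicates", {
  expect_error(
    cohort_table(data.frame(subject_id = "s1", timepoint = 0,
                            a = "maybe", b = "true"), specs2),
    "'maybe'")
  expect_error(
    cohort_table(data.frame(subject_id = c("s1", "s1"), timepoint = c(0, 0),
                            a = c("true", "false"), b = "true"), specs2),
    "duplicate")
  expect_error(
    cohort_table(data.frame(subject_id = "s1", timepoint = -1,
                            a = "true", b = "true"), specs2),
    "non-negative")
})

test_that("validation reports subject, record and missingness counts", {
  empty <- cohort_table(data.frame(subject_id = character(0),
                                   timepoint = integer(0),
                                   a = character(0), b = character(0)),
                        specs2)
  rep0 <- validate_cohort(empty)
  expect_equal(rep0$n_subjects, 0L)
  expect_equal(rep0$n_records, 0L)

  tab <- cohort_table(data.frame(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    timepoint = rep(0:1, 3),
    a = rep("true", 6), b = rep("false", 6)), specs2)
  rep <- validate_cohort(tab)
  expect_equal(rep$n_subjects, 3L)
  expect_equal(rep$n_records, 6L)
  expect_equal(sum(rep$missing_by_factor), 0L)
})

test_that("initial dataset keeps exactly the complete t = 0 records", {
  tab <- cohort_table(data.frame(
    subject_id = c("s1", "s1", "s2", "s3"),
    timepoint = c(0, 1, 0, 0),
    a = c("true", NA, NA, "false"),
    b = c("true", "false", "true", "true")), specs2)
  ds <- build_initial_dataset(tab)
  # s1: complete t=0, missing t=1 -> included; s2: missing a at t=0 ->
  # excluded; s3 complete -> included
  expect_setequal(ds$subject_id, c("s1", "s3"))
  expect_false(anyNA(ds))

  set.seed(8)
  big <- random_gappy_cohort(10, 2, specs2, p_present = 1, seed = 8)
  t0 <- as.data.frame(big)[big$timepoint == 0, ]
  n_complete <- sum(stats::complete.cases(t0[, c("a", "b")]))
  expect_equal(nrow(build_initial_dataset(big)), n_complete)
})

test_that("transition dataset stacks exactly the complete consecutive pairs", {
  tab <- cohort_table(data.frame(
    subject_id = c(rep("s1", 3), "s2", "s2", rep("s3", 4)),
    timepoint = c(0, 1, 2, 0, 2, 0, 1, 2, 3),
    a = c(rep("true", 5), "true", NA, "true", "false"),
    b = rep("false", 9)), specs2)
  ds <- build_transition_dataset(tab)
  # s1 complete at 0,1,2 -> two pairs; s2 only 0 and 2 -> none (not
  # consecutive); s3 missing t=1 -> only the 2 -> 3 pair
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$subject_id, c("s1", "s1", "s3"))
  expect_equal(ds$t, c(0L, 1L, 2L))
  expect_named(ds, c("subject_id", "t", "a@t", "b@t", "a@t1", "b@t1"))
  expect_false(anyNA(ds))
})

test_that("pair counts match the brute-force scan on random cohorts", {
  for (seed in 1:5) {
    tab <- random_gappy_cohort(25, 5, specs2, p_present = 0.7, seed = seed)
    oracle <- brute_pair_count(tab, specs2)
    got <- tryCatch(nrow(build_transition_dataset(tab)),
                    error = function(e) 0L)
    expect_equal(got, oracle, info = paste("seed", seed))
  }
})

test_that("datasets are invariant to subject relabelling up to row order", {
  tab <- random_gappy_cohort(15, 4, specs2, p_present = 0.8, seed = 42)
  df <- as.data.frame(tab)
  ids <- unique(df$subject_id)
  remap <- stats::setNames(sprintf("Z%03d", rev(seq_along(ids))), ids)
  relab <- df
  relab$subject_id <- unname(remap[df$subject_id])
  tab2 <- cohort_table(relab, specs2)
  a <- build_transition_dataset(tab)
  b <- build_transition_dataset(tab2)
  cols <- setdiff(names(a), "subject_id")
  key <- function(x) do.call(paste, c(x[cols], sep = "\r"))
  expect_setequal(key(as.data.frame(a)), key(as.data.frame(b)))
})

test_that("binary collapse assigns true to the truthy levels only", {
  dx <- diagnosis_factor("depression")
  expect_true(collapse_to_binary("full-threshold", dx))
  expect_true(collapse_to_binary("subthreshold", dx))
  expect_false(collapse_to_binary("none", dx))
  expect_error(collapse_to_binary("mild", dx), "not one of its levels")
  expect_identical(collapse_to_binary(c("none", NA, "subthreshold"), dx),
                   c(FALSE, NA, TRUE))
})

test_that("CSV reader thresholds continuous sources and flags missing", {
  spec_path <- system.file("extdata", "example_factors.yaml",
                           package = "cohortdbn")
  csv_path <- system.file("extdata", "example_cohort.csv",
                          package = "cohortdbn")
  specs <- read_factor_specs(spec_path)
  expect_named(specs, c("sofas_good", "older", "ideation", "depression"))
  tab <- read_cohort_csv(csv_path, specs)
  df <- as.data.frame(tab)
  r <- df[df$subject_id == "S001" & df$timepoint == 0, ]
  expect_equal(r$sofas_good, "poor")  # SOFAS 65, not > 70
  expect_equal(r$older, "false")      # age 17, not > 18
  r2 <- df[df$subject_id == "S002" & df$timepoint == 0, ]
  expect_equal(r2$sofas_good, "good") # SOFAS 75
  expect_true(is.na(df[df$subject_id == "S005" &
                         df$timepoint == 1, "sofas_good"]))
  expect_error(build_initial_dataset(
    cohort_table(data.frame(subject_id = "s", timepoint = 0,
                            a = NA_character_, b = "true"), specs2)),
    "reduce the factor subset")
})
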