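test_that("the default truth is reproducible and structurally sound", {
  t1 <- make_default_truth(3)
  t2 <- make_default_truth(3)
  expect_identical(t1, t2)
  expect_false(identical(t1, make_default_truth(4)))

  fac <- names(t1$specs)
  expect_length(fac, 16L)
  expect_gte(sum(vapply(t1$specs, function(sp)
    length(sp$levels) == 3L, logical(1))), 2L)
  expect_setequal(unique(vapply(t1$specs, `[[`, character(1),
                                "domain_group")),
                  c("function", "suicidality", "substance", "physical",
                    "syndrome"))
  # every factor persists across slices
  for (f in fac) {
    expect_true(paste0(f, "@t") %in%
                  t1$transition$dag$parents[[paste0(f, "@t1")]])
  }
  expect_true(is_two_slice(t1$transition$dag$parents, t1$slices))
  # planted cross-domain effects present
  expect_true("sofas_good@t" %in% t1$transition$dag$parents[["ideation@t1"]])
  expect_true("ideation@t" %in% t1$transition$dag$parents[["attempt@t1"]])
})

test_that("simulation is seeded and fills the grid when rates are zero", {
  truth <- make_effect_truth()
  cfg <- sim_config(n_subjects = 50, n_timepoints = 3,
                    missing_timepoint_rate = 0, dropout_rate = 0, seed = 5)
  tab1 <- simulate_cohort(truth, cfg)
  tab2 <- simulate_cohort(truth, cfg)
  expect_identical(as.data.frame(tab1), as.data.frame(tab2))
  expect_equal(nrow(tab1), 150L)
  expect_false(anyNA(as.data.frame(tab1)))
})

test_that("simulated time-0 frequencies match the analytic marginals", {
  truth <- make_default_truth(1)
  tab <- simulate_cohort(truth, sim_config(n_subjects = 5000,
                                           n_timepoints = 1,
                                           missing_timepoint_rate = 0,
                                           dropout_rate = 0, seed = 11))
  df <- as.data.frame(tab)
  for (f in c("sofas_good", "ideation", "depression", "cannabis_use")) {
    want <- initial_marginal(truth, f)
    got <- table(factor(df[[f]], levels = truth$specs[[f]]$levels)) /
      nrow(df)
    expect_lt(max(abs(as.numeric(got) - want)), 0.02)
  }
})

test_that("missed-visit deletion hits the configured rate", {
  truth <- make_effect_truth()
  tab <- simulate_cohort(truth, sim_config(n_subjects = 2000,
                                           n_timepoints = 4,
                                           missing_timepoint_rate = 0.3,
                                           dropout_rate = 0, seed = 13))
  frac <- nrow(tab) / (2000 * 4)
  expect_lt(abs(frac - 0.7), 0.02)
})

test_that("dropout truncates subjects geometrically but gaps allow return", {
  truth <- make_effect_truth()
  tab <- simulate_cohort(truth, sim_config(n_subjects = 3000,
                                           n_timepoints = 6,
                                           missing_timepoint_rate = 0.25,
                                           dropout_rate = 0.3, seed = 17))
  df <- as.data.frame(tab)
  lens <- tapply(df$timepoint, df$subject_id, max)
  expect_gt(mean(lens < 5), 0.5) # most subjects truncated early
  # reappearance: some subject has a gap followed by a later visit
  has_gap <- vapply(split(df$timepoint, df$subject_id), function(tp)
    any(diff(sort(tp)) > 1L), logical(1))
  expect_gt(sum(has_gap), 0)
})

test_that("transition frequencies converge to the truth's CPTs with n", {
  truth <- make_effect_truth()
  err_at <- function(n, seed) {
    tab <- simulate_cohort(truth, sim_config(n_subjects = n,
                                             n_timepoints = 2,
                                             missing_timepoint_rate = 0,
                                             dropout_rate = 0, seed = seed))
    td <- build_transition_dataset(tab)
    # P(f@t1 = true | f@t) for both conditions vs the generator CPT
    p <- truth$transition$cpts[["f@t1"]]$prob["true", ]
    df <- as.data.frame(td)
    est <- vapply(c("false", "true"), function(l) {
      sel <- df[["f@t"]] == l
      mean(df[["f@t1"]][sel] == "true")
    }, numeric(1))
    max(abs(est - p))
  }
  errs <- vapply(c(500, 2000, 8000), err_at, numeric(1), seed = 19)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 3 / sqrt(8000) + 0.01)
})

test_that("recovery reports score perfect and uninformative probabilities", {
  truth <- make_effect_truth()
  sl <- truth$slices
  nodes <- c(sl$t, sl$t1)
  perfect <- matrix(0, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
  for (v in sl$t1) {
    for (p in truth$transition$dag$parents[[v]]) perfect[p, v] <- 1
  }
  rep1 <- structure_recovery_report(truth, perfect)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$tpr, 1)
  expect_equal(rep1$fpr, 0)
  flat <- perfect * 0 + 0.5
  rep2 <- structure_recovery_report(truth, flat)
  expect_equal(rep2$auc, 0.5)
  expect_error(structure_recovery_report(truth, perfect[1:3, 1:3]),
               "does not cover")
})

test_that("structure recovery improves with cohort size", {
  truth <- make_effect_truth()
  auc_at <- function(n, seed) {
    tab <- simulate_cohort(truth, sim_config(n_subjects = n,
                                             n_timepoints = 2,
                                             missing_timepoint_rate = 0,
                                             dropout_rate = 0, seed = seed))
    ex <- exact_transition_posterior(build_transition_dataset(tab))
    structure_recovery_report(truth, ex$edge_prob)$auc
  }
  wins <- vapply(1:3, function(seed)
    auc_at(1500, 300 + seed) >= auc_at(150, 300 + seed), logical(1))
  expect_gte(sum(wins), 2L)
})

test_that("informative missingness biases attendance against active cases", {
  truth <- make_effect_truth()
  tab <- simulate_cohort(truth, sim_config(
    n_subjects = 4000, n_timepoints = 2, missing_timepoint_rate = 0.2,
    dropout_rate = 0, seed = 23,
    informative_missingness = list(factor = "i", multiplier = 4)))
  df <- as.data.frame(tab)
  # active-i records are deleted more often, so the observed prevalence
  # falls below the analytic marginal
  p_obs <- mean(df$i[df$timepoint == 0] == "true")
  p_true <- initial_marginal(truth, "i")[["true"]]
  expect_lt(p_obs, p_true - 0.01)
})
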