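test_that("CPT cells are Dirichlet posterior means with BDeu hyperparameters", {
  specs <- bin2("a", "b")
  df <- data.frame(a = rep("true", 4),
                   b = c("true", "true", "true", "false"),
                   stringsAsFactors = FALSE)
  attr(df, "specs") <- specs
  pbn <- fit_parameters(dag(c("a", "b"), list(b = "a")), df, prior_ess = 1)
  # q = 2, r = 2: alpha_jk = 1/4; (3 + 0.25) / (4 + 0.5)
  expect_equal(unname(pbn$cpts$b$prob["true", 2]), 3.25 / 4.5,
               tolerance = 1e-12)
  expect_true(all(pbn$cpts$b$prob > 0))
  expect_equal(colSums(pbn$cpts$b$prob), rep(1, 2), tolerance = 1e-12)

  expect_warning(pbn0 <- fit_parameters(dag("a"), df[0, , drop = FALSE],
                                        specs), "prior mean")
  expect_equal(unname(pbn0$cpts$a$prob[, 1]), c(0.5, 0.5))

  # smoothing keeps cells strictly inside (0, 1) even for pure data
  df1 <- data.frame(a = rep("true", 500), stringsAsFactors = FALSE)
  attr(df1, "specs") <- bin2("a")
  pbn1 <- fit_parameters(dag("a"), df1)
  expect_lt(pbn1$cpts$a$prob["true", 1], 1)
  expect_gt(pbn1$cpts$a$prob["true", 1], 0.99)
})

test_that("interventional marginals follow the truncated factorization", {
  specs <- bin2("a", "b")
  pbn <- make_param_bn(dag(c("a", "b"), list(b = "a")),
                       list(a = cpt_binary(0.4),
                            b = cpt_binary(c(0.2, 0.8))), specs)
  expect_equal(interventional_marginal(pbn, list(a = "true"), "b")[["true"]],
               0.8, tolerance = 1e-12)
  # intervening on the child leaves the parent at its marginal
  expect_equal(interventional_marginal(pbn, list(b = "true"), "a")[["true"]],
               0.4, tolerance = 1e-12)
  expect_error(interventional_marginal(pbn, list(a = "true"), "a"),
               "target")
})

test_that("exact inference matches full joint enumeration on random networks", {
  for (cfg in list(c(8, 101), c(12, 102), c(15, 103))) {
    pbn <- random_param_bn(cfg[1], seed = cfg[2])
    nodes <- pbn$dag$nodes
    set.seed(cfg[2])
    do_node <- sample(nodes, 1)
    target <- sample(setdiff(nodes, do_node), 1)
    got <- interventional_marginal(pbn, stats::setNames(list("true"),
                                                        do_node), target)
    want <- joint_marginal_oracle(pbn, stats::setNames(list("true"),
                                                       do_node), target)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("the HDI is the narrowest window at the requested mass", {
  expect_equal(hdi(rep(3, 5)), c(3, 3))
  h <- hdi(1:100, 0.95)
  expect_equal(h[2] - h[1], 94)
  set.seed(7)
  z <- stats::rnorm(10000)
  hz <- hdi(z)
  expect_lt(max(abs(hz - c(-1.96, 1.96))), 0.1)
  expect_error(hdi(1:10, mass = 1.2), "mass")
  # sliding-window oracle on irregular draws
  set.seed(9)
  x <- sort(stats::rexp(200))
  k <- ceiling(0.9 * length(x))
  widths <- vapply(seq_len(length(x) - k + 1L), function(i)
    x[i + k - 1L] - x[i], numeric(1))
  expect_equal(diff(hdi(x, 0.9)), min(widths), tolerance = 1e-12)
})

test_that("single-structure plug-in RR is the fitted CPT ratio", {
  specs <- bin2("a", "b")
  set.seed(15)
  n <- 2000
  a <- sample(c("false", "true"), n, TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "true", 0.8, 0.2),
              "true", "false")
  df <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  attr(df, "specs") <- specs
  s <- structure(list(dags = list(list(a = character(0), b = "a")),
                      nodes = c("a", "b"), meta = list()),
                 class = "dbn_posterior")
  est <- causal_rr(s, df, A = "a", B = "b", cpt_draws = "mean")
  pbn <- fit_parameters(dag(c("a", "b"), list(b = "a")), df)
  want <- unname(pbn$cpts$b$prob["true", 2] / pbn$cpts$b$prob["true", 1])
  expect_equal(est$rr_mean, want, tolerance = 1e-12)
  expect_equal(est$rr_hdi, c(want, want))
  expect_gt(want, 3.5)
})

test_that("disconnected pairs have relative risk exactly 1", {
  df <- random_binary_data(c("a", "b"), 200, seed = 21)
  s <- structure(list(dags = rep(list(list(a = character(0),
                                           b = character(0))), 5),
                      nodes = c("a", "b"), meta = list()),
                 class = "dbn_posterior")
  est <- causal_rr(s, df, A = "a", B = "b")
  expect_identical(unique(est$rr_draws), 1)
  expect_equal(est$rr_mean, 1)
  expect_false(est$reportable)
})

test_that("a pure indirect chain effect is recovered from the mediator", {
  # A -> M -> B: with the direct edge absent, the interventional RR is
  # the total effect flowing through M
  specs <- bin2("A", "M", "B")
  gen <- make_param_bn(dag(c("A", "M", "B"), list(M = "A", B = "M")),
                       list(A = cpt_binary(0.5),
                            M = cpt_binary(c(0.15, 0.85)),
                            B = cpt_binary(c(0.1, 0.7))), specs)
  p1 <- joint_marginal_oracle(gen, list(A = "true"), "B")[["true"]]
  p0 <- joint_marginal_oracle(gen, list(A = "false"), "B")[["true"]]
  analytic <- p1 / p0
  set.seed(25)
  n <- 5000
  A <- sample(c("false", "true"), n, TRUE)
  M <- ifelse(stats::runif(n) < ifelse(A == "true", 0.85, 0.15),
              "true", "false")
  B <- ifelse(stats::runif(n) < ifelse(M == "true", 0.7, 0.1),
              "true", "false")
  df <- data.frame(A = A, M = M, B = B, stringsAsFactors = FALSE)
  attr(df, "specs") <- specs
  s <- structure(list(dags = list(list(A = character(0), M = "A", B = "M")),
                      nodes = c("A", "M", "B"), meta = list()),
                 class = "dbn_posterior")
  est <- causal_rr(s, df, A = "A", B = "B", cpt_draws = "mean")
  expect_lt(abs(est$rr_mean - analytic) / analytic, 0.1)
})

test_that("strengthening the planted contrast increases the recovered effect", {
  recover_mu <- function(p_hi) {
    set.seed(33)
    n <- 3000
    a <- sample(c("false", "true"), n, TRUE)
    b <- ifelse(stats::runif(n) < ifelse(a == "true", p_hi, 0.2),
                "true", "false")
    df <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
    attr(df, "specs") <- bin2("a", "b")
    s <- structure(list(dags = list(list(a = character(0), b = "a")),
                        nodes = c("a", "b"), meta = list()),
                   class = "dbn_posterior")
    causal_rr(s, df, A = "a", B = "b", cpt_draws = "mean")$rr_mean
  }
  mus <- vapply(c(0.4, 0.6, 0.8), recover_mu, numeric(1))
  expect_true(all(diff(mus) > 0))
})

test_that("the RR matrix covers all pairs and suppresses by interval", {
  truth <- make_effect_truth()
  tab <- simulate_cohort(truth, sim_config(n_subjects = 600,
                                           n_timepoints = 3,
                                           missing_timepoint_rate = 0,
                                           dropout_rate = 0, seed = 91))
  td <- build_transition_dataset(tab)
  s <- learn_transition_network(tab, attr(tab, "specs"),
                                transition_config(), seed = 92,
                                n_iter = 3000, burn_in = 800, thin = 10,
                                n_chains = 1)
  rr <- rr_matrix(s, td, seed = 5)
  # 5 x 5 ordered pairs including the same-factor diagonal
  expect_equal(nrow(rr), 25L)
  expect_true(all(paste0(c("f", "i", "s", "x", "y"), "@t") %in% rr$source))
  diag_cell <- rr[rr$source == "f@t" & rr$target == "f@t1", ]
  expect_true(diag_cell$reportable)   # strong persistence
  expect_identical(rr$reportable,
                   rr$hdi_low > 1 | rr$hdi_high < 1)
  path <- tempfile(fileext = ".csv")
  write_rr_csv(rr, path)
  kept <- utils::read.csv(path)
  expect_true(all(kept$reportable))
  write_rr_csv(rr, path, all_cells = TRUE)
  expect_equal(nrow(utils::read.csv(path)), 25L)
  unlink(path)
})

test_that("observational conditioning is available as a sensitivity mode", {
  specs <- bin2("a", "b")
  set.seed(41)
  n <- 1500
  a <- sample(c("false", "true"), n, TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "true", 0.7, 0.3),
              "true", "false")
  df <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  attr(df, "specs") <- specs
  s <- structure(list(dags = list(list(a = character(0), b = "a")),
                      nodes = c("a", "b"), meta = list()),
                 class = "dbn_posterior")
  ei <- causal_rr(s, df, A = "a", B = "b", cpt_draws = "mean")
  eo <- causal_rr(s, df, A = "a", B = "b", cpt_draws = "mean",
                  mode = "observational")
  # with a single edge a -> b the two coincide
  expect_equal(eo$rr_mean, ei$rr_mean, tolerance = 1e-9)
})
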