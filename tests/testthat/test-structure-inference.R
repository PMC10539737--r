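test_that("labelled DAG counts match brute-force enumeration", {
  expect_identical(count_dags(0), "1")
  expect_identical(count_dags(1), "1")
  expect_identical(count_dags(2), "3")
  # independent oracle: filter all 3-node digraphs for acyclicity
  nodes <- c("a", "b", "c")
  pairs <- t(combn(3, 2))
  arcs <- rbind(pairs, pairs[, 2:1])
  n_acyclic <- 0L
  for (mask in 0:(2^6 - 1)) {
    sel <- bitwAnd(bitwShiftR(mask, 0:5), 1L) == 1L
    a <- matrix(0L, 3, 3, dimnames = list(nodes, nodes))
    a[arcs[sel, , drop = FALSE]] <- 1L
    ok <- tryCatch({ amat_to_dag(a); TRUE }, error = function(e) FALSE)
    if (ok) n_acyclic <- n_acyclic + 1L
  }
  expect_identical(count_dags(3), as.character(n_acyclic))
  expect_identical(count_dags(3), "25")
  expect_error(count_dags(-1), "non-negative")
})

test_that("exhaustive posterior is uniform on empty data and honours support", {
  df <- random_binary_data(c("u", "v"), 0, seed = 1)
  en <- enumerate_dag_posterior(df)
  expect_equal(en$n_dags, 3L)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  expect_equal(en$edge_prob["u", "v"], 1 / 3, tolerance = 1e-12)

  dfn <- random_binary_data(c("u", "v"), 50, seed = 2)
  all_forbidden <- edge_constraint(forbidden = rbind(c("u", "v"),
                                                     c("v", "u")))
  en2 <- enumerate_dag_posterior(dfn, constraint = all_forbidden)
  expect_equal(en2$n_dags, 1L)
  expect_equal(en2$prob, 1)
  expect_equal(nrow(dag_edges(en2$dag_at(1))), 0L)

  expect_error(enumerate_dag_posterior(
    random_binary_data(letters[1:6], 5, seed = 1)), "5 nodes")
})

test_that("strong pairwise dependence is detected by the exact posterior", {
  set.seed(11)
  n <- 500
  u <- sample(c("false", "true"), n, TRUE)
  v <- ifelse(stats::runif(n) < ifelse(u == "true", 0.9, 0.1),
              "true", "false")
  w <- sample(c("false", "true"), n, TRUE)
  df <- data.frame(u = u, v = v, w = w, stringsAsFactors = FALSE)
  attr(df, "specs") <- bin2("u", "v", "w")
  en <- enumerate_dag_posterior(df)
  expect_gt(en$edge_prob["u", "v"] + en$edge_prob["v", "u"], 0.95)
})

test_that("the sampler is reproducible and never leaves the prior support", {
  df <- random_binary_data(c("a", "b", "c"), 80, seed = 3)
  con <- edge_constraint(forbidden = cbind("a", "b"))
  s1 <- partition_mcmc_sample(df, constraint = con, seed = 7,
                              n_iter = 1500, burn_in = 300, thin = 5,
                              n_chains = 1)
  s2 <- partition_mcmc_sample(df, constraint = con, seed = 7,
                              n_iter = 1500, burn_in = 300, thin = 5,
                              n_chains = 1)
  expect_identical(s1$dags, s2$dags)
  expect_true(all(vapply(s1$dags, function(d)
    !"a" %in% d[["b"]], logical(1))))
  expect_error(partition_mcmc_sample(df, n_iter = 100, burn_in = 10),
               "seed")
})

test_that("required edges appear in every sampled DAG", {
  df <- random_binary_data(c("a", "b", "c"), 60, seed = 13)
  con <- edge_constraint(required = cbind("a", "b"))
  s <- partition_mcmc_sample(df, constraint = con, seed = 5,
                             n_iter = 1200, burn_in = 200, thin = 5,
                             n_chains = 1)
  expect_true(all(vapply(s$dags, function(d) "a" %in% d[["b"]],
                         logical(1))))
})

test_that("sampled edge frequencies track the exhaustive posterior", {
  set.seed(21)
  n <- 200
  a <- sample(c("false", "true"), n, TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "true", 0.8, 0.2),
              "true", "false")
  cc <- sample(c("false", "true"), n, TRUE)
  df <- data.frame(a = a, b = b, c = cc, stringsAsFactors = FALSE)
  attr(df, "specs") <- bin2("a", "b", "c")
  en <- enumerate_dag_posterior(df)
  s <- partition_mcmc_sample(df, seed = 31, n_iter = 8000, burn_in = 2000,
                             thin = 10, n_chains = 2)
  expect_lt(max(abs(edge_probabilities(s) - en$edge_prob)), 0.03)
})

test_that("edge probabilities are sample frequencies", {
  d1 <- list(a = character(0), b = "a")
  d2 <- list(a = character(0), b = character(0))
  s <- structure(list(dags = list(d1, d2), nodes = c("a", "b"),
                      meta = list()), class = "dbn_posterior")
  ep <- edge_probabilities(s)
  expect_equal(ep["a", "b"], 0.5)
  expect_equal(ep["b", "a"], 0)
  s2 <- structure(list(dags = list(d1, d1), nodes = c("a", "b"),
                       meta = list()), class = "dbn_posterior")
  expect_equal(edge_probabilities(s2)["a", "b"], 1)
})

test_that("symmetric moves give reciprocal acceptance ratios", {
  df <- random_binary_data(c("a", "b", "c", "d"), 100, seed = 17)
  s <- partition_mcmc_sample(df, seed = 19, n_iter = 400, burn_in = 100,
                             thin = 5, n_chains = 1, log_moves = TRUE)
  mv <- s$meta$moves[[1]]
  # proposals are symmetric, so alpha(P -> P') * alpha(P' -> P) =
  # exp(dR) * exp(-dR) = 1 for every logged move
  expect_true(all(is.finite(mv[, "log_ratio"]) |
                    mv[, "log_ratio"] == -Inf))
  finite <- is.finite(mv[, "log_ratio"])
  expect_equal(exp(mv[finite, "log_ratio"]) * exp(-mv[finite, "log_ratio"]),
               rep(1, sum(finite)), tolerance = 1e-12)
})

test_that("doubling the chain leaves edge probabilities stable", {
  set.seed(23)
  n <- 150
  a <- sample(c("false", "true"), n, TRUE)
  b <- ifelse(stats::runif(n) < ifelse(a == "true", 0.85, 0.15),
              "true", "false")
  cc <- ifelse(stats::runif(n) < ifelse(b == "true", 0.8, 0.25),
               "true", "false")
  df <- data.frame(a = a, b = b, c = cc, stringsAsFactors = FALSE)
  attr(df, "specs") <- bin2("a", "b", "c")
  s1 <- partition_mcmc_sample(df, seed = 41, n_iter = 6000, burn_in = 1500,
                              thin = 10, n_chains = 1)
  s2 <- partition_mcmc_sample(df, seed = 43, n_iter = 12000, burn_in = 3000,
                              thin = 10, n_chains = 1)
  expect_lt(max(abs(edge_probabilities(s1) - edge_probabilities(s2))), 0.02)
})

test_that("posterior samples round-trip through JSON-lines", {
  df <- random_binary_data(c("a", "b", "c"), 40, seed = 29)
  s <- partition_mcmc_sample(df, seed = 3, n_iter = 600, burn_in = 100,
                             thin = 10, n_chains = 1)
  path <- tempfile(fileext = ".jsonl")
  write_posterior_jsonl(s, path)
  s2 <- read_posterior_jsonl(path)
  expect_identical(s2$nodes, s$nodes)
  expect_equal(edge_probabilities(s2), edge_probabilities(s))
  unlink(path)
})

test_that("parent-set filters are exact at the 31-candidate boundary", {
  # 31 candidates set every usable bit of the mask integer; the subset
  # test must not overflow into the NA sentinel
  cand <- sprintf("c%02d", 1:31)
  tb <- list(node = "x", cand = cand,
             mask = c(0L, 1L, 2L, as.integer(2^30),
                      as.integer(2^30 + 2^29 + 1)),
             size = c(0L, 1L, 1L, 1L, 3L),
             score = c(-5, -1, -2, -3, -4), has_empty = TRUE)
  cache <- new.env(parent = emptyenv())
  ctx <- cohortdbn:::node_context(tb, cand, cand, FALSE, cache)
  expect_setequal(ctx$idx, 2:5) # every nonempty set allowed
  expect_equal(ctx$lse, cohortdbn:::logsumexp(c(-1, -2, -3, -4)))
  # with U restricted to the first candidate only
  ctx2 <- cohortdbn:::node_context(tb, cand[1], cand[1], FALSE, cache)
  expect_identical(ctx2$idx, 2L)
})
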