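# Shared fixtures and independent oracles, all built in code.

bin2 <- function(...) as_spec_list(lapply(c(...), binary_factor))

# random complete binary dataset (columns = node names)
random_binary_data <- function(nodes, n, seed) {
  set.seed(seed)
  df <- as.data.frame(stats::setNames(lapply(nodes, function(v)
    sample(c("false", "true"), n, replace = TRUE)), nodes),
    stringsAsFactors = FALSE)
  attr(df, "specs") <- bin2(nodes)
  df
}

# cohort with random whole-record gaps for dataset-builder property tests
random_gappy_cohort <- function(n_subj, n_tp, specs, p_present, seed) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) {
    for (t in 0:(n_tp - 1L)) {
      if (stats::runif(1) > p_present) next
      vals <- lapply(specs, function(sp)
        if (stats::runif(1) < 0.1) NA_character_ else
          sample(sp$levels, 1L))
      rows[[length(rows) + 1L]] <- c(list(subject_id = sprintf("P%03d", s),
                                          timepoint = t), vals)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame,
                              stringsAsFactors = FALSE))
  cohort_table(df, specs)
}

# brute-force count of complete consecutive pairs (independent oracle)
brute_pair_count <- function(tab, specs) {
  fac <- names(specs)
  df <- as.data.frame(tab)
  total <- 0L
  for (s in unique(df$subject_id)) {
    sub <- df[df$subject_id == s, , drop = FALSE]
    ok <- stats::complete.cases(sub[, fac, drop = FALSE])
    tp <- sub$timepoint[ok]
    total <- total + sum((tp + 1L) %in% tp)
  }
  total
}

# v-structure signature of a DAG (for equivalence-class grouping)
vstructure_key <- function(g) {
  a <- dag_amat(g)
  out <- character(0)
  for (v in seq_len(nrow(a))) {
    ps <- which(a[, v] == 1L)
    if (length(ps) < 2L) next
    for (i in seq_along(ps)) {
      for (j in seq_len(i - 1L)) {
        if (a[ps[i], ps[j]] == 0L && a[ps[j], ps[i]] == 0L) {
          pr <- sort(c(ps[i], ps[j]))
          out <- c(out, paste(pr[1L], v, pr[2L]))
        }
      }
    }
  }
  paste(sort(out), collapse = "|")
}

skeleton_key <- function(g) {
  a <- dag_amat(g)
  s <- a | t(a)
  idx <- which(s & upper.tri(s), arr.ind = TRUE)
  paste(paste(idx[, 1], idx[, 2], sep = "-"), collapse = "|")
}

equivalence_class_key <- function(g) {
  paste(skeleton_key(g), vstructure_key(g), sep = " / ")
}

# all labelled DAGs on the given nodes (enumeration via the exhaustive
# posterior machinery on an empty dataset: every allowed DAG appears once)
all_dags_on <- function(nodes) {
  df <- as.data.frame(stats::setNames(
    lapply(nodes, function(v) character(0)), nodes),
    stringsAsFactors = FALSE)
  attr(df, "specs") <- bin2(nodes)
  en <- enumerate_dag_posterior(
    df, constraint = edge_constraint(max_parents = length(nodes) - 1L))
  lapply(seq_len(en$n_dags), en$dag_at)
}

# compact 5-factor two-slice truth with planted effects and null pairs:
# f -> i and i -> s carry cross-slice effects, x and y are independent of
# each other; the time-t slice is independent so analytic RRs are exact
make_effect_truth <- function() {
  specs <- bin2("f", "i", "s", "x", "y")
  fac <- names(specs)
  init <- make_param_bn(dag(fac), list(
    f = cpt_binary(0.45), i = cpt_binary(0.25), s = cpt_binary(0.2),
    x = cpt_binary(0.3), y = cpt_binary(0.35)), specs)
  sl <- slice_nodes(fac)
  gt <- dag(c(sl$t, sl$t1),
            list("f@t1" = "f@t", "i@t1" = c("i@t", "f@t"),
                 "s@t1" = c("s@t", "i@t"), "x@t1" = "x@t", "y@t1" = "y@t"))
  trc <- list(
    "f@t1" = cpt_binary(c(0.15, 0.75)),
    "i@t1" = risk_cpt(0.12, specs[c("i", "f")], c(5, 2.2)),
    "s@t1" = risk_cpt(0.10, specs[c("s", "i")], c(5, 2.8)),
    "x@t1" = cpt_binary(c(0.12, 0.7)),
    "y@t1" = cpt_binary(c(0.15, 0.72)),
    "f@t" = cpt_binary(0.45), "i@t" = cpt_binary(0.25),
    "s@t" = cpt_binary(0.2), "x@t" = cpt_binary(0.3),
    "y@t" = cpt_binary(0.35))
  ground_truth_dbn(specs, init, make_param_bn(gt, trc, specs))
}

# random parameterised BN over binary nodes (for inference-exactness tests)
random_param_bn <- function(n_nodes, seed, max_parents = 3L) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n_nodes))
  specs <- bin2(nodes)
  parents <- list()
  for (j in seq_along(nodes)[-1]) {
    k <- min(stats::rbinom(1, max_parents, 0.5), j - 1L)
    if (k > 0L) parents[[nodes[j]]] <- sample(nodes[seq_len(j - 1L)], k)
  }
  g <- dag(nodes, parents)
  cpts <- lapply(nodes, function(v) {
    q <- prod(c(1L, vapply(g$parents[[v]], function(p) 2L, integer(1))))
    cpt_binary(stats::runif(q, 0.05, 0.95))
  })
  names(cpts) <- nodes
  make_param_bn(g, cpts, specs)
}

# full-joint oracle: P(target | clamped values) by enumerating all 2^n
# configurations of a binary param_bn
joint_marginal_oracle <- function(pbn, do, target) {
  nodes <- pbn$dag$nodes
  grids <- rep(list(1:2), length(nodes))
  names(grids) <- nodes
  conf <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  w <- rep(1, nrow(conf))
  for (v in nodes) {
    cpt <- pbn$cpts[[v]]
    if (v %in% names(do)) {
      lev <- match(do[[v]], rownames(cpt$prob))
      w <- w * (conf[, v] == lev) # clamp, CPT factor removed
      next
    }
    p <- cpt$parents
    idx <- integer(nrow(conf))
    if (length(p)) {
      pr <- cpt$plev
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (conf[, p[j]] - 1L)
    }
    w <- w * cpt$prob[cbind(conf[, v], idx + 1L)]
  }
  out <- vapply(1:2, function(k) sum(w[conf[, target] == k]), numeric(1))
  names(out) <- rownames(pbn$cpts[[target]]$prob)
  out / sum(out)
}
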