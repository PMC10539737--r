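#' Fit conditional probability tables for a DAG
#'
#' Each CPT cell is the Dirichlet posterior mean
#' \eqn{(n_{jk} + \alpha_{jk}) / (n_j + \alpha_j)} with BDeu-consistent
#' hyperparameters \eqn{\alpha_{jk} = \mathrm{ess}/(qr)}, so every entry is
#' strictly positive (the smoothing also guarantees finite relative risks
#' downstream, with no ad-hoc epsilon).
#'
#' @param g a [dag()] whose nodes are dataset columns.
#' @param dataset complete-case dataset.
#' @param specs factor specs (defaults to the dataset attribute).
#' @param prior_ess equivalent sample size of the Dirichlet prior.
#' @return object of class `param_bn`: the DAG plus, per node, a CPT
#'   matrix `[child level, parent configuration]` with parent configuration
#'   index varying fastest in the first listed parent.
#' @export
fit_parameters <- function(g, dataset, specs = attr(dataset, "specs"),
                           prior_ess = 1) {
  stopifnot(inherits(g, "bn_dag"))
  specs <- as_spec_list(specs)
  df <- as.data.frame(dataset)
  if (nrow(df) == 0L) {
    warning("empty dataset: CPTs equal the prior mean", call. = FALSE)
  }
  enc <- encode_dataset(dataset, specs, columns = g$nodes)
  nlev <- attr(enc, "nlev")
  cpts <- lapply(g$nodes, function(v) {
    p <- g$parents[[v]]
    r <- nlev[[v]]
    pr <- nlev[p]
    q <- if (length(pr)) prod(pr) else 1
    idx <- integer(nrow(enc))
    if (length(p)) {
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (enc[, p[j]] - 1L)
    }
    counts <- tabulate(idx * r + (enc[, v] - 1L) + 1L, nbins = q * r)
    njk <- matrix(counts, nrow = r)
    ajk <- prior_ess / (q * r)
    prob <- sweep(njk + ajk, 2, colSums(njk) + prior_ess / q, "/")
    f <- sub("@t1?$", "", v)
    dimnames(prob) <- list(specs[[f]]$levels, NULL)
    list(parents = p, plev = pr, prob = prob)
  })
  names(cpts) <- g$nodes
  structure(list(dag = g, cpts = cpts, nlev = nlev,
                 prior_ess = prior_ess),
            class = "param_bn")
}

#' @export
print.param_bn <- function(x, ...) {
  cat(sprintf("<param_bn> %d nodes, %d edges, prior ESS %g\n",
              length(x$dag$nodes), nrow(dag_edges(x$dag)), x$prior_ess))
  invisible(x)
}

ancestors_of <- function(parents, v) {
  seen <- character(0)
  frontier <- parents[[v]]
  while (length(frontier)) {
    seen <- union(seen, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        seen)
  }
  seen
}

# exact P(target | do / clamp assignments) by summation over the joint of
# the target's ancestors in the mutilated graph; exact because all other
# nodes marginalise out of the truncated factorisation
marginal_given_clamps <- function(pbn, clamps, target) {
  parents <- lapply(pbn$cpts, `[[`, "parents")
  mut <- parents
  for (v in names(clamps)) mut[[v]] <- character(0)
  relevant <- union(ancestors_of(mut, target), target)
  free <- setdiff(relevant, names(clamps))
  r_target <- pbn$nlev[[target]]
  grid_nodes <- free
  grids <- lapply(grid_nodes, function(v) seq_len(pbn$nlev[[v]]))
  names(grids) <- grid_nodes
  conf <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  value_of <- function(v) {
    if (v %in% names(clamps)) rep(clamps[[v]], nrow(conf)) else conf[, v]
  }
  w <- rep(1, nrow(conf))
  for (v in free) {
    cpt <- pbn$cpts[[v]]
    p <- mut[[v]]
    idx <- integer(nrow(conf))
    if (length(p)) {
      pr <- cpt$plev
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (value_of(p[j]) - 1L)
    }
    w <- w * cpt$prob[cbind(conf[, v], idx + 1L)]
  }
  out <- vapply(seq_len(r_target), function(k)
    sum(w[conf[, target] == k]), numeric(1))
  f <- sub("@t1?$", "", target)
  names(out) <- rownames(pbn$cpts[[target]]$prob)
  out / sum(out)
}

#' Interventional marginal distribution of a target node
#'
#' Applies the truncated factorization: the CPTs of intervened nodes are
#' removed, their values clamped, and all remaining nodes marginalised
#' exactly. Exact summation is over the target's ancestors in the
#' mutilated graph, which reproduces full-joint enumeration to machine
#' accuracy.
#'
#' @param pbn a [fit_parameters()] result.
#' @param do named list / vector of interventions, `node = level label`.
#' @param target node whose post-intervention marginal is wanted (must not
#'   itself be intervened on).
#' @return named probability vector over the target's levels.
#' @export
interventional_marginal <- function(pbn, do, target) {
  stopifnot(inherits(pbn, "param_bn"))
  do <- as.list(do)
  if (target %in% names(do)) {
    stop("target cannot be among the intervened nodes", call. = FALSE)
  }
  unknown <- setdiff(c(names(do), target), pbn$dag$nodes)
  if (length(unknown)) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  clamps <- lapply(names(do), function(v) {
    lev <- rownames(pbn$cpts[[v]]$prob)
    k <- match(as.character(do[[v]]), lev)
    if (is.na(k)) stop("'", do[[v]], "' is not a level of ", v, call. = FALSE)
    k
  })
  names(clamps) <- names(do)
  marginal_given_clamps(pbn, clamps, target)
}

#' Shortest interval containing a given posterior mass
#'
#' The highest-density credible interval of a sample of draws: the
#' narrowest contiguous window of the sorted values containing
#' `ceiling(mass * n)` points. Deterministic given the draws; no kernel
#' smoothing.
#'
#' @param values numeric vector of posterior draws (length >= 2).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return numeric `c(low, high)`.
#' @export
hdi <- function(values, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1) {
    stop("mass must be in (0, 1)", call. = FALSE)
  }
  values <- sort(values)
  n <- length(values)
  stopifnot(n >= 2L)
  k <- ceiling(mass * n)
  if (k >= n) return(c(values[1L], values[n]))
  starts <- seq_len(n - k + 1L)
  widths <- values[starts + k - 1L] - values[starts]
  i <- starts[which.min(widths)]
  c(values[i], values[i + k - 1L])
}

# collapse every factor column of a dataset to false/true labels
collapse_dataset <- function(dataset, specs) {
  specs <- as_spec_list(specs)
  df <- as.data.frame(dataset)
  out <- df
  bin_specs <- list()
  for (col in names(df)) {
    f <- sub("@t1?$", "", col)
    if (!f %in% names(specs)) next
    out[[col]] <- ifelse(collapse_to_binary(df[[col]], specs[[f]]),
                         "true", "false")
    if (is.null(bin_specs[[f]])) {
      bin_specs[[f]] <- binary_factor(f, specs[[f]]$domain_group)
    }
  }
  attr(out, "specs") <- as_spec_list(bin_specs)
  out
}

# distinct draws with multiplicities
dedupe_draws <- function(sample) {
  keys <- vapply(sample$dags, function(d)
    paste(vapply(sample$nodes, function(v)
      paste(sort(d[[v]]), collapse = ","), character(1)), collapse = ";"),
    character(1))
  first <- which(!duplicated(keys))
  counts <- as.numeric(table(keys)[keys[first]])
  list(idx = first, counts = counts)
}

# sufficient statistics per node for one structure (counts, not CPTs),
# so that CPT realisations can be drawn repeatedly from the Dirichlet
# posterior without re-tabulating
fit_family_counts <- function(parents_list, enc, nlev) {
  lapply(stats::setNames(names(parents_list), names(parents_list)),
         function(v) {
    p <- parents_list[[v]]
    r <- nlev[[v]]
    pr <- nlev[p]
    q <- if (length(pr)) prod(pr) else 1L
    idx <- integer(nrow(enc))
    if (length(p)) {
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (enc[, p[j]] - 1L)
    }
    counts <- tabulate(idx * r + (enc[, v] - 1L) + 1L, nbins = q * r)
    list(parents = p, plev = pr, njk = matrix(counts, nrow = r), q = q,
         r = r)
  })
}

# realise CPTs from family counts: Dirichlet posterior mean ("mean") or a
# Dirichlet posterior draw ("sample")
realise_cpts <- function(fam, prior_ess, cpt_draws, levels_of) {
  cpts <- lapply(names(fam), function(v) {
    fc <- fam[[v]]
    ajk <- prior_ess / (fc$q * fc$r)
    prob <- if (cpt_draws == "mean") {
      sweep(fc$njk + ajk, 2, colSums(fc$njk) + prior_ess / fc$q, "/")
    } else {
      gm <- matrix(stats::rgamma(length(fc$njk), shape = fc$njk + ajk),
                   nrow = fc$r)
      sweep(gm, 2, colSums(gm), "/")
    }
    rownames(prob) <- levels_of(v)
    list(parents = fc$parents, plev = fc$plev, prob = prob)
  })
  names(cpts) <- names(fam)
  cpts
}

# P(B = true | clamped nodes): direct CPT lookup when all of B's parents
# are clamped (the temporal-only two-slice case), exact elimination
# otherwise
prob_true_given <- function(pbn, clamps, B) {
  cpt <- pbn$cpts[[B]]
  p <- cpt$parents
  if (all(p %in% names(clamps))) {
    idx <- 0L
    if (length(p)) {
      pr <- cpt$plev
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (clamps[[p[j]]] - 1L)
    }
    return(cpt$prob["true", idx + 1L])
  }
  marginal_given_clamps(pbn, clamps, B)[["true"]]
}

# relative risk of one (A, B) pair under one CPT realisation
rr_value <- function(pbn, A, B, z_weights, mode) {
  parents <- lapply(pbn$cpts, `[[`, "parents")
  if (mode == "observational") {
    return(cond_prob_true(pbn, A, B, 2L) / cond_prob_true(pbn, A, B, 1L))
  }
  if (!A %in% ancestors_of(parents, B)) return(1)
  if (is.null(z_weights)) {
    pt <- marginal_given_clamps(pbn, stats::setNames(list(2L), A), B)[["true"]]
    pf <- marginal_given_clamps(pbn, stats::setNames(list(1L), A), B)[["true"]]
    return(pt / pf)
  }
  # two-slice: average P(B | do(A), Z = z) over the empirical joint of the
  # non-intervened time-t ancestors Z (g-computation with the observed
  # covariate distribution at time t)
  p_at <- function(aval) {
    sum(vapply(seq_along(z_weights$w), function(i) {
      clamps <- c(stats::setNames(list(aval), A), z_weights$configs[[i]])
      z_weights$w[i] * prob_true_given(pbn, clamps, B)
    }, numeric(1)))
  }
  p_at(2L) / p_at(1L)
}

# empirical joint of the time-t ancestors of B other than A (NULL when the
# sample is single-slice, meaning pure truncated factorisation applies)
z_weight_table <- function(parents_list, A, B, enc, slices) {
  if (is.null(slices)) return(NULL)
  mut <- parents_list
  mut[[A]] <- character(0)
  z <- setdiff(intersect(union(ancestors_of(mut, B), B), slices$t), A)
  if (!length(z)) return(list(w = 1, configs = list(stats::setNames(
    list(), character(0)))))
  zm <- enc[, z, drop = FALSE]
  key <- apply(zm, 1, paste, collapse = ",")
  tab <- table(key)
  rows <- match(names(tab), key)
  list(w = as.numeric(tab) / sum(tab),
       configs = lapply(rows, function(i)
         stats::setNames(as.list(zm[i, ]), z)))
}

# observational P(B = true | A = a) by enumeration over the union of
# ancestors of A and B (sensitivity-analysis mode)
cond_prob_true <- function(pbn, A, B, aval) {
  parents <- lapply(pbn$cpts, `[[`, "parents")
  relevant <- Reduce(union, list(ancestors_of(parents, A),
                                 ancestors_of(parents, B), c(A, B)))
  grids <- lapply(relevant, function(v) seq_len(pbn$nlev[[v]]))
  names(grids) <- relevant
  conf <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  w <- rep(1, nrow(conf))
  for (v in relevant) {
    cpt <- pbn$cpts[[v]]
    p <- cpt$parents
    idx <- integer(nrow(conf))
    if (length(p)) {
      pr <- cpt$plev
      for (j in rev(seq_along(p))) idx <- idx * pr[j] + (conf[, p[j]] - 1L)
    }
    w <- w * cpt$prob[cbind(conf[, v], idx + 1L)]
  }
  sel <- conf[, A] == aval
  sum(w[sel & conf[, B] == 2L]) / sum(w[sel])
}

#' Posterior-averaged interventional relative risk from factor A to B
#'
#' For each sampled structure, CPTs are fitted to the binary-collapsed
#' dataset (three-level diagnosis factors assign true to the sub- and
#' full-threshold levels and false otherwise) and the relative risk
#' \deqn{RR_G = P(B = \mathrm{true} \mid do(A = \mathrm{true})) /
#'   P(B = \mathrm{true} \mid do(A = \mathrm{false}))}
#' is computed by truncated factorization. The estimate is the mean over
#' draws together with the 95% highest-density credible interval of the
#' per-draw values, so it reflects both structure uncertainty (one draw
#' per sampled DAG) and, by default, parameter uncertainty (each draw's
#' CPTs are sampled from their Dirichlet posterior rather than plugged in
#' at the posterior mean). Effects with no directed path from A to B are
#' exactly 1. For two-slice samples A must be a `@t` node and B a `@t1`
#' node, and the time-t covariates are integrated over their empirical
#' joint.
#'
#' @param sample a `dbn_posterior`.
#' @param dataset the dataset the sample was learned from.
#' @param specs factor specs (defaults to the dataset attribute).
#' @param A source node; @param B target node (as named in the sample).
#' @param prior_ess Dirichlet prior equivalent sample size.
#' @param mass credible-interval mass (default 0.95).
#' @param mode `"interventional"` (default, do-operator) or
#'   `"observational"` (plain conditioning; sensitivity analysis).
#' @param cpt_draws `"sample"` (default): one Dirichlet-posterior CPT draw
#'   per retained structure draw, so the interval carries parameter
#'   uncertainty; `"mean"`: plug-in posterior-mean CPTs, so the interval
#'   reflects structure uncertainty only.
#' @param n_effect_draws cap on posterior draws used (evenly spaced
#'   subsample when the sample is larger).
#' @param seed seed for the CPT draws (deterministic estimates).
#' @return object of class `effect_estimate`: `source`, `target`,
#'   `rr_mean`, `rr_hdi`, `rr_draws` (one value per posterior draw),
#'   `reportable` (HDI excludes 1).
#' @export
causal_rr <- function(sample, dataset, specs = attr(dataset, "specs"),
                      A, B, prior_ess = 1, mass = 0.95,
                      mode = c("interventional", "observational"),
                      cpt_draws = c("sample", "mean"),
                      n_effect_draws = 250L, seed = 1L) {
  mode <- match.arg(mode)
  cpt_draws <- match.arg(cpt_draws)
  stopifnot(inherits(sample, "dbn_posterior"))
  if (!length(sample$dags)) stop("empty posterior sample", call. = FALSE)
  if (A == B) stop("A and B must differ", call. = FALSE)
  slices <- sample$meta$slices
  if (!is.null(slices)) {
    stopifnot(A %in% slices$t, B %in% slices$t1)
  }
  ctx <- rr_context(sample, dataset, specs, prior_ess, cpt_draws,
                    n_effect_draws, seed)
  rr_from_context(ctx, A, B, mass, mode)
}

# shared per-sample state for effect estimation: collapsed data, the
# (sub)set of draws used, their family counts (per distinct structure),
# and one CPT realisation per retained draw
rr_context <- function(sample, dataset, specs, prior_ess,
                       cpt_draws = "sample", n_effect_draws = 250L,
                       seed = 1L) {
  specs <- as_spec_list(specs)
  bin <- collapse_dataset(dataset, specs)
  bin_specs <- attr(bin, "specs")
  enc <- encode_dataset(bin, bin_specs, columns = sample$nodes)
  for (f in sample$nodes) {
    if (length(unique(enc[, f])) < 2L) {
      warning("factor column '", f, "' is degenerate after collapsing (",
              "single observed level); estimates rely on CPT smoothing",
              call. = FALSE)
    }
  }
  n_all <- length(sample$dags)
  keep <- if (n_all > n_effect_draws) {
    unique(round(seq(1L, n_all, length.out = n_effect_draws)))
  } else {
    seq_len(n_all)
  }
  keys <- vapply(sample$dags[keep], function(d)
    paste(vapply(sample$nodes, function(v)
      paste(sort(d[[v]]), collapse = ","), character(1)), collapse = ";"),
    character(1))
  uniq <- !duplicated(keys)
  fams <- lapply(which(uniq), function(i)
    fit_family_counts(sample$dags[[keep[i]]], enc, attr(enc, "nlev")))
  names(fams) <- keys[uniq]
  levels_of <- function(v) c("false", "true")
  set.seed(seed)
  pbns <- lapply(seq_along(keep), function(i) {
    cpts <- realise_cpts(fams[[keys[i]]], prior_ess, cpt_draws, levels_of)
    structure(list(dag = NULL, cpts = cpts, nlev = attr(enc, "nlev"),
                   prior_ess = prior_ess), class = "param_bn")
  })
  list(sample = sample, keys = keys, pbns = pbns, enc = enc,
       slices = sample$meta$slices)
}

rr_from_context <- function(ctx, A, B, mass = 0.95,
                            mode = "interventional") {
  zcache <- list()
  draws <- vapply(seq_along(ctx$pbns), function(i) {
    key <- ctx$keys[i]
    zw <- zcache[[key]]
    if (is.null(zw) && !is.null(ctx$slices)) {
      zw <- z_weight_table(lapply(ctx$pbns[[i]]$cpts, `[[`, "parents"),
                           A, B, ctx$enc, ctx$slices)
      zcache[[key]] <<- zw
    }
    rr_value(ctx$pbns[[i]], A, B, zw, mode)
  }, numeric(1))
  interval <- if (length(draws) >= 2L) hdi(draws, mass) else rep(draws, 2L)
  structure(list(source = A, target = B,
                 rr_mean = mean(draws), rr_hdi = interval,
                 rr_draws = draws,
                 reportable = interval[1L] > 1 || interval[2L] < 1),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s -> %s: RR %.3f (%.2f%% HDI %.3f-%.3f)%s\n",
              x$source, x$target, x$rr_mean, 95, x$rr_hdi[1], x$rr_hdi[2],
              if (x$reportable) "" else " [CI contains 1; suppressed]"))
  invisible(x)
}

#' Relative-risk matrix over all ordered factor pairs
#'
#' Computes [causal_rr()] for every ordered pair (all ordered pairs of
#' factors for an initial-network sample; every `@t` source against every
#' `@t1` target, including the same factor at both timepoints, for a
#' transition sample). Each cell is flagged `reportable` iff its HDI
#' excludes 1; exports conventionally render only reportable cells.
#'
#' @inheritParams causal_rr
#' @return data.frame with columns `source`, `target`, `rr_mean`,
#'   `hdi_low`, `hdi_high`, `reportable`.
#' @export
rr_matrix <- function(sample, dataset, specs = attr(dataset, "specs"),
                      prior_ess = 1, mass = 0.95,
                      mode = c("interventional", "observational"),
                      cpt_draws = c("sample", "mean"),
                      n_effect_draws = 250L, seed = 1L) {
  mode <- match.arg(mode)
  cpt_draws <- match.arg(cpt_draws)
  ctx <- rr_context(sample, dataset, specs, prior_ess, cpt_draws,
                    n_effect_draws, seed)
  slices <- sample$meta$slices
  pairs <- if (!is.null(slices)) {
    expand.grid(source = slices$t, target = slices$t1,
                stringsAsFactors = FALSE)
  } else {
    pg <- expand.grid(source = sample$nodes, target = sample$nodes,
                      stringsAsFactors = FALSE)
    pg[pg$source != pg$target, ]
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    est <- rr_from_context(ctx, pairs$source[i], pairs$target[i], mass, mode)
    data.frame(source = est$source, target = est$target,
               rr_mean = est$rr_mean, hdi_low = est$rr_hdi[1L],
               hdi_high = est$rr_hdi[2L], reportable = est$reportable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a relative-risk matrix to CSV
#'
#' By default only reportable cells (HDI excluding 1) are written, the
#' convention for presenting posterior effect matrices; set
#' `all_cells = TRUE` to keep every pair.
#'
#' @param rr data.frame from [rr_matrix()].
#' @param path output CSV path.
#' @param all_cells write suppressed cells too.
#' @return `path`, invisibly.
#' @export
write_rr_csv <- function(rr, path, all_cells = FALSE) {
  if (!all_cells) rr <- rr[rr$reportable, , drop = FALSE]
  utils::write.csv(rr, path, row.names = FALSE)
  invisible(path)
}
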