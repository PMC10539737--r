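# Synthetic-cohort generator: a known ground-truth DBN (initial network +
# homogeneous two-slice transition network) from which longitudinal cohorts
# with missed visits and dropout are sampled, so that every pipeline stage
# can be validated end-to-end against planted structure and effects.

clamp01 <- function(x, lo = 0.02, hi = 0.95) pmin(pmax(x, lo), hi)

#' Construct a parameterised Bayesian network directly
#'
#' Builds a `param_bn` from a DAG and explicit CPTs (as opposed to fitting
#' them from data with [fit_parameters()]); used to define ground truths.
#'
#' @param g a [dag()]; node names may carry `@t` / `@t1` suffixes.
#' @param cpts named list: node -> probability matrix `[child level,
#'   parent configuration]`, columns in the order of
#'   [parent_configs()] rows, each column summing to 1.
#' @param specs factor specs resolving each node's levels.
#' @return a `param_bn`.
#' @export
make_param_bn <- function(g, cpts, specs) {
  specs <- as_spec_list(specs)
  nlev <- vapply(g$nodes, function(v)
    length(specs[[sub("@t1?$", "", v)]]$levels), integer(1))
  built <- lapply(g$nodes, function(v) {
    p <- g$parents[[v]]
    pr <- nlev[p]
    q <- if (length(pr)) prod(pr) else 1L
    prob <- cpts[[v]]
    if (is.null(prob)) stop("missing CPT for node '", v, "'", call. = FALSE)
    prob <- as.matrix(prob)
    if (nrow(prob) != nlev[[v]] || ncol(prob) != q) {
      stop("CPT for '", v, "' must be ", nlev[[v]], " x ", q, call. = FALSE)
    }
    if (any(abs(colSums(prob) - 1) > 1e-12) || any(prob <= 0)) {
      stop("CPT columns for '", v,
           "' must be strictly positive and sum to 1", call. = FALSE)
    }
    dimnames(prob) <- list(specs[[sub("@t1?$", "", v)]]$levels, NULL)
    list(parents = p, plev = pr, prob = prob)
  })
  names(built) <- g$nodes
  structure(list(dag = g, cpts = built, nlev = nlev, prior_ess = NA_real_),
            class = "param_bn")
}

#' Parent-configuration grid matching CPT column order
#'
#' @param plev integer vector of parent cardinalities (in parent order).
#' @return data.frame, one row per CPT column, first parent varying
#'   fastest.
#' @export
parent_configs <- function(plev) {
  if (!length(plev)) return(data.frame(row.names = 1))
  expand.grid(lapply(plev, seq_len), KEEP.OUT.ATTRS = FALSE)
}

#' Bundle a ground-truth DBN
#'
#' @param specs factor specs.
#' @param initial `param_bn` over the factor names (time 0).
#' @param transition `param_bn` over `factor@t` / `factor@t1` nodes; must
#'   satisfy the two-slice invariants (exogenous, unconnected t slice).
#' @return object of class `ground_truth_dbn` with a `slices` layout.
#' @export
ground_truth_dbn <- function(specs, initial, transition) {
  specs <- as_spec_list(specs)
  sl <- slice_nodes(names(specs))
  stopifnot(setequal(initial$dag$nodes, names(specs)),
            setequal(transition$dag$nodes, c(sl$t, sl$t1)))
  if (!is_two_slice(transition$dag$parents, sl, allow_contemporaneous = TRUE)) {
    stop("transition network violates the two-slice slice constraints",
         call. = FALSE)
  }
  contemporaneous <- any(vapply(sl$t1, function(v)
    any(transition$dag$parents[[v]] %in% sl$t1), logical(1)))
  structure(list(specs = specs, initial = initial, transition = transition,
                 slices = sl, contemporaneous = contemporaneous),
            class = "ground_truth_dbn")
}

#' @export
print.ground_truth_dbn <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_dbn> %d factors; %d initial edges, %d transition edges%s\n",
    length(x$specs), nrow(dag_edges(x$initial$dag)),
    nrow(dag_edges(x$transition$dag)),
    if (x$contemporaneous) " (contemporaneous)" else ""))
  invisible(x)
}

#' Binary CPT from per-configuration success probabilities
#'
#' @param p_true vector of P(true), one entry per parent configuration in
#'   [parent_configs()] order.
#' @return 2 x q probability matrix (rows: false, true).
#' @export
cpt_binary <- function(p_true) rbind(1 - p_true, p_true)

#' Three-level diagnosis CPT from P(any threshold)
#'
#' The probability of any diagnosis is split 60/40 between the
#' subthreshold and full-threshold levels.
#'
#' @param p_any vector of P(sub- or full-threshold) per configuration.
#' @return 3 x q probability matrix (rows: none, subthreshold,
#'   full-threshold).
#' @export
cpt_diagnosis <- function(p_any) {
  rbind(1 - p_any, 0.6 * p_any, 0.4 * p_any)
}

#' Risk-multiplier CPT
#'
#' P(child active | configuration) = base rate times the product of the
#' multipliers of the parents whose value is in their truthy levels,
#' clamped to [0.02, 0.95]; a multiplier above 1 is a risk factor, below 1
#' protective.
#'
#' @param base baseline probability when no parent is active.
#' @param parents_spec list of the parents' [factor_spec()]s, in parent
#'   order.
#' @param mult numeric multipliers, one per parent.
#' @param three_level build a diagnosis CPT via [cpt_diagnosis()].
#' @return probability matrix over the child's levels.
#' @export
risk_cpt <- function(base, parents_spec, mult, three_level = FALSE) {
  plev <- vapply(parents_spec, function(sp) length(sp$levels), integer(1))
  cfg <- parent_configs(plev)
  p <- vapply(seq_len(nrow(cfg)), function(i) {
    m <- base
    for (j in seq_along(parents_spec)) {
      sp <- parents_spec[[j]]
      active <- sp$levels[cfg[i, j]] %in% sp$truthy_levels
      if (active) m <- m * mult[j]
    }
    clamp01(m)
  }, numeric(1))
  if (three_level) cpt_diagnosis(p) else cpt_binary(p)
}

#' Default ground-truth DBN emulating a youth mental-health cohort
#'
#' Sixteen categorical factors across five clinical domains (social and
#' occupational function, self-harm and suicidality, alcohol and substance
#' use, physical health, psychiatric syndromes), mostly binary plus two
#' three-level diagnosis factors. Baseline prevalences are drawn uniformly
#' in [0.05, 0.5] from the seed. The transition network plants a strong
#' same-factor persistence edge for every factor and a documented set of
#' cross-domain effects (function to ideation and self-harm, ideation to
#' attempt and self-harm, depression to ideation, cannabis to manic-like
#' experiences, alcohol to cannabis), each with a risk-multiplier contrast
#' of at least 1.5.
#'
#' @param seed integer seed fixing the drawn prevalences.
#' @return a [ground_truth_dbn()].
#' @export
make_default_truth <- function(seed = 1L) {
  set.seed(seed)
  specs <- as_spec_list(list(
    binary_factor("sofas_good", "function"),
    binary_factor("neet", "function"),
    binary_factor("ideation", "suicidality"),
    binary_factor("self_harm", "suicidality"),
    binary_factor("attempt", "suicidality"),
    binary_factor("alcohol_misuse", "substance"),
    binary_factor("cannabis_use", "substance"),
    binary_factor("other_drug_use", "substance"),
    binary_factor("physical_illness", "physical"),
    binary_factor("sleep_problem", "physical"),
    diagnosis_factor("depression", "syndrome"),
    diagnosis_factor("anxiety", "syndrome"),
    binary_factor("bipolar", "syndrome"),
    binary_factor("mle", "syndrome"),
    binary_factor("ple", "syndrome"),
    binary_factor("circadian_disturbance", "syndrome")
  ))
  fac <- names(specs)
  prev <- stats::setNames(stats::runif(length(fac), 0.05, 0.5), fac)
  # prevalence of sofas_good means prevalence of *good* functioning; keep
  # it common enough that both levels are well represented
  prev["sofas_good"] <- stats::runif(1, 0.4, 0.6)

  init_edges <- list(
    ideation = "depression",
    self_harm = "ideation",
    attempt = "ideation",
    neet = "sofas_good",
    anxiety = "depression",
    other_drug_use = "cannabis_use",
    ple = "mle",
    circadian_disturbance = "depression"
  )
  init_mult <- list(
    ideation = 3, self_harm = 3.5, attempt = 3, neet = 0.4,
    anxiety = 2.5, other_drug_use = 3, ple = 3.5,
    circadian_disturbance = 2.5
  )
  g0 <- dag(fac, init_edges)
  cpts0 <- lapply(fac, function(v) {
    three <- length(specs[[v]]$levels) == 3L
    p <- init_edges[[v]]
    if (is.null(p)) {
      if (three) cpt_diagnosis(prev[[v]]) else cpt_binary(prev[[v]])
    } else {
      risk_cpt(prev[[v]], specs[p], init_mult[[v]], three)
    }
  })
  names(cpts0) <- fac
  initial <- make_param_bn(g0, cpts0, specs)

  sl <- slice_nodes(fac)
  cross <- list( # child factor -> (parent factor, multiplier)
    ideation = list(c("sofas_good", 0.45), c("depression", 2.0)),
    self_harm = list(c("sofas_good", 0.55), c("ideation", 2.5)),
    attempt = list(c("ideation", 3.5)),
    mle = list(c("cannabis_use", 2.2)),
    cannabis_use = list(c("alcohol_misuse", 2.2))
  )
  persist <- stats::setNames(stats::runif(length(fac), 5, 9), fac)
  base_new <- clamp01(prev * 0.35, 0.03, 0.3)
  tr_parents <- list()
  tr_cpts <- list()
  for (v in fac) {
    extra <- cross[[v]] %||% list()
    pf <- c(v, vapply(extra, `[[`, character(1), 1L))
    mult <- c(persist[[v]], as.numeric(vapply(extra, `[[`, character(1), 2L)))
    tr_parents[[paste0(v, "@t1")]] <- paste0(pf, "@t")
    tr_cpts[[paste0(v, "@t1")]] <-
      risk_cpt(base_new[[v]], specs[pf], mult,
               three_level = length(specs[[v]]$levels) == 3L)
  }
  gt <- dag(c(sl$t, sl$t1), tr_parents)
  # exogenous @t nodes need placeholder marginals for the param_bn; they are
  # never used in simulation (slice-t values come from the previous slice)
  for (v in sl$t) {
    f <- sub("@t$", "", v)
    tr_cpts[[v]] <- if (length(specs[[f]]$levels) == 3L)
      cpt_diagnosis(prev[[f]]) else cpt_binary(prev[[f]])
  }
  transition <- make_param_bn(gt, tr_cpts, specs)
  ground_truth_dbn(specs, initial, transition)
}

#' Simulation settings for a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param n_timepoints maximum follow-up index plus one (t = 0 .. T - 1).
#' @param missing_timepoint_rate probability a scheduled visit record is
#'   missing entirely (missed visit, MCAR); subjects can reappear after a
#'   gap.
#' @param dropout_rate per-step geometric probability that a subject stops
#'   attending for good after a timepoint.
#' @param seed integer seed.
#' @param informative_missingness optional list `(factor, multiplier)`
#'   multiplying the missed-visit odds when the factor is active at that
#'   visit, to probe the missing-at-random assumption.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2663L, n_timepoints = 4L,
                       missing_timepoint_rate = 0.2, dropout_rate = 0.15,
                       seed = 1L, informative_missingness = NULL) {
  stopifnot(n_subjects >= 1L, n_timepoints >= 1L,
            missing_timepoint_rate >= 0, missing_timepoint_rate < 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 missing_timepoint_rate = missing_timepoint_rate,
                 dropout_rate = dropout_rate, seed = seed,
                 informative_missingness = informative_missingness),
            class = "sim_config")
}

sample_node_values <- function(cpt, parent_vals) {
  n <- if (length(cpt$parents)) nrow(parent_vals) else parent_vals
  idx <- integer(n)
  if (length(cpt$parents)) {
    pr <- cpt$plev
    for (j in rev(seq_along(cpt$parents))) {
      idx <- idx * pr[j] + (parent_vals[, j] - 1L)
    }
  }
  pm <- cpt$prob[, idx + 1L, drop = FALSE]
  cum <- apply(pm, 2, cumsum)
  r <- nrow(cum)
  u <- stats::runif(n)
  if (r == 2L) {
    1L + as.integer(u > cum[1L, ])
  } else {
    1L + colSums(cum[-r, , drop = FALSE] < rep(u, each = r - 1L))
  }
}

#' Simulate a longitudinal cohort from a ground-truth DBN
#'
#' Time 0 is drawn from the initial network by ancestral sampling; each
#' later timepoint from the transition network given the previous one
#' (contemporaneous parents are resolved in topological order within the
#' new slice). Whole visit records are then deleted at the missed-visit
#' rate and subjects truncated after a geometric dropout draw, emulating
#' irregular service attendance with reappearance after gaps.
#'
#' @param truth a [ground_truth_dbn()].
#' @param config a [sim_config()].
#' @return a [cohort_table()] carrying the truth's factor specs.
#' @export
simulate_cohort <- function(truth, config = sim_config()) {
  stopifnot(inherits(truth, "ground_truth_dbn"),
            inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  tt <- config$n_timepoints
  fac <- names(truth$specs)
  vals <- array(NA_integer_, c(n, tt, length(fac)),
                dimnames = list(NULL, NULL, fac))
  ord0 <- dag_topo_order(truth$initial$dag)
  for (v in ord0) {
    cpt <- truth$initial$cpts[[v]]
    pv <- if (length(cpt$parents)) {
      matrix(vals[, 1L, cpt$parents], ncol = length(cpt$parents))
    } else n
    vals[, 1L, v] <- sample_node_values(cpt, pv)
  }
  if (tt > 1L) {
    sl <- truth$slices
    sub <- truth$transition$dag$parents[sl$t1]
    ord1 <- sl$t1[order(match(sl$t1, dag_topo_order(truth$transition$dag)))]
    for (t in 2:tt) {
      for (v1 in ord1) {
        cpt <- truth$transition$cpts[[v1]]
        f1 <- sub("@t1$", "", v1)
        if (length(cpt$parents)) {
          pv <- sapply(cpt$parents, function(p) {
            if (grepl("@t1$", p)) vals[, t, sub("@t1$", "", p)]
            else vals[, t - 1L, sub("@t$", "", p)]
          })
          if (!is.matrix(pv)) pv <- matrix(pv, ncol = length(cpt$parents))
        } else {
          pv <- n
        }
        vals[, t, f1] <- sample_node_values(cpt, pv)
      }
    }
  }
  horizon <- if (config$dropout_rate > 0) {
    pmin(1L + stats::rgeom(n, config$dropout_rate), tt)
  } else {
    rep(tt, n)
  }
  observed <- outer(horizon, seq_len(tt), `>=`)
  if (config$missing_timepoint_rate > 0) {
    pmiss <- matrix(config$missing_timepoint_rate, n, tt)
    im <- config$informative_missingness
    if (!is.null(im)) {
      sp <- truth$specs[[im$factor]]
      active <- matrix(sp$levels[vals[, , im$factor]] %in% sp$truthy_levels,
                       n, tt)
      odds <- pmiss / (1 - pmiss) * ifelse(active, im$multiplier, 1)
      pmiss <- odds / (1 + odds)
    }
    observed <- observed & matrix(stats::runif(n * tt), n, tt) >= pmiss
  }
  idx <- which(observed, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(
    subject_id = sprintf("S%05d", idx[, 1]),
    timepoint = idx[, 2] - 1L,
    stringsAsFactors = FALSE
  )
  for (f in fac) {
    out[[f]] <- truth$specs[[f]]$levels[vals[cbind(idx[, 1], idx[, 2],
                                                   match(f, fac))]]
  }
  cohort_table(out, truth$specs)
}

#' Analytic time-0 marginal of a factor under the truth
#'
#' Exact summation over the initial network's joint (an oracle for
#' checking simulated frequencies).
#'
#' @param truth a [ground_truth_dbn()].
#' @param factor factor name.
#' @return named probability vector over the factor's levels.
#' @export
initial_marginal <- function(truth, factor) {
  marginal_given_clamps(truth$initial, list(), factor)
}

#' Analytic interventional relative risk implied by the truth
#'
#' Brute-force joint summation: the time-t slice distribution is taken as
#' the initial network's joint, the intervened factor is clamped, and the
#' transition CPT of the target is averaged over the marginal joint of the
#' remaining time-t factors. Requires a temporal-only (non-contemporaneous)
#' truth and a binary source factor; "true" for a three-level target means
#' its truthy levels.
#'
#' @param truth a [ground_truth_dbn()].
#' @param A source factor (binary); @param B target factor.
#' @return the relative risk RR = P(B active | do(A = true)) /
#'   P(B active | do(A = false)).
#' @export
analytic_transition_rr <- function(truth, A, B) {
  stopifnot(!truth$contemporaneous)
  spA <- truth$specs[[A]]
  stopifnot(length(spA$levels) == 2L)
  cpt <- truth$transition$cpts[[paste0(B, "@t1")]]
  pf <- sub("@t$", "", cpt$parents)
  z <- setdiff(pf, A)
  spB <- truth$specs[[B]]
  truthy_idx <- match(spB$truthy_levels, spB$levels)
  p_active <- function(aval) {
    if (!A %in% pf) {
      # A has no direct arrow into B; with an exogenous, temporal-only
      # truth there is no other path, so the intervention is inert
      cfg <- parent_configs(cpt$plev)
      w <- joint_weights(truth$initial, pf)
      return(sum(vapply(seq_len(nrow(cfg)), function(i) {
        wi <- w[[paste(unlist(cfg[i, ]), collapse = ",")]] %||% 0
        wi * sum(cpt$prob[truthy_idx, i])
      }, numeric(1))))
    }
    w <- joint_weights(truth$initial, z)
    cfg <- parent_configs(cpt$plev)
    total <- 0
    for (i in seq_len(nrow(cfg))) {
      v <- unlist(cfg[i, ])
      names(v) <- pf
      if (v[[A]] != aval) next
      key <- paste(v[z], collapse = ",")
      wi <- if (length(z)) (w[[key]] %||% 0) else 1
      total <- total + wi * sum(cpt$prob[truthy_idx, i])
    }
    total
  }
  tru <- match("true", spA$levels)
  fal <- match("false", spA$levels)
  p_active(tru) / p_active(fal)
}

# marginal joint of a subset of time-0 factors, as an environment-free
# lookup: key "v1,v2,..." (integer levels, subset order) -> probability
joint_weights <- function(pbn, subset) {
  nodes <- pbn$dag$nodes
  if (prod(pbn$nlev) > 1e6) {
    stop("joint enumeration guarded to 1e6 configurations", call. = FALSE)
  }
  grids <- lapply(nodes, function(v) seq_len(pbn$nlev[[v]]))
  names(grids) <- nodes
  conf <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  w <- rep(1, nrow(conf))
  for (v in nodes) {
    cpt <- pbn$cpts[[v]]
    idx <- integer(nrow(conf))
    if (length(cpt$parents)) {
      pr <- cpt$plev
      for (j in rev(seq_along(cpt$parents))) {
        idx <- idx * pr[j] + (conf[, cpt$parents[j]] - 1L)
      }
    }
    w <- w * cpt$prob[cbind(conf[, v], idx + 1L)]
  }
  if (!length(subset)) return(list())
  key <- apply(conf[, subset, drop = FALSE], 1, paste, collapse = ",")
  as.list(tapply(w, key, sum))
}

#' Compare learned edge probabilities against the planted structure
#'
#' @param truth a [ground_truth_dbn()].
#' @param edge_prob matrix of learned edge probabilities (from
#'   [edge_probabilities()] or [exact_transition_posterior()]).
#' @param network `"transition"` (default; candidate edges are all
#'   `@t` to `@t1` pairs, plus `@t1` pairs when the truth is
#'   contemporaneous) or `"initial"` (all ordered factor pairs).
#' @return list: `edges` (data.frame of pair, truth label, probability),
#'   `tpr` and `fpr` at probability > 0.5, and `auc`.
#' @export
structure_recovery_report <- function(truth, edge_prob,
                                      network = c("transition", "initial")) {
  network <- match.arg(network)
  if (network == "transition") {
    sl <- truth$slices
    pairs <- expand.grid(from = sl$t, to = sl$t1, stringsAsFactors = FALSE)
    if (truth$contemporaneous) {
      pg <- expand.grid(from = sl$t1, to = sl$t1, stringsAsFactors = FALSE)
      pairs <- rbind(pairs, pg[pg$from != pg$to, ])
    }
    true_dag <- truth$transition$dag
  } else {
    fac <- names(truth$specs)
    pairs <- expand.grid(from = fac, to = fac, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$from != pairs$to, ]
    true_dag <- truth$initial$dag
  }
  if (!all(c(pairs$from, pairs$to) %in% rownames(edge_prob))) {
    stop("edge probability matrix does not cover the truth's nodes",
         call. = FALSE)
  }
  pairs$truth <- vapply(seq_len(nrow(pairs)), function(i)
    pairs$from[i] %in% true_dag$parents[[pairs$to[i]]], logical(1))
  pairs$probability <- edge_prob[cbind(pairs$from, pairs$to)]
  roc <- pROC::roc(response = pairs$truth, predictor = pairs$probability,
                   quiet = TRUE, direction = "<", levels = c(FALSE, TRUE))
  list(edges = pairs,
       tpr = mean(pairs$probability[pairs$truth] > 0.5),
       fpr = mean(pairs$probability[!pairs$truth] > 0.5),
       auc = as.numeric(roc$auc))
}

#' Serialise a ground truth to JSON
#'
#' Writes factor specs, both edge lists, and all CPTs as plain text for
#' provenance alongside a simulated cohort.
#'
#' @param truth a [ground_truth_dbn()].
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    factors = lapply(truth$specs, function(sp)
      list(levels = sp$levels, domain_group = sp$domain_group,
           truthy_levels = sp$truthy_levels)),
    initial_edges = as.data.frame(dag_edges(truth$initial$dag)),
    transition_edges = as.data.frame(dag_edges(truth$transition$dag)),
    initial_cpts = lapply(truth$initial$cpts, function(cpt)
      list(parents = cpt$parents, prob = cpt$prob)),
    transition_cpts = lapply(truth$transition$cpts, function(cpt)
      list(parents = cpt$parents, prob = cpt$prob))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
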