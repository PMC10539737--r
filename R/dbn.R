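#' Configuration of the transition-network analysis
#'
#' The primary analysis assumes factors at t + 1 are conditionally
#' independent given the factors at t, so edges run only from the t slice
#' to the t + 1 slice. The secondary analysis additionally allows
#' contemporaneous edges among the t + 1 factors. In both regimes the t
#' slice is exogenous: nothing points into a `@t` node and `@t` nodes are
#' mutually unconnected (their joint is the initial network's business).
#'
#' @param allow_contemporaneous allow edges among `@t1` nodes.
#' @param constraint an [edge_constraint()] expressed on slice node names
#'   (`factor@t`, `factor@t1`); slice rules are enforced on top of it.
#' @param ess equivalent sample size for scoring.
#' @param factors optional subset of factor names to model.
#' @param static_factors factors treated as fixed covariates: they appear
#'   only as exogenous `@t` candidates, never as `@t1` children.
#' @return object of class `transition_config`.
#' @export
transition_config <- function(allow_contemporaneous = FALSE,
                              constraint = edge_constraint(),
                              ess = 1, factors = NULL,
                              static_factors = character(0)) {
  structure(list(allow_contemporaneous = isTRUE(allow_contemporaneous),
                 constraint = constraint, ess = ess, factors = factors,
                 static_factors = as.character(static_factors)),
            class = "transition_config")
}

#' Slice node layout of a two-slice transition network
#'
#' Maps factor names to their `@t` (time t, exogenous) and `@t1`
#' (time t + 1, modelled) node names.
#'
#' @param factors factor names.
#' @param static_factors factors present only as `@t` covariates.
#' @return list with `t`, `t1`, `factors`, `dynamic`.
#' @export
slice_nodes <- function(factors, static_factors = character(0)) {
  dynamic <- setdiff(factors, static_factors)
  list(t = paste0(factors, "@t"),
       t1 = paste0(dynamic, "@t1"),
       factors = factors, dynamic = dynamic)
}

#' Learn the initial network
#'
#' Samples the structure posterior of the network over factors at first
#' presentation (t = 0), using the complete-case t = 0 dataset.
#'
#' @param table a [cohort_table()] (or a prebuilt `initial_dataset`).
#' @param specs factor specs (defaults to the table attribute).
#' @param constraint an [edge_constraint()] on factor names.
#' @param ess equivalent sample size.
#' @param seed integer seed (required).
#' @param ... chain settings passed to [partition_mcmc_sample()]
#'   (`n_iter`, `burn_in`, `thin`, `n_chains`).
#' @return a `dbn_posterior` over the factor set.
#' @export
learn_initial_network <- function(table, specs = attr(table, "specs"),
                                  constraint = edge_constraint(),
                                  ess = 1, seed, ...) {
  dataset <- if (inherits(table, "initial_dataset")) table
             else build_initial_dataset(table, specs)
  partition_mcmc_sample(dataset, specs, constraint, ess, seed = seed, ...)
}

#' Learn the transition network
#'
#' Samples the structure posterior of the two-slice transition network on
#' the stacked complete consecutive-pair dataset. Only the `@t1` families
#' are modelled; `@t` nodes are exogenous. With
#' `config$allow_contemporaneous = FALSE` every sampled graph is bipartite
#' from the t slice to the t + 1 slice; otherwise acyclic dependencies
#' among `@t1` nodes are also explored.
#'
#' @param table a [cohort_table()] (or a prebuilt `transition_dataset`).
#' @param specs factor specs (defaults to the table attribute).
#' @param config a [transition_config()].
#' @param seed integer seed (required).
#' @param ... chain settings passed to [partition_mcmc_sample()].
#' @return a `dbn_posterior` over `factor@t` / `factor@t1` nodes, with
#'   `meta$slices` recording the slice layout.
#' @export
learn_transition_network <- function(table, specs = attr(table, "specs"),
                                     config = transition_config(),
                                     seed, ...) {
  stopifnot(inherits(config, "transition_config"))
  specs <- as_spec_list(specs)
  dataset <- if (inherits(table, "transition_dataset")) table
             else build_transition_dataset(table, specs)
  fac <- if (is.null(config$factors)) names(specs) else config$factors
  sl <- slice_nodes(fac, config$static_factors)
  nodes <- c(sl$t, sl$t1)
  candidates <- c(
    stats::setNames(rep(list(character(0)), length(sl$t)), sl$t),
    stats::setNames(lapply(sl$t1, function(v) {
      if (config$allow_contemporaneous) c(sl$t, setdiff(sl$t1, v)) else sl$t
    }), sl$t1)
  )
  sample <- partition_mcmc_sample(dataset, specs, config$constraint,
                                  config$ess, seed = seed, nodes = nodes,
                                  candidates = candidates, ...)
  sample$meta$slices <- sl
  sample$meta$allow_contemporaneous <- config$allow_contemporaneous
  sample
}

#' Exact factorized posterior of the temporal-only transition network
#'
#' Under the primary regime (no contemporaneous edges) every graph from t
#' to t + 1 is bipartite and automatically acyclic, so the structure
#' posterior factorises over the `@t1` children: each child's parent-set
#' posterior is an independent normalised table. This gives exact edge
#' probabilities against which the MCMC sampler can be validated at any
#' problem size whose parent sets are enumerable.
#'
#' @param dataset a `transition_dataset`.
#' @param specs factor specs (defaults to the dataset attribute).
#' @param config a [transition_config()] with
#'   `allow_contemporaneous = FALSE`.
#' @return list: per-child tables (`parent_sets`, `posterior`), and
#'   `edge_prob` over the full slice node set.
#' @export
exact_transition_posterior <- function(dataset,
                                       specs = attr(dataset, "specs"),
                                       config = transition_config()) {
  stopifnot(inherits(config, "transition_config"))
  if (config$allow_contemporaneous) {
    stop("the factorized posterior requires allow_contemporaneous = FALSE",
         call. = FALSE)
  }
  specs <- as_spec_list(specs)
  fac <- if (is.null(config$factors)) names(specs) else config$factors
  sl <- slice_nodes(fac, config$static_factors)
  nodes <- c(sl$t, sl$t1)
  enc <- encode_dataset(dataset, specs, columns = nodes)
  constraint <- config$constraint
  cand_all <- candidate_parent_sets(
    nodes, constraint,
    allowed = c(stats::setNames(rep(list(character(0)), length(sl$t)), sl$t),
                stats::setNames(rep(list(sl$t), length(sl$t1)), sl$t1)))
  reqs <- required_parent_sets(nodes, constraint)
  tables <- build_score_tables(enc, sl$t1, cand_all, constraint$max_parents,
                               config$ess, reqs)
  edge_prob <- matrix(0, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
  children <- lapply(tables, function(tb) {
    post <- exp(tb$score - logsumexp(tb$score))
    post <- post / sum(post)
    sets <- lapply(tb$mask, mask_to_parents, cand = tb$cand)
    for (p in tb$cand) {
      in_set <- vapply(sets, function(s) p %in% s, logical(1))
      edge_prob[p, tb$node] <<- sum(post[in_set])
    }
    list(node = tb$node, parent_sets = sets, posterior = post)
  })
  list(children = children, edge_prob = edge_prob, nodes = nodes,
       slices = sl)
}

#' Check the two-slice structural invariants of a sampled graph
#'
#' @param parents named parent-set list (one posterior draw).
#' @param slices slice layout from `meta$slices`.
#' @param allow_contemporaneous whether `@t1` to `@t1` edges are legal.
#' @return `TRUE` if no edge points into the t slice, no edge joins two t
#'   nodes, and `@t1` edges appear only when allowed.
#' @export
is_two_slice <- function(parents, slices, allow_contemporaneous = FALSE) {
  for (v in slices$t) {
    if (length(parents[[v]])) return(FALSE)
  }
  for (v in slices$t1) {
    p <- parents[[v]]
    if (!allow_contemporaneous && any(p %in% slices$t1)) return(FALSE)
    if (!all(p %in% c(slices$t, slices$t1))) return(FALSE)
  }
  TRUE
}
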