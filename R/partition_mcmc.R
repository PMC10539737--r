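# Partition MCMC over DAG posteriors.
#
# The chain's state is an ordered partition (p1, ..., pm) of the node set.
# A DAG is compatible with exactly one ordered partition: p1 holds its
# parentless nodes, and a node sits in p_i (i > 1) iff all its parents lie
# in p1 ... p_{i-1} with at least one in p_{i-1}. The partition's score is
# the sum over compatible DAGs of exp(posterior score), which factorises
# over nodes: each node contributes the log-sum-exp of its family scores
# over parent sets drawn from the preceding parts and touching the adjacent
# part. Sampling partitions proportional to this score and then drawing a
# DAG from the partition's conditional therefore samples DAGs from the
# structure posterior without bias.

new_dag_unchecked <- function(nodes, parents) {
  structure(list(nodes = nodes, parents = parents), class = "bn_dag")
}

# contribution of one node given its part's context; memoised on the
# node's local (U, A) masks. Returns list(idx = allowed set indices,
# lse = log-sum-exp of their scores).
node_context <- function(tb, u_nodes, a_nodes, first_part, cache) {
  um <- local_mask(tb$cand, u_nodes)
  am <- local_mask(tb$cand, a_nodes)
  key <- paste0(tb$node, ":", if (first_part) "0" else paste0(um, ":", am))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  idx <- if (first_part) {
    which(tb$mask == 0L)
  } else {
    # subset test written as mask & U == mask: bitwNot(um) would hit the
    # NA sentinel (INT_MIN) when all 31 candidate bits are set
    which(bitwAnd(tb$mask, um) == tb$mask & bitwAnd(tb$mask, am) != 0L)
  }
  out <- list(idx = idx, lse = logsumexp(tb$score[idx]))
  cache[[key]] <- out
  out
}

partition_contributions <- function(parts, nodes, tables, cache) {
  contrib <- stats::setNames(numeric(length(nodes)), nodes)
  u <- character(0)
  a <- character(0)
  for (i in seq_along(parts)) {
    part_nodes <- nodes[parts[[i]]]
    for (v in part_nodes) {
      contrib[v] <- node_context(tables[[v]], u, a, i == 1L, cache)$lse
    }
    a <- part_nodes
    u <- c(u, part_nodes)
  }
  contrib
}

# draw one DAG from the partition's conditional distribution
draw_dag_from_partition <- function(parts, nodes, tables, cache) {
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  u <- character(0)
  a <- character(0)
  for (i in seq_along(parts)) {
    part_nodes <- nodes[parts[[i]]]
    for (v in part_nodes) {
      tb <- tables[[v]]
      ctx <- node_context(tb, u, a, i == 1L, cache)
      if (!length(ctx$idx)) stop("internal: empty support in DAG draw")
      w <- exp(tb$score[ctx$idx] - ctx$lse)
      pick <- ctx$idx[sample.int(length(ctx$idx), 1L, prob = w)]
      parents[[v]] <- mask_to_parents(tb$cand, tb$mask[pick])
    }
    a <- part_nodes
    u <- c(u, part_nodes)
  }
  parents
}

propose_relocation <- function(parts, n) {
  x <- sample.int(n, 1L)
  q <- lapply(parts, function(p) p[p != x])
  q <- q[lengths(q) > 0L]
  m <- length(q)
  k <- sample.int(2L * m + 1L, 1L)
  if (k <= m) {
    q[[k]] <- c(q[[k]], x)
  } else {
    gap <- k - m # 1 .. m+1, insert new singleton before position `gap`
    q <- append(q, list(x), after = gap - 1L)
  }
  q
}

propose_swap <- function(parts, n) {
  xy <- sample.int(n, 2L)
  lapply(parts, function(p) {
    p[p == xy[1L]] <- 0L
    p[p == xy[2L]] <- xy[1L]
    p[p == 0L] <- xy[2L]
    p
  })
}

# reverse a contiguous run of parts: an involution for a fixed (i, j), so
# the proposal is symmetric. Jumps directly between partitions of
# Markov-equivalent orientations (e.g. a chain and its reversal), which
# single-node moves only reach through deep posterior valleys.
propose_reversal <- function(parts) {
  m <- length(parts)
  if (m < 2L) return(parts)
  ij <- sort(sample.int(m, 2L))
  parts[ij[1L]:ij[2L]] <- rev(parts[ij[1L]:ij[2L]])
  parts
}

# the unique ordered partition a DAG is compatible with: p1 holds the
# parentless nodes; p_i the nodes with all parents placed and at least one
# in p_{i-1} (used to seed the chain when required edges exist)
partition_of_dag <- function(g) {
  nodes <- g$nodes
  parts <- list()
  remaining <- nodes
  placed <- character(0)
  prev <- character(0)
  while (length(remaining)) {
    nxt <- if (!length(parts)) {
      remaining[lengths(g$parents[remaining]) == 0L]
    } else {
      remaining[vapply(remaining, function(v) {
        p <- g$parents[[v]]
        length(p) > 0L && all(p %in% placed) && any(p %in% prev)
      }, logical(1))]
    }
    if (!length(nxt)) stop("internal: cannot layer DAG", call. = FALSE)
    parts <- c(parts, list(match(nxt, nodes)))
    prev <- nxt
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  parts
}

run_partition_chain <- function(tables, nodes, n_iter, burn_in, thin, seed,
                                start_parts = NULL, p_swap = 0.1,
                                p_reversal = 0.15, log_moves = FALSE) {
  set.seed(seed)
  n <- length(nodes)
  cache <- new.env(parent = emptyenv())
  parts <- start_parts %||% list(seq_len(n))
  contrib <- partition_contributions(parts, nodes, tables, cache)
  score <- sum(contrib)
  if (!is.finite(score)) {
    stop("starting partition has zero posterior mass; check constraints",
         call. = FALSE)
  }
  draws <- list()
  draw_scores <- numeric(0)
  accepts <- 0L
  moves <- if (log_moves) vector("list", n_iter) else NULL
  for (it in seq_len(n_iter)) {
    u_move <- stats::runif(1)
    prop <- if (n >= 2L && u_move < p_swap) {
      propose_swap(parts, n)
    } else if (u_move < p_swap + p_reversal) {
      propose_reversal(parts)
    } else {
      propose_relocation(parts, n)
    }
    prop_contrib <- partition_contributions(prop, nodes, tables, cache)
    prop_score <- sum(prop_contrib)
    log_alpha <- prop_score - score
    acc <- is.finite(prop_score) && log(stats::runif(1)) < log_alpha
    if (log_moves) {
      moves[[it]] <- c(log_ratio = log_alpha, accepted = as.numeric(acc))
    }
    if (acc) {
      parts <- prop
      score <- prop_score
      accepts <- accepts + 1L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      draws[[length(draws) + 1L]] <-
        draw_dag_from_partition(parts, nodes, tables, cache)
      draw_scores <- c(draw_scores, score)
    }
  }
  list(draws = draws, partition_scores = draw_scores,
       acceptance_rate = accepts / n_iter,
       moves = if (log_moves) do.call(rbind, moves) else NULL)
}

#' Sample DAGs from the structure posterior by partition MCMC
#'
#' Runs a Metropolis-Hastings chain over ordered partitions of the node set
#' whose stationary law, combined with a conditional DAG draw per recorded
#' iteration, is the BDeu structure posterior P(G | D) restricted to the
#' edge constraint's support. Moves are single-node relocations and node
#' swaps, both with symmetric proposals. Identical inputs and seed yield
#' an identical sample.
#'
#' @param dataset complete-case dataset whose factor columns are the nodes.
#' @param specs factor specs (defaults to the dataset attribute).
#' @param constraint an [edge_constraint()].
#' @param ess equivalent sample size.
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded at the start (default 25% of
#'   `n_iter`); must be below `n_iter`.
#' @param thin record one DAG every `thin` post-burn-in iterations.
#' @param seed integer seed; required. Chain `c` uses `seed + c - 1`.
#' @param n_chains independent chains to run and pool (default 2).
#' @param nodes node columns (default: all factor columns).
#' @param candidates optional named list child -> candidate parents,
#'   overriding the all-other-nodes default (used for two-slice learning).
#' @param log_moves keep per-iteration proposal log-ratios in `meta$moves`.
#' @return object of class `dbn_posterior`: `dags` (list of named
#'   parent-set lists), `nodes`, and `meta` (seed, chain settings, ESS,
#'   constraint key, acceptance rates, per-chain draw counts).
#' @export
partition_mcmc_sample <- function(dataset, specs = attr(dataset, "specs"),
                                  constraint = edge_constraint(),
                                  ess = 1, n_iter = 20000L,
                                  burn_in = floor(n_iter / 4),
                                  thin = 20L, seed,
                                  n_chains = 2L, nodes = NULL,
                                  candidates = NULL, log_moves = FALSE) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for a reproducible posterior sample",
         call. = FALSE)
  }
  stopifnot(n_iter > burn_in, thin >= 1L, n_chains >= 1L)
  specs <- as_spec_list(specs)
  df <- as.data.frame(dataset)
  if (is.null(nodes)) nodes <- intersect(names(df), names(specs))
  enc <- encode_dataset(dataset, specs, columns = nodes)
  cands <- candidate_parent_sets(nodes, constraint, allowed = candidates)
  reqs <- required_parent_sets(nodes, constraint)
  tables <- build_score_tables(enc, nodes, cands, constraint$max_parents,
                               ess, reqs)
  start_parts <- NULL
  if (nrow(constraint$required)) {
    g0 <- dag(nodes, split(constraint$required[, "from"],
                           constraint$required[, "to"]))
    start_parts <- partition_of_dag(g0)
  }
  chains <- lapply(seq_len(n_chains), function(c) {
    run_partition_chain(tables, nodes, n_iter, burn_in, thin,
                        seed = seed + c - 1L, start_parts = start_parts,
                        log_moves = log_moves)
  })
  dags <- do.call(c, lapply(chains, `[[`, "draws"))
  structure(list(
    dags = dags,
    nodes = nodes,
    meta = list(seed = seed, n_iter = n_iter, burn_in = burn_in,
                thin = thin, ess = ess,
                constraint = constraint_key(constraint),
                n_chains = n_chains,
                chain_draws = vapply(chains, function(ch)
                  length(ch$draws), integer(1)),
                acceptance_rates = vapply(chains, `[[`, numeric(1),
                                          "acceptance_rate"),
                moves = if (log_moves) lapply(chains, `[[`, "moves"))
  ), class = "dbn_posterior")
}

#' @export
print.dbn_posterior <- function(x, ...) {
  cat(sprintf("<dbn_posterior> %d draws over %d nodes (%d chains, ESS %g)\n",
              length(x$dags), length(x$nodes), x$meta$n_chains, x$meta$ess))
  invisible(x)
}

#' Materialise one posterior draw as a DAG object
#' @param sample a `dbn_posterior`.
#' @param i draw index.
#' @return a [dag()].
#' @export
posterior_dag <- function(sample, i) {
  new_dag_unchecked(sample$nodes, sample$dags[[i]])
}

#' Posterior edge probabilities from a DAG sample
#'
#' The probability of an edge is the number of sampled DAGs containing it
#' divided by the number of samples.
#'
#' @param sample a `dbn_posterior`.
#' @return matrix indexed `[from, to]` with values in `[0, 1]`.
#' @export
edge_probabilities <- function(sample) {
  stopifnot(inherits(sample, "dbn_posterior"), length(sample$dags) > 0L)
  nodes <- sample$nodes
  n <- length(nodes)
  acc <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (d in sample$dags) {
    to <- rep(names(d), lengths(d))
    from <- unlist(d, use.names = FALSE)
    if (length(from)) {
      ij <- cbind(match(from, nodes), match(to, nodes))
      acc[ij] <- acc[ij] + 1
    }
  }
  acc / length(sample$dags)
}

#' Serialise a posterior sample to JSON-lines
#'
#' First line is a metadata object, then one JSON object per sampled DAG
#' mapping each node to its parent vector.
#'
#' @param sample a `dbn_posterior`.
#' @param path output file (plain text; `.gz` paths are gzip-compressed).
#' @return `path`, invisibly.
#' @export
write_posterior_jsonl <- function(sample, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  meta <- sample$meta
  meta$moves <- NULL
  writeLines(jsonlite::toJSON(c(list(nodes = sample$nodes), meta),
                              auto_unbox = TRUE), con)
  for (d in sample$dags) {
    writeLines(jsonlite::toJSON(lapply(d, as.character)), con)
  }
  invisible(path)
}

#' Read a posterior sample written by [write_posterior_jsonl()]
#' @param path JSON-lines file (optionally gzipped).
#' @return a `dbn_posterior`.
#' @export
read_posterior_jsonl <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  meta <- jsonlite::fromJSON(lines[1L])
  nodes <- meta$nodes
  meta$nodes <- NULL
  dags <- lapply(lines[-1L], function(l) {
    d <- jsonlite::fromJSON(l)
    parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
    for (v in names(d)) parents[[v]] <- as.character(unlist(d[[v]]))
    parents
  })
  structure(list(dags = dags, nodes = nodes, meta = meta),
            class = "dbn_posterior")
}
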