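# --- minimal exact big-integer arithmetic (non-negative, base 1e4) ---------
# needed because labelled-DAG counts overflow doubles from n = 10 or so and
# no arbitrary-precision package is available; only add/sub/mul by small are
# required by the counting recurrence.

BIGBASE <- 1e4

big_norm <- function(v) {
  carry <- 0
  for (i in seq_along(v)) {
    x <- v[i] + carry
    v[i] <- x %% BIGBASE
    carry <- (x - v[i]) / BIGBASE
  }
  while (carry > 0) {
    d <- carry %% BIGBASE
    v <- c(v, d)
    carry <- (carry - d) / BIGBASE
  }
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}

big_from_num <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  if (x == 0) return(0)
  v <- numeric(0)
  while (x > 0) {
    d <- x %% BIGBASE
    v <- c(v, d)
    x <- (x - d) / BIGBASE
  }
  v
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_cmp <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  for (i in rev(seq_len(n))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}

# a - b, requiring a >= b
big_sub <- function(a, b) {
  stopifnot(big_cmp(a, b) >= 0)
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  borrow <- 0
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- a[i] - b[i] - borrow
    borrow <- if (x < 0) 1 else 0
    out[i] <- x + borrow * BIGBASE
  }
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

# multiply by a double-precision integer s with s * BIGBASE < 2^53
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == floor(s), s * BIGBASE < 2^53)
  if (s == 0) return(0)
  big_norm(a * s)
}

big_mul <- function(a, b) {
  # schoolbook convolution; accumulated digits stay far below 2^53
  out <- numeric(length(a) + length(b) + 1L)
  idx0 <- seq_along(a)
  for (i in seq_along(b)) {
    if (b[i] == 0) next
    out[idx0 + i - 1L] <- out[idx0 + i - 1L] + a * b[i]
  }
  big_norm(out)
}

big_pow2 <- function(e) {
  stopifnot(e >= 0)
  out <- big_from_num(1)
  x <- big_from_num(2)
  while (e > 0) {
    if (e %% 2 == 1) out <- big_mul(out, x)
    x <- big_mul(x, x)
    e <- e %/% 2
  }
  out
}

big_to_string <- function(v) {
  hi <- format(v[length(v)], scientific = FALSE, trim = TRUE)
  lo <- if (length(v) > 1L) {
    sprintf("%04d", rev(v[-length(v)]))
  } else character(0)
  paste0(hi, paste(lo, collapse = ""))
}

# --- DAG counting ----------------------------------------------------------

#' Count labelled DAGs on n nodes exactly
#'
#' Uses the classical alternating recurrence
#' \deqn{a(n) = \sum_{k=1}^n (-1)^{k+1} \binom{n}{k} 2^{k(n-k)} a(n-k)}
#' with \eqn{a(0)=1}, in exact integer arithmetic. The super-exponential
#' growth of this count (about \eqn{4.18 \times 10^{18}} already at
#' \eqn{n = 10}) is why structure learning must search or sample rather
#' than enumerate.
#'
#' @param n number of labelled nodes (0 to ~25).
#' @return exact count as a decimal string (convert with `as.numeric()`
#'   when an approximation suffices).
#' @export
count_dags <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != floor(n) || n < 0) {
    stop("n must be a non-negative integer", call. = FALSE)
  }
  n <- as.integer(n)
  a <- vector("list", n + 1L)
  a[[1L]] <- big_from_num(1)
  if (n >= 1L) {
    for (m in 1:n) {
      pos <- big_from_num(0)
      neg <- big_from_num(0)
      for (k in 1:m) {
        term <- big_mul(big_pow2(k * (m - k)), a[[m - k + 1L]])
        term <- big_mul(term, big_from_num(choose(m, k)))
        if (k %% 2 == 1) pos <- big_add(pos, term) else neg <- big_add(neg, term)
      }
      a[[m + 1L]] <- big_sub(pos, neg)
    }
  }
  big_to_string(a[[n + 1L]])
}

# --- exhaustive posterior enumeration --------------------------------------

#' Exact structure posterior by exhaustive enumeration
#'
#' Enumerates every DAG on the dataset's factors that the edge constraint
#' allows, scores each with [dag_log_score()], and normalises. Intended as
#' an oracle for validating the MCMC sampler on small problems; guarded to
#' at most 5 nodes.
#'
#' @param dataset complete-case dataset whose factor columns are the nodes.
#' @param specs factor specs (defaults to the dataset attribute).
#' @param constraint an [edge_constraint()].
#' @param ess equivalent sample size.
#' @param nodes node columns (default: all factor columns of the dataset).
#' @return list with `nodes`, `log_score` and `prob` per allowed acyclic
#'   graph, `edge_prob` (matrix of exact posterior edge probabilities),
#'   and `dag_at(i)` to materialise the i-th graph as a [dag()].
#' @export
enumerate_dag_posterior <- function(dataset, specs = attr(dataset, "specs"),
                                    constraint = edge_constraint(),
                                    ess = 1, nodes = NULL) {
  specs <- as_spec_list(specs)
  df <- as.data.frame(dataset)
  if (is.null(nodes)) nodes <- intersect(names(df), names(specs))
  n <- length(nodes)
  if (n > 5L) {
    stop("exhaustive enumeration is guarded to <= 5 nodes (got ", n, ")",
         call. = FALSE)
  }
  enc <- encode_dataset(dataset, specs, columns = nodes)
  cands <- candidate_parent_sets(nodes, constraint)
  reqs <- required_parent_sets(nodes, constraint)
  tables <- build_score_tables(enc, nodes, cands, constraint$max_parents,
                               ess, reqs)
  # per node, per parent set: global bitmask over `nodes`
  gmask <- lapply(tables, function(tb) {
    vapply(seq_along(tb$mask), function(i) {
      p <- mask_to_parents(tb$cand, tb$mask[i])
      local_mask(nodes, p) # nodes as the "candidate" ordering = global mask
    }, integer(1))
  })
  combos <- as.matrix(expand.grid(lapply(tables, function(tb)
    seq_along(tb$mask)), KEEP.OUT.ATTRS = FALSE))
  colnames(combos) <- nodes
  M <- matrix(0L, nrow(combos), n)
  for (j in seq_len(n)) M[, j] <- gmask[[j]][combos[, j]]
  # parallel Kahn peeling, vectorised across all graphs
  rem <- rep(as.integer(2^n - 1), nrow(combos))
  for (round in seq_len(n)) {
    removable <- rep(0L, nrow(combos))
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      free <- bitwAnd(rem, bit) != 0L & bitwAnd(M[, j], rem) == 0L
      removable[free] <- bitwOr(removable[free], bit)
    }
    rem <- bitwAnd(rem, bitwNot(removable))
  }
  acyclic <- rem == 0L
  combos <- combos[acyclic, , drop = FALSE]
  M <- M[acyclic, , drop = FALSE]
  ls <- rep(0, nrow(combos))
  for (j in seq_len(n)) ls <- ls + tables[[j]]$score[combos[, j]]
  prob <- exp(ls - logsumexp(ls))
  prob <- prob / sum(prob)
  edge_prob <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (u in seq_len(n)) {
    bit <- bitwShiftL(1L, u - 1L)
    for (v in seq_len(n)) {
      if (u == v) next
      edge_prob[u, v] <- sum(prob[bitwAnd(M[, v], bit) != 0L])
    }
  }
  dag_at <- function(i) {
    parents <- lapply(seq_len(n), function(j)
      mask_to_parents(tables[[j]]$cand, tables[[j]]$mask[combos[i, j]]))
    names(parents) <- nodes
    dag(nodes, parents)
  }
  list(nodes = nodes, log_score = ls, prob = prob,
       edge_prob = edge_prob, dag_at = dag_at, n_dags = nrow(combos))
}

# candidate parents per child under a constraint (blacklist applied)
candidate_parent_sets <- function(nodes, constraint, allowed = NULL) {
  stats::setNames(lapply(nodes, function(v) {
    cand <- setdiff(if (is.null(allowed)) nodes else allowed[[v]], v)
    f <- constraint$forbidden
    if (nrow(f)) cand <- setdiff(cand, f[f[, 2] == v, 1])
    cand
  }), nodes)
}

required_parent_sets <- function(nodes, constraint) {
  r <- constraint$required
  if (!nrow(r)) return(list())
  split(r[, "from"], factor(r[, "to"], levels = nodes))[
    intersect(unique(r[, "to"]), nodes)]
}
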