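#' BDeu marginal-likelihood score of one node family
#'
#' Computes the log Bayesian-Dirichlet equivalent uniform (BDeu) marginal
#' likelihood contribution of a child node given a candidate parent set:
#' \deqn{\log \prod_j \frac{\Gamma(\alpha_j)}{\Gamma(\alpha_j + n_j)}
#'   \prod_k \frac{\Gamma(\alpha_{jk} + n_{jk})}{\Gamma(\alpha_{jk})}}
#' over parent configurations \eqn{j} and child states \eqn{k}, with
#' \eqn{\alpha_j = \mathrm{ess}/q} and \eqn{\alpha_{jk} = \mathrm{ess}/(qr)}
#' for \eqn{q} parent configurations and \eqn{r} child states. BDeu is
#' decomposable and score-equivalent: Markov-equivalent DAGs receive the
#' same total score, which the CPDAG summaries downstream presuppose.
#'
#' @param node child column name.
#' @param parent_set character vector of parent column names (possibly empty).
#' @param dataset complete-case dataset (an `initial_dataset`,
#'   `transition_dataset`, or plain data.frame of level labels).
#' @param ess equivalent sample size (> 0), default 1.
#' @param specs factor specs (defaults to the dataset attribute).
#' @return log marginal likelihood (finite).
#' @export
bdeu_family_score <- function(node, parent_set, dataset, ess = 1,
                              specs = attr(dataset, "specs")) {
  if (!is.numeric(ess) || length(ess) != 1L || !is.finite(ess) || ess <= 0) {
    stop("ess must be a positive number", call. = FALSE)
  }
  cols <- c(node, parent_set)
  df <- as.data.frame(dataset)
  unknown <- setdiff(cols, names(df))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  enc <- encode_dataset(dataset, specs, columns = cols)
  nlev <- attr(enc, "nlev")
  bdeu_from_encoded(enc[, 1L], nlev[[1L]],
                    enc[, -1L, drop = FALSE], nlev[-1L], ess)
}

# child: integer vector (1..r); parents: integer matrix with per-column
# cardinalities pr
bdeu_from_encoded <- function(child, r, parents, pr, ess) {
  q <- if (length(pr)) prod(pr) else 1
  n <- length(child)
  if (n == 0L) return(0)
  idx <- integer(n) # 0-based parent configuration index
  if (length(pr)) {
    for (j in seq_along(pr)) idx <- idx * pr[j] + (parents[, j] - 1L)
  }
  joint <- idx * r + (child - 1L) + 1L
  counts <- tabulate(joint, nbins = q * r)
  njk <- matrix(counts, nrow = r) # [k, j]
  nj <- colSums(njk)
  aj <- ess / q
  ajk <- ess / (q * r)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + njk) - lgamma(ajk))
}

#' Log posterior score of a whole DAG
#'
#' Sum of BDeu family scores plus the log structure prior. The prior is
#' uniform over DAGs satisfying the edge constraint (so constant, taken as
#' 0) and zero outside its support: a DAG containing a forbidden edge,
#' missing a required edge, or exceeding the parent cap scores `-Inf`.
#'
#' @param g a [dag()] whose nodes are dataset columns.
#' @param dataset complete-case dataset.
#' @param ess equivalent sample size.
#' @param constraint an [edge_constraint()] (default: unconstrained).
#' @param specs factor specs (defaults to the dataset attribute).
#' @return log score; `-Inf` outside the prior's support.
#' @export
dag_log_score <- function(g, dataset, ess = 1,
                          constraint = edge_constraint(max_parents = length(g$nodes)),
                          specs = attr(dataset, "specs")) {
  if (!dag_respects_constraint(g, constraint)) return(-Inf)
  sum(vapply(g$nodes, function(v)
    bdeu_family_score(v, g$parents[[v]], dataset, ess, specs), numeric(1)))
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Per-child table of BDeu scores for every allowed parent set.
#
# enc: encoded matrix for all columns; children: column names to score;
# candidates: named list child -> character vector of candidate parents
# (already excluding forbidden ones); required: named list child ->
# parents every set must contain. Masks are bitmasks over the child's
# candidate ordering (<= 30 candidates).
build_score_tables <- function(enc, children, candidates, max_parents, ess,
                               required = list()) {
  nlev <- attr(enc, "nlev")
  lapply(stats::setNames(children, children), function(v) {
    cand <- candidates[[v]]
    if (length(cand) > 31L) {
      # parent-set bitmasks live in 32-bit integers (bits 0..30 plus the
      # value 2^30 for position 31 stay below .Machine$integer.max)
      stop("node '", v, "': more than 31 candidate parents", call. = FALSE)
    }
    req <- intersect(required[[v]] %||% character(0), cand)
    free <- setdiff(cand, req)
    req_pos <- match(req, cand)
    free_pos <- match(free, cand)
    kmax <- max_parents - length(req)
    if (kmax < 0L) {
      stop("node '", v, "': required parents exceed max_parents",
           call. = FALSE)
    }
    sets <- list()
    for (k in 0:min(kmax, length(free))) {
      sets <- c(sets, if (k == 0L) {
        list(integer(0))
      } else if (length(free_pos) == 1L) {
        list(free_pos) # combn(x, k) would misread a scalar x as 1:x
      } else {
        utils::combn(free_pos, k, simplify = FALSE)
      })
    }
    sets <- lapply(sets, function(s) sort(c(req_pos, s)))
    child <- enc[, v]
    r <- nlev[[v]]
    mask <- vapply(sets, function(s)
      as.integer(sum(bitwShiftL(1L, s - 1L))), integer(1))
    score <- vapply(sets, function(s) {
      p <- cand[s]
      bdeu_from_encoded(child, r, enc[, p, drop = FALSE], nlev[p], ess)
    }, numeric(1))
    list(node = v, cand = cand, mask = mask,
         size = lengths(sets), score = score,
         has_empty = length(req) == 0L)
  })
}

# local bitmask of a node set restricted to a child's candidates
local_mask <- function(cand, nodes) {
  pos <- match(intersect(nodes, cand), cand)
  if (!length(pos)) return(0L)
  as.integer(sum(bitwShiftL(1L, pos - 1L)))
}

mask_to_parents <- function(cand, mask) {
  if (mask == 0L) return(character(0))
  cand[bitwAnd(bitwShiftR(mask, seq_along(cand) - 1L), 1L) == 1L]
}
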