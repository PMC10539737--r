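#' Construct a directed acyclic graph over named nodes
#'
#' @param nodes character vector of node names (order fixes matrix layouts).
#' @param parents named list mapping node -> character vector of parents;
#'   nodes absent from the list have no parents.
#' @return object of class `bn_dag`.
#' @export
dag <- function(nodes, parents = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  ps <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (v in names(parents)) {
    if (!v %in% nodes) stop("unknown node '", v, "'", call. = FALSE)
    p <- unique(as.character(parents[[v]]))
    if (!all(p %in% nodes)) {
      stop("unknown parent of '", v, "': ",
           paste(setdiff(p, nodes), collapse = ", "), call. = FALSE)
    }
    if (v %in% p) stop("self-loop at '", v, "'", call. = FALSE)
    ps[[v]] <- p
  }
  g <- structure(list(nodes = nodes, parents = ps), class = "bn_dag")
  if (!dag_is_acyclic(g)) stop("graph has a directed cycle", call. = FALSE)
  g
}

dag_is_acyclic <- function(g) {
  # Kahn peeling on the parent lists; avoids building an igraph per check
  remaining <- g$nodes
  ps <- g$parents
  repeat {
    free <- remaining[vapply(ps[remaining], function(p)
      !any(p %in% remaining), logical(1))]
    if (!length(free)) break
    remaining <- setdiff(remaining, free)
  }
  length(remaining) == 0L
}

#' Edges of a DAG as a two-column matrix
#' @param g a [dag()].
#' @return character matrix with columns `from`, `to` (0 rows if empty).
#' @export
dag_edges <- function(g) {
  from <- unlist(g$parents, use.names = FALSE)
  to <- rep(names(g$parents), lengths(g$parents))
  cbind(from = as.character(from), to = as.character(to))
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e)) cat(paste0("  ", e[, 1], " -> ", e[, 2], collapse = "\n"), "\n")
  invisible(x)
}

# adjacency matrix (1 = row -> col edge)
dag_amat <- function(g) {
  n <- length(g$nodes)
  a <- matrix(0L, n, n, dimnames = list(g$nodes, g$nodes))
  e <- dag_edges(g)
  if (nrow(e)) a[e] <- 1L
  a
}

amat_to_dag <- function(a) {
  nodes <- rownames(a)
  parents <- lapply(seq_along(nodes), function(j) nodes[a[, j] == 1L])
  names(parents) <- nodes
  dag(nodes, parents)
}

dag_topo_order <- function(g) {
  ordered <- character(0)
  remaining <- g$nodes
  while (length(remaining)) {
    free <- remaining[vapply(g$parents[remaining], function(p)
      !any(p %in% remaining), logical(1))]
    if (!length(free)) stop("cycle detected", call. = FALSE)
    ordered <- c(ordered, free)
    remaining <- setdiff(remaining, free)
  }
  ordered
}

# canonical single-line serialisation, stable under node reordering
dag_key <- function(g) {
  nodes <- sort(g$nodes)
  paste(vapply(nodes, function(v)
    paste0(v, "<", paste(sort(g$parents[[v]]), collapse = ",")),
    character(1)), collapse = ";")
}

#' Convert a DAG to an igraph object
#' @param g a [dag()].
#' @return an `igraph` directed graph.
#' @export
dag_to_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(dag_amat(g), mode = "directed")
}

#' Edge constraints for structure learning
#'
#' Encodes the structure prior's support: prior knowledge removes
#' unrealistic edges via a blacklist, optionally forces edges via a
#' whitelist, and caps the number of parents per node.
#'
#' @param forbidden two-column matrix / data.frame of (from, to) pairs that
#'   may never appear.
#' @param required two-column matrix of (from, to) pairs that must appear
#'   (default none); must be jointly acyclic and disjoint from `forbidden`.
#' @param max_parents cap on parent-set size per node (default 4).
#' @return object of class `edge_constraint`.
#' @export
edge_constraint <- function(forbidden = NULL, required = NULL,
                            max_parents = 4L) {
  norm <- function(x) {
    if (is.null(x) || (is.data.frame(x) && !nrow(x))) {
      return(matrix(character(0), 0, 2,
                    dimnames = list(NULL, c("from", "to"))))
    }
    m <- as.matrix(x)
    stopifnot(ncol(m) == 2)
    colnames(m) <- c("from", "to")
    unique(m)
  }
  forbidden <- norm(forbidden)
  required <- norm(required)
  if (nrow(forbidden) && nrow(required)) {
    fk <- paste(forbidden[, 1], forbidden[, 2], sep = "\r")
    rk <- paste(required[, 1], required[, 2], sep = "\r")
    if (length(intersect(fk, rk))) {
      stop("an edge cannot be both forbidden and required", call. = FALSE)
    }
  }
  if (nrow(required)) {
    nodes <- unique(c(required))
    dag(nodes, split(required[, "from"], required[, "to"])) # acyclicity check
  }
  max_parents <- as.integer(max_parents)
  stopifnot(max_parents >= 1L)
  structure(list(forbidden = forbidden, required = required,
                 max_parents = max_parents),
            class = "edge_constraint")
}

#' Read an edge-constraint YAML file
#'
#' Layout: `forbidden: [[from,to], ...]`, `required: [...]`,
#' `max_parents: k`, optional `ess: x` (returned as an attribute).
#'
#' @param path YAML file path.
#' @return an [edge_constraint()]; attribute `ess` if the file sets one.
#' @export
read_edge_constraint <- function(path) {
  raw <- yaml::read_yaml(path)
  pairs <- function(x) {
    if (is.null(x) || !length(x)) return(NULL)
    do.call(rbind, lapply(x, function(p) c(p[[1]], p[[2]])))
  }
  ec <- edge_constraint(pairs(raw$forbidden), pairs(raw$required),
                        raw$max_parents %||% 4L)
  if (!is.null(raw$ess)) attr(ec, "ess") <- as.numeric(raw$ess)
  ec
}

constraint_forbids <- function(constraint, from, to) {
  f <- constraint$forbidden
  nrow(f) > 0L && any(f[, 1] == from & f[, 2] == to)
}

# does the DAG satisfy the constraint's support?
dag_respects_constraint <- function(g, constraint) {
  e <- dag_edges(g)
  key <- paste(e[, 1], e[, 2], sep = "\r")
  f <- constraint$forbidden
  if (nrow(f) && any(paste(f[, 1], f[, 2], sep = "\r") %in% key)) return(FALSE)
  r <- constraint$required
  if (nrow(r)) {
    rk <- paste(r[, 1], r[, 2], sep = "\r")
    if (!all(rk %in% key)) return(FALSE)
  }
  all(lengths(g$parents) <= constraint$max_parents)
}

# hash for reproducibility metadata
constraint_key <- function(constraint) {
  paste0("f:", paste(constraint$forbidden[, 1], constraint$forbidden[, 2],
                     sep = ">", collapse = "|"),
         ";r:", paste(constraint$required[, 1], constraint$required[, 2],
                      sep = ">", collapse = "|"),
         ";mp:", constraint$max_parents)
}
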