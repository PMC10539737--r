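# CPDAG machinery: a Markov equivalence class is summarised by its
# completed partially directed acyclic graph, in which compelled edges
# (same orientation in every member of the class) stay directed and
# reversible edges become undirected. Conversion here starts from the
# DAG's skeleton and v-structures, adds any background orientations
# (for two-slice graphs the temporal blacklist compels every cross-slice
# edge), and closes under the Meek orientation-propagation rules.

new_cpdag <- function(nodes, amat) {
  structure(list(nodes = nodes, amat = amat), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  d <- cpdag_directed(x)
  u <- cpdag_undirected(x)
  cat(sprintf("<cpdag> %d nodes, %d compelled, %d reversible\n",
              length(x$nodes), nrow(d), nrow(u)))
  invisible(x)
}

#' Compelled (directed) edges of a CPDAG
#' @param x a `cpdag`.
#' @return two-column character matrix (from, to).
#' @export
cpdag_directed <- function(x) {
  a <- x$amat
  idx <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  cbind(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]])
}

#' Reversible (undirected) edges of a CPDAG
#' @param x a `cpdag`.
#' @return two-column character matrix, one row per unordered pair.
#' @export
cpdag_undirected <- function(x) {
  a <- x$amat
  idx <- which(a == 1L & t(a) == 1L, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  cbind(from = x$nodes[idx[, 1]], to = x$nodes[idx[, 2]])
}

# canonical serialisation (sorted edge lists) for MAP counting / tie-breaks
cpdag_key <- function(x) {
  d <- cpdag_directed(x)
  u <- cpdag_undirected(x)
  dk <- if (nrow(d)) sort(paste(d[, 1], d[, 2], sep = ">")) else character(0)
  uk <- if (nrow(u)) {
    sort(apply(u, 1, function(e) paste(sort(e), collapse = "~")))
  } else character(0)
  paste(c(dk, uk), collapse = ";")
}

# Meek closure on a partially directed adjacency matrix.
# a[i,j] = 1 & a[j,i] = 0: directed i->j; both 1: undirected.
meek_closure <- function(a) {
  n <- nrow(a)
  adj <- function(i, j) a[i, j] == 1L || a[j, i] == 1L
  repeat {
    changed <- FALSE
    dir <- a == 1L & t(a) == 0L
    und <- a == 1L & t(a) == 1L
    for (b in seq_len(n)) {
      for (cc in seq_len(n)) {
        if (!und[b, cc]) next
        oriented <- FALSE
        # R1: a -> b, b - c, a and c nonadjacent  =>  b -> c
        for (aa in which(dir[, b])) {
          if (!adj(aa, cc)) { oriented <- TRUE; break }
        }
        # R2: b -> x -> c with b - c  =>  b -> c
        if (!oriented && any(dir[b, ] & dir[, cc])) oriented <- TRUE
        # R3: b - c with b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 nonadjacent
        if (!oriented) {
          ds <- which(und[b, ] & dir[, cc])
          if (length(ds) >= 2L) {
            for (i in seq_along(ds)) {
              for (j in seq_len(i - 1L)) {
                if (!adj(ds[i], ds[j])) { oriented <- TRUE; break }
              }
              if (oriented) break
            }
          }
        }
        # R4: b - c with b - d, d -> e, e -> c, and c,d nonadjacent => b -> c
        if (!oriented) {
          for (dd in which(und[b, ])) {
            if (dd == cc || adj(dd, cc)) next
            if (any(dir[dd, ] & dir[, cc])) { oriented <- TRUE; break }
          }
        }
        if (oriented) {
          a[cc, b] <- 0L
          changed <- TRUE
          dir <- a == 1L & t(a) == 0L
          und <- a == 1L & t(a) == 1L
        }
      }
    }
    if (!changed) break
  }
  a
}

#' Convert a DAG to its completed partially directed acyclic graph
#'
#' Keeps an edge directed iff it has the same orientation in every member
#' of the DAG's Markov equivalence class: the skeleton and v-structures
#' are retained, optional background orientations are imposed, and the
#' Meek rules are applied to a fixpoint; edges left unoriented become
#' undirected.
#'
#' @param g a [dag()] (or a named parent-set list plus `nodes`).
#' @param nodes node ordering when `g` is a bare parent list.
#' @param background optional two-column (from, to) matrix of edge
#'   orientations compelled by prior knowledge, e.g. the temporal
#'   direction of cross-slice edges in a transition network.
#' @return a `cpdag`.
#' @export
dag_to_cpdag <- function(g, nodes = NULL, background = NULL) {
  if (inherits(g, "bn_dag")) {
    nodes <- g$nodes
    parents <- g$parents
  } else {
    stopifnot(!is.null(nodes))
    parents <- g
  }
  n <- length(nodes)
  d <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (v in names(parents)) {
    p <- parents[[v]]
    if (length(p)) d[cbind(match(p, nodes), match(v, nodes))] <- 1L
  }
  a <- d | t(d) # skeleton, all edges undirected
  mode(a) <- "integer"
  # v-structures: nonadjacent co-parents keep their edges directed
  for (v in seq_len(n)) {
    ps <- which(d[, v] == 1L)
    if (length(ps) < 2L) next
    for (i in seq_along(ps)) {
      for (j in seq_len(i - 1L)) {
        if (a[ps[i], ps[j]] == 0L && a[ps[j], ps[i]] == 0L) {
          a[v, ps[i]] <- 0L
          a[v, ps[j]] <- 0L
        }
      }
    }
  }
  if (!is.null(background) && nrow(background)) {
    ij <- cbind(match(background[, 1], nodes), match(background[, 2], nodes))
    keep <- !is.na(ij[, 1]) & !is.na(ij[, 2])
    ij <- ij[keep, , drop = FALSE]
    present <- d[ij] == 1L
    a[ij[present, 2:1, drop = FALSE]] <- 0L
  }
  new_cpdag(nodes, meek_closure(a))
}

# cross-slice orientations for a two-slice draw
slice_background <- function(parents, slices) {
  out <- NULL
  for (v in intersect(names(parents), slices$t1)) {
    p <- intersect(parents[[v]], slices$t)
    if (length(p)) out <- rbind(out, cbind(p, v))
  }
  out
}

# convert every draw of a posterior sample, deduplicating identical DAGs
sample_cpdags <- function(sample) {
  stopifnot(inherits(sample, "dbn_posterior"))
  keys <- vapply(sample$dags, function(d)
    paste(vapply(sample$nodes, function(v)
      paste(sort(d[[v]]), collapse = ","), character(1)), collapse = ";"),
    character(1))
  counts <- table(keys)
  first <- !duplicated(keys)
  slices <- sample$meta$slices
  cp <- lapply(which(first), function(i) {
    bg <- if (!is.null(slices)) slice_background(sample$dags[[i]], slices)
    dag_to_cpdag(sample$dags[[i]], nodes = sample$nodes, background = bg)
  })
  list(cpdags = cp, weight = as.numeric(counts[keys[first]]),
       n = length(sample$dags))
}

#' Directional edge probabilities over the CPDAG-converted sample
#'
#' Each sampled DAG is converted to its CPDAG, then for an ordered pair
#' (u, v) the probability is the fraction of converted samples in which
#' u -> v is compelled plus the fraction in which u - v is reversible:
#' a reversible edge supports both directions at full weight, so the two
#' directional probabilities of a pair can sum to more than 1.
#'
#' @param sample a `dbn_posterior`.
#' @return matrix indexed `[from, to]` with values in `[0, 1]`.
#' @export
summarize_directional_probabilities <- function(sample) {
  sc <- sample_cpdags(sample)
  nodes <- sample$nodes
  n <- length(nodes)
  acc <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(sc$cpdags)) {
    a <- sc$cpdags[[i]]$amat
    acc <- acc + sc$weight[i] * a
  }
  acc / sc$n
}

#' Posterior summary graph around the MAP CPDAG
#'
#' The maximum a posteriori (MAP) summary is the modal CPDAG among the
#' converted posterior draws. Edges whose directional probability exceeds
#' the threshold are exported, solid when present in the MAP CPDAG and
#' dashed otherwise, with a transparency attribute proportional to the
#' probability (mirroring the usual presentation of sampled network
#' structures).
#'
#' @param sample a `dbn_posterior`.
#' @param threshold minimum directional edge probability to keep
#'   (default 0.1); must be in `[0, 1)`.
#' @return list of class `summary_graph`: `map` (the modal `cpdag`),
#'   `map_probability`, and `edges` (data.frame with `from`, `to`,
#'   `probability`, `in_map`, `style`, `transparency`).
#' @export
map_summary_graph <- function(sample, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold < 1)
  sc <- sample_cpdags(sample)
  keys <- vapply(sc$cpdags, cpdag_key, character(1))
  w <- tapply(sc$weight, keys, sum)
  best <- names(w)[w == max(w)]
  if (length(best) > 1L) {
    warning("tie for the modal CPDAG; using the lexicographically smallest",
            call. = FALSE)
    best <- sort(best)[1L]
  }
  map <- sc$cpdags[[match(best, keys)]]
  prob <- summarize_directional_probabilities(sample)
  amap <- map$amat
  idx <- which(prob > threshold & row(prob) != col(prob), arr.ind = TRUE)
  edges <- data.frame(
    from = sample$nodes[idx[, 1]],
    to = sample$nodes[idx[, 2]],
    probability = prob[idx],
    in_map = amap[idx] == 1L,
    stringsAsFactors = FALSE
  )
  edges$style <- ifelse(edges$in_map, "solid", "dashed")
  edges$transparency <- edges$probability
  edges <- edges[order(-edges$probability, edges$from, edges$to), ]
  rownames(edges) <- NULL
  structure(list(map = map, map_probability = unname(max(w) / sc$n),
                 edges = edges, threshold = threshold,
                 nodes = sample$nodes),
            class = "summary_graph")
}

#' @export
print.summary_graph <- function(x, ...) {
  cat(sprintf(
    "<summary_graph> MAP CPDAG (posterior prob %.3f), %d edges > %.2f\n",
    x$map_probability, nrow(x$edges), x$threshold))
  invisible(x)
}

node_domain_groups <- function(nodes, specs) {
  specs <- as_spec_list(specs)
  vapply(nodes, function(v) {
    f <- sub("@t1?$", "", v)
    if (f %in% names(specs)) specs[[f]]$domain_group else "demographic"
  }, character(1))
}

#' Export a summary graph to Graphviz DOT
#'
#' Nodes carry their clinical domain group as a fill-colour key; edges
#' carry `probability` and solid/dashed style.
#'
#' @param summary a [map_summary_graph()] result.
#' @param path output `.dot` file.
#' @param specs factor specs used for domain colours.
#' @return `path`, invisibly.
#' @export
write_summary_dot <- function(summary, path, specs) {
  groups <- node_domain_groups(summary$nodes, specs)
  palette <- c("function" = "palegreen", suicidality = "lightblue",
               substance = "gold", physical = "grey80",
               syndrome = "orange", demographic = "white")
  lines <- c("digraph summary {")
  for (v in summary$nodes) {
    lines <- c(lines, sprintf(
      "  \"%s\" [style=filled, fillcolor=\"%s\", domain_group=\"%s\"];",
      v, palette[[groups[[v]]]], groups[[v]]))
  }
  e <- summary$edges
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [style=%s, probability=%.4f];",
      e$from[i], e$to[i], e$style[i], e$probability[i]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Export a summary graph to GraphML
#'
#' @inheritParams write_summary_dot
#' @param path output `.graphml` file.
#' @return `path`, invisibly.
#' @export
write_summary_graphml <- function(summary, path, specs) {
  e <- summary$edges
  g <- igraph::graph_from_data_frame(
    e[, c("from", "to", "probability", "style")],
    directed = TRUE,
    vertices = data.frame(name = summary$nodes,
                          domain_group = node_domain_groups(summary$nodes,
                                                            specs)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
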