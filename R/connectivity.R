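#' Minimum spanning tree of a distance matrix
#'
#' Kruskal's greedy algorithm over a deterministic edge ordering: candidate
#' edges are sorted by (distance, first node name, second node name) before
#' selection, so exact ties are broken lexicographically and the selected
#' tree is identical across runs and platforms.
#'
#' @param d Symmetric numeric matrix with zero diagonal and finite entries,
#'   at least 2 x 2.  Row/column names identify the nodes.
#' @return `data.frame` with columns `node_a`, `node_b` (with
#'   `node_a < node_b` lexicographically) and `distance`; `N - 1` rows.
#' @export
minimum_spanning_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("minimum spanning tree is undefined for fewer than 2 nodes",
                  call. = FALSE)
  if (ncol(d) != n) stop("distance matrix must be square", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  if (max(abs(d - t(d))) > 1e-9) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  nodes <- rownames(d)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(n))

  idx <- which(upper.tri(d), arr.ind = TRUE)
  a <- nodes[idx[, 1]]
  b <- nodes[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  edges <- data.frame(node_a = a, node_b = b, distance = d[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$distance, edges$node_a, edges$node_b,
                       method = "radix"), ]

  # union-find with path halving
  parent <- seq_len(n)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  ia <- match(edges$node_a, nodes)
  ib <- match(edges$node_b, nodes)
  for (k in seq_len(nrow(edges))) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the semantic connectivity map
#'
#' Filters the trained AutoCM's distance matrix with a minimum spanning
#' tree and annotates each surviving edge with its link strength: the
#' resulting acyclic, connected graph keeps, for every variable, only its
#' strongest association routes.  High-degree nodes ("hubs") organize the
#' association scheme.
#'
#' @param model A trained `autocm` model, or a distance matrix (in which
#'   case `ls` must be supplied).
#' @param ls Optional link-strength matrix aligned with `model` when the
#'   latter is a plain distance matrix.
#' @param polarity Optional named character vector tagging each node
#'   `high`/`low`/`indicator`; inferred from variable names
#'   (`"high "`/`"low "` prefixes) when missing.
#' @return A `connectivity_map`: list with `nodes` (data.frame of `name`,
#'   `polarity`, `degree`), and `edges` (data.frame of `node_a`, `node_b`,
#'   `ls`, `distance`, sorted by descending `ls`, ties lexicographic).
#' @export
connectivity_map <- function(model, ls = NULL, polarity = NULL) {
  if (inherits(model, "autocm")) {
    d <- autocm_distances(model)
    ls <- link_strengths(model)
  } else {
    d <- as.matrix(model)
    if (is.null(ls)) stop("supply a link-strength matrix when not passing ",
                          "a trained model", call. = FALSE)
    ls <- as.matrix(ls)
  }
  if (any(ls < -1e-12) || any(ls > 1 + 1e-12)) {
    stop("link strengths must lie in [0, 1]", call. = FALSE)
  }
  tree <- minimum_spanning_tree(d)
  nodes <- rownames(d)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(d)))

  if (is.null(polarity)) {
    polarity <- ifelse(startsWith(nodes, "high "), "high",
                       ifelse(startsWith(nodes, "low "), "low", "indicator"))
    names(polarity) <- nodes
  }
  tree$ls <- ls[cbind(match(tree$node_a, nodes), match(tree$node_b, nodes))]
  tree <- tree[order(-tree$ls, tree$node_a, tree$node_b, method = "radix"),
               c("node_a", "node_b", "ls", "distance")]
  rownames(tree) <- NULL

  degree <- table(factor(c(tree$node_a, tree$node_b), levels = nodes))
  node_df <- data.frame(name = nodes,
                        polarity = unname(polarity[nodes]),
                        degree = as.integer(degree),
                        stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = tree), class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("Semantic connectivity map:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  hubs <- x$nodes[order(-x$nodes$degree), ][1:min(3, nrow(x$nodes)), ]
  cat("  top hubs:",
      paste0(hubs$name, " (", hubs$degree, ")", collapse = ", "), "\n")
  cat("  strongest edge:", x$edges$node_a[1], "--", x$edges$node_b[1],
      "(ls", signif(x$edges$ls[1], 3), ")\n")
  invisible(x)
}

#' Hub scores of a connectivity map
#'
#' Node degree within the spanning tree.  By the handshake lemma degrees
#' sum to `2 (N - 1)`; nodes of high degree act as organizing hubs of the
#' association scheme.
#'
#' @param map A `connectivity_map`.
#' @return `data.frame` with `name` and `degree`, sorted by decreasing
#'   degree (ties lexicographic).
#' @export
hub_scores <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  out <- map$nodes[order(-map$nodes$degree, map$nodes$name, method = "radix"),
                   c("name", "degree")]
  rownames(out) <- NULL
  out
}

#' Graph distances within a connectivity map
#'
#' Unweighted shortest-path (hop) distances between all node pairs of the
#' tree; used to express statements like "marker X sits within two steps
#' of phenotype Y".
#'
#' @param map A `connectivity_map`.
#' @return Symmetric integer-valued matrix of hop counts.
#' @export
map_graph_distances <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  nodes <- map$nodes$name
  n <- length(nodes)
  adj <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(adj) <- 0
  ia <- match(map$edges$node_a, nodes)
  ib <- match(map$edges$node_b, nodes)
  adj[cbind(ia, ib)] <- 1
  adj[cbind(ib, ia)] <- 1
  # BFS from each node; the map is a tree so this is cheap
  out <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] == 1))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0) {
      i <- queue[1]; queue <- queue[-1]
      for (j in nbrs[[i]]) {
        if (!is.finite(dist[j])) {
          dist[j] <- dist[i] + 1
          queue <- c(queue, j)
        }
      }
    }
    out[s, ] <- dist
  }
  out
}
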