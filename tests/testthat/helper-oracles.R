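# Independent oracles and fixture builders shared across the suite.

# Scalar-recursion AutoCM trainer: same learning rule as the package, but
# written as plain elementwise loops with no vectorization, so it serves as
# an independent check of the matrix implementation.
oracle_train <- function(X, C = ncol(X), eps = 0.01, tol = 1e-6,
                         max_epochs = 10000) {
  N <- ncol(X)
  v <- rep(eps, N)
  w <- matrix(eps, N, N)
  for (ep in seq_len(max_epochs)) {
    w0 <- w
    for (r in seq_len(nrow(X))) {
      ms <- X[r, ]
      mh <- numeric(N)
      for (i in seq_len(N)) mh[i] <- ms[i] * (1 - v[i] / C)
      mt <- numeric(N)
      for (i in seq_len(N)) {
        net <- 0
        for (j in seq_len(N)) net <- net + w[i, j] * mh[j] / C
        mt[i] <- mh[i] * (1 - net / C)
      }
      for (i in seq_len(N)) v[i] <- v[i] + (ms[i] - mh[i]) * (1 - v[i] / C)
      for (i in seq_len(N)) for (j in seq_len(N)) {
        w[i, j] <- w[i, j] + (mh[i] - mt[i]) * (1 - w[i, j] / C) * mh[j]
      }
    }
    if (mean(abs(w - w0)) < tol) {
      return(list(v = v, w = w, epochs = ep, converged = TRUE))
    }
  }
  list(v = v, w = w, epochs = max_epochs, converged = FALSE)
}

# Decode a Pruefer sequence into the edge list of a labeled tree on
# n = length(seq) + 2 nodes.
prufer_decode <- function(pruefer, n) {
  degree <- rep(1L, n)
  for (x in pruefer) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (x in pruefer) {
    leaf <- which(degree == 1L)[1]
    k <- k + 1L
    edges[k, ] <- c(leaf, x)
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  rest <- which(degree == 1L)
  edges[n - 1, ] <- rest
  edges
}

# Minimum spanning-tree total distance by exhaustive enumeration of all
# n^(n-2) labeled trees (Cayley's formula) via Pruefer sequences.
brute_force_mst_total <- function(d) {
  n <- nrow(d)
  if (n == 2) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (k in seq_len(nrow(seqs))) {
    edges <- prufer_decode(seqs[k, ], n)
    tot <- sum(d[edges])
    if (tot < best) best <- tot
  }
  best
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  dimnames(d) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  d
}

# Uniform-ish scaled data matrix, entries in [0, 1].
random_scaled_matrix <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(runif(n * p), n, p)
  colnames(X) <- paste0("V", seq_len(p))
  X
}

# Small raw marker table over the full study panel.
tiny_marker_table <- function(n_per_group = 3, seed = 1) {
  set.seed(seed)
  groups <- rep(ms_phenotypes(), each = n_per_group)
  vals <- matrix(runif(length(groups) * 11, 0.5, 50), length(groups), 11)
  colnames(vals) <- ms_markers()
  df <- data.frame(subject_id = sprintf("S%02d", seq_along(groups)),
                   phenotype = groups, stringsAsFactors = FALSE,
                   check.names = FALSE)
  cbind(df, as.data.frame(vals, check.names = FALSE))
}

# Fixture for the separation property: one latent-coupled pair (r ~ 0.9)
# among independent noise variables, all means 0.5.
separation_fixture <- function(seed, n = 400, p_noise = 6) {
  set.seed(seed)
  clip01 <- function(z) pmin(pmax(0.5 + z, 0), 1)
  f <- rnorm(n)
  x1 <- clip01(0.2 * f + 0.065 * rnorm(n))
  x2 <- clip01(0.2 * f + 0.065 * rnorm(n))
  rest <- matrix(clip01(0.21 * rnorm(n * p_noise)), n, p_noise)
  X <- cbind(x1, x2, rest)
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  X
}

tree_edges_connected <- function(edges, nodes) {
  sub <- edges[edges$node_a %in% nodes & edges$node_b %in% nodes, ]
  nrow(sub) == length(nodes) - 1
}
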