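# Independent brute-force references used as oracles. Everything here
# works on a plain adjacency matrix (never through igraph's centrality,
# clique, coreness or component code), so package results are checked by
# double-entry.

adj_of <- function(g) {
  ids <- sort(igraph::V(g)$name)
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    A[cbind(el[, 1], el[, 2])] <- 1L
    A[cbind(el[, 2], el[, 1])] <- 1L
  }
  diag(A) <- 0L
  A
}

graph_of <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# BFS distances from one source; Inf where unreachable.
bf_dist_from <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] == 1 & is.infinite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

bf_distances <- function(A) t(vapply(seq_len(nrow(A)), bf_dist_from,
                                     numeric(nrow(A)), A = A))

# Number of shortest paths between every pair (DP over BFS layers).
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  N <- matrix(0, n, n)
  for (u in seq_len(n)) {
    N[u, u] <- 1
    for (dist in seq_len(max(D[u, ][is.finite(D[u, ])]))) {
      for (w in which(D[u, ] == dist)) {
        pred <- which(A[w, ] == 1 & D[u, ] == dist - 1)
        N[u, w] <- sum(N[u, pred])
      }
    }
  }
  N
}

bf_betweenness <- function(A) {
  D <- bf_distances(A)
  N <- bf_path_counts(A, D)
  n <- nrow(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    for (u in seq_len(n - 1)) for (w in (u + 1):n) {
      if (u == v || w == v || !is.finite(D[u, w]) || N[u, w] == 0) next
      if (is.finite(D[u, v]) && is.finite(D[v, w]) &&
          D[u, v] + D[v, w] == D[u, w])
        out[v] <- out[v] + N[u, v] * N[v, w] / N[u, w]
    }
  }
  stats::setNames(out, rownames(A))
}

bf_closeness <- function(A) {
  D <- bf_distances(A)
  out <- vapply(seq_len(nrow(A)), function(v) {
    d <- D[, v]; d <- d[is.finite(d) & d > 0]
    if (!length(d)) 0 else length(d) / sum(d)
  }, 0)
  stats::setNames(out, rownames(A))
}

bf_avg_neighbor_degree <- function(A) {
  deg <- rowSums(A)
  out <- vapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] == 1)
    if (!length(nb)) 0 else mean(deg[nb])
  }, 0)
  stats::setNames(out, rownames(A))
}

bf_clustering <- function(A) {
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  out <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  stats::setNames(out, rownames(A))
}

# Largest clique containing each vertex, by subset enumeration (n <= 10).
bf_clique_number <- function(A) {
  n <- nrow(A)
  out <- rep(1, n)
  idx <- seq_len(n)
  for (k in 2:n) {
    for (s in utils::combn(idx, k, simplify = FALSE)) {
      sub <- A[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)] == 1))
        out[s] <- pmax(out[s], k)
    }
  }
  stats::setNames(out, rownames(A))
}

# Core number by iterative shell peeling.
bf_core_number <- function(A) {
  n <- nrow(A)
  alive <- rep(TRUE, n)
  core <- rep(0L, n)
  k <- 0L
  while (any(alive)) {
    repeat {
      deg <- rowSums(A[, alive, drop = FALSE])[alive]
      low <- which(deg < k + 1L)
      if (!length(low)) break
      victims <- which(alive)[low]
      core[victims] <- k
      alive[victims] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1L
    if (k > n) break
  }
  stats::setNames(core, rownames(A))
}

# Component labelling from scratch (for the resilience double-entry).
bf_components <- function(A) {
  n <- nrow(A)
  if (n == 0) return(list(sizes = integer(0), n = 0L))
  lab <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] > 0) next
    cur <- cur + 1L
    d <- bf_dist_from(A, s)
    lab[is.finite(d)] <- cur
  }
  list(sizes = as.integer(table(lab)), n = cur)
}

bf_measure <- function(A, s_ids, measure) {
  ids <- rownames(A)
  rest <- setdiff(ids, s_ids)
  if (!length(rest)) { cmax <- 0; omega <- 1 }
  else {
    comp <- bf_components(A[rest, rest, drop = FALSE])
    cmax <- max(comp$sizes); omega <- comp$n
  }
  switch(measure,
         VAT = length(s_ids) / (length(rest) - cmax + 1),
         integrity = length(s_ids) + cmax,
         tenacity = (length(s_ids) + cmax) / omega)
}

# Named random connected graph on n vertices (rejection sampling).
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    up <- which(upper.tri(A))
    A[up] <- as.integer(stats::runif(length(up)) < p)
    A <- A + t(A)
    dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
    if (all(is.finite(bf_dist_from(A, 1)))) return(A)
  }
}

path_graph <- function(n) {
  g <- igraph::make_ring(n, circular = FALSE)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

star_graph <- function(n_leaves) {
  g <- igraph::make_star(n_leaves + 1, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("ctr", sprintf("lf%d", seq_len(n_leaves)))
  g
}

complete_graph <- function(n) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

# Small labeled table fixture.
toy_table <- function(n_per_group = 6, n_taxa = 8, seed = 42) {
  withr::with_seed(seed, {
    v <- matrix(stats::rpois(2 * n_per_group * n_taxa, 20),
                2 * n_per_group, n_taxa)
    dimnames(v) <- list(sprintf("s%02d", seq_len(2 * n_per_group)),
                        sprintf("g__%s", letters[seq_len(n_taxa)]))
    OTUTable(v, labels = rep(c("Healthy", "IBD"), each = n_per_group))
  })
}

# Independent exhaustive minima of all three resilience measures in one
# subset sweep (components labelled from scratch).
bf_min_measures <- function(A) {
  ids <- rownames(A)
  n <- length(ids)
  best <- c(VAT = Inf, integrity = Inf, tenacity = Inf)
  for (mask in 0:(2^n - 2)) {          # every proper subset of V
    s <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    rest <- setdiff(ids, s)
    comp <- bf_components(A[rest, rest, drop = FALSE])
    cmax <- max(comp$sizes); omega <- comp$n
    if (length(s) > 0)
      best["VAT"] <- min(best["VAT"], length(s) / (length(rest) - cmax + 1))
    best["integrity"] <- min(best["integrity"], length(s) + cmax)
    best["tenacity"] <- min(best["tenacity"], (length(s) + cmax) / omega)
  }
  best
}
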