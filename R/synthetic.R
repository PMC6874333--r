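#' Paired phenotype graphs with planted differential nodes
#'
#' Builds two taxon-taxon association graphs over the same vertex set that
#' differ only at a planted subset of nodes: graph B is graph A with every
#' edge incident to a planted node removed and the same number of edges
#' re-attached to fresh random endpoints. These serve as the latent "truth"
#' networks of the synthetic benchmark.
#'
#' @param n_taxa number of taxa (vertices).
#' @param n_planted number of planted differential nodes (`< n_taxa`).
#' @param base_degree expected vertex degree of the base random graph.
#' @param seed integer seed.
#' @param model `"erdos_renyi"` (default) or `"scale_free"` base graph.
#' @return list with igraph objects `graph_a`, `graph_b` and character
#'   vector `planted` of planted taxon IDs.
#' @export
make_paired_graphs <- function(n_taxa, n_planted, base_degree = 4L, seed = 1L,
                               model = c("erdos_renyi", "scale_free")) {
  model <- match.arg(model)
  if (n_planted >= n_taxa) stop("n_planted must be < n_taxa")
  if (base_degree >= n_taxa) stop("base_degree must be < n_taxa")
  ids <- taxon_names(n_taxa)
  with_seed(seed, {
    g_a <- if (model == "erdos_renyi") {
      igraph::sample_gnp(n_taxa, p = base_degree / (n_taxa - 1))
    } else {
      igraph::sample_pa(n_taxa, m = max(1L, round(base_degree / 2)),
                        directed = FALSE)
    }
    igraph::V(g_a)$name <- ids
    planted <- sort(sample(ids, n_planted))
    g_b <- rewire_nodes(g_a, planted)
    list(graph_a = g_a, graph_b = g_b, planted = planted)
  })
}

taxon_names <- function(n) sprintf("g__T%03d", seq_len(n))

## Remove every edge incident to `nodes` and reattach the same number of
## edges between a planted node and a random new partner. Reattachment is
## deliberately role-changing: alternate planted nodes act as "gainers"
## that concentrate the reattached edges (emerging hubs) while the rest
## keep almost none (emerging peripherals). In a homogeneous random graph,
## uniform reattachment would leave every planted node's structural role
## statistically unchanged (same expected degree, centrality drawn from
## the same distribution), so the planted differential would be invisible
## to role-sensitive properties; flipping roles makes the planted nodes
## the genuinely differential ones. Only edges touching `nodes` can differ
## between input and output.
rewire_nodes <- function(g, nodes) {
  ids <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  touch <- el[, 1] %in% nodes | el[, 2] %in% nodes
  n_rewire <- sum(touch)
  g2 <- igraph::delete_edges(g, which(touch))
  existing <- apply(igraph::as_edgelist(g2), 1, function(e)
    paste(sort(e), collapse = "\r"))
  wts <- rep(c(0.02, 1), length.out = length(nodes))
  wts <- wts / sum(wts)
  new_edges <- character(0)
  guard <- 0L
  while (length(new_edges) < n_rewire && guard < 500L * max(1L, n_rewire)) {
    guard <- guard + 1L
    a <- if (length(nodes) == 1) nodes else sample(nodes, 1L, prob = wts)
    b <- sample(setdiff(ids, a), 1L)
    key <- paste(sort(c(a, b)), collapse = "\r")
    if (!(key %in% existing) && !(key %in% names(new_edges)))
      new_edges[key] <- key
  }
  pairs <- do.call(rbind, strsplit(unname(new_edges), "\r", fixed = TRUE))
  if (length(new_edges))
    g2 <- igraph::add_edges(g2, as.vector(t(pairs)))
  g2
}

#' Sample compositional counts from a graph-structured latent model
#'
#' Draws abundances whose taxon-taxon correlation structure follows a given
#' graph: the latent precision matrix is `I + w * A` (shrunk towards the
#' identity until positive definite), inverted and converted to a
#' correlation matrix; multivariate-normal draws are exponentiated to
#' positive abundances, multinomially resampled at a fixed sequencing depth
#' (compositionality), and finally masked to zero independently at rate
#' `zero_inflation` (excess sparsity).
#'
#' @param graph igraph object whose vertices are taxon IDs.
#' @param n_samples number of samples to draw.
#' @param depth sequencing depth per sample (multinomial size).
#' @param zero_inflation probability in `[0, 1)` that any count is zeroed.
#' @param seed integer seed.
#' @param w adjacency weight of the precision matrix (default 0.3).
#' @return An [OTUTable] of counts (`n_samples` x `n_taxa`).
#' @export
sample_counts <- function(graph, n_samples, depth = 10000L, zero_inflation = 0.1,
                          seed = 1L, w = 0.3) {
  stopifnot(depth > 0, zero_inflation >= 0, zero_inflation < 1)
  R <- graph_correlation(graph, w = w)
  n_taxa <- ncol(R)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- taxon_names(n_taxa)
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_samples * n_taxa), n_samples, n_taxa) %*% chol(R)
    abund <- exp(z)
    counts <- t(apply(abund, 1, function(a)
      stats::rmultinom(1, size = depth, prob = a / sum(a))[, 1]))
    if (zero_inflation > 0) {
      mask <- matrix(stats::runif(length(counts)) < zero_inflation,
                     nrow(counts), ncol(counts))
      counts[mask] <- 0
    }
    dimnames(counts) <- list(sprintf("s%04d", seq_len(n_samples)), ids)
    OTUTable(counts)
  })
}

## Correlation matrix implied by a graph: precision I + w*A, shrinking w
## (with a warning) until the smallest eigenvalue exceeds 1e-8.
graph_correlation <- function(graph, w = 0.3) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  A <- (A > 0) * 1
  diag(A) <- 0
  repeat {
    P <- diag(nrow(A)) + w * A
    if (nrow(A) == 0 || min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) > 1e-8)
      break
    w <- w * 0.9
    warning("precision matrix not positive definite; shrinking w to ", signif(w, 3))
  }
  stats::cov2cor(solve(P))
}

#' Generate the planted-biomarker benchmark
#'
#' Composes [make_paired_graphs()] and [sample_counts()]: one labeled OTU
#' table holding both phenotype groups, the two latent truth graphs, and
#' the identities of the planted differential taxa. Defaults define the
#' package's reference study conditions (see the methods vignette).
#'
#' @param n_taxa,n_planted,base_degree,graph_model passed to
#'   [make_paired_graphs()].
#' @param n_per_group samples per phenotype group.
#' @param depth,zero_inflation,w passed to [sample_counts()].
#' @param labels length-2 character vector of group labels.
#' @param seed integer seed controlling graphs and both count draws.
#' @return list of class `"planted_benchmark"` with elements `table`
#'   (labeled [OTUTable] of `2 * n_per_group` samples), `truth_graph_a`,
#'   `truth_graph_b`, `planted`, `params`.
#' @export
make_benchmark <- function(n_taxa = 100L, n_planted = 10L, n_per_group = 100L,
                           base_degree = 4L, depth = 10000L,
                           zero_inflation = 0.1, w = 0.3, seed = 7L,
                           labels = c("Healthy", "IBD"),
                           graph_model = "erdos_renyi") {
  stopifnot(length(labels) == 2, labels[1] != labels[2])
  gp <- make_paired_graphs(n_taxa, n_planted, base_degree = base_degree,
                           seed = seed, model = graph_model)
  t_a <- sample_counts(gp$graph_a, n_per_group, depth = depth,
                       zero_inflation = zero_inflation, seed = seed + 1001L, w = w)
  t_b <- sample_counts(gp$graph_b, n_per_group, depth = depth,
                       zero_inflation = zero_inflation, seed = seed + 2002L, w = w)
  v <- rbind(t_a$values, t_b$values)
  rownames(v) <- c(sprintf("%s_%04d", labels[1], seq_len(n_per_group)),
                   sprintf("%s_%04d", labels[2], seq_len(n_per_group)))
  lab <- rep(labels, each = n_per_group)
  structure(list(
    table = OTUTable(v, labels = lab),
    truth_graph_a = gp$graph_a,
    truth_graph_b = gp$graph_b,
    planted = gp$planted,
    params = list(n_taxa = n_taxa, n_planted = n_planted,
                  n_per_group = n_per_group, base_degree = base_degree,
                  depth = depth, zero_inflation = zero_inflation, w = w,
                  seed = seed, labels = labels, graph_model = graph_model)),
    class = "planted_benchmark")
}

#' @export
#' @method print planted_benchmark
print.planted_benchmark <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("planted benchmark: %d taxa, %d planted, %d samples/group, ",
                     "depth %d, zero inflation %.2f (seed %d)\n"),
              p$n_taxa, p$n_planted, p$n_per_group, p$depth,
              p$zero_inflation, p$seed))
  invisible(x)
}

#' Write a benchmark to plain-text artifacts
#'
#' Writes the count table, a metadata TSV, both truth edge lists and the
#' planted-node list into `out_dir`.
#'
#' @param bench a `"planted_benchmark"`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(bench$table, file.path(out_dir, "table.tsv"))
  utils::write.table(
    data.frame(sample_id = sample_ids(bench$table), label = bench$table$labels),
    file.path(out_dir, "metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_edge_list(bench$truth_graph_a, file.path(out_dir, "truth_edges_a.tsv"))
  write_edge_list(bench$truth_graph_b, file.path(out_dir, "truth_edges_b.tsv"))
  writeLines(bench$planted, file.path(out_dir, "planted_nodes.txt"))
  invisible(out_dir)
}
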