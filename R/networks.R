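## Network construction: four interchangeable ways of turning one
## phenotype's OTU table into an undirected microbial ecology network
## (taxa as vertices, association edges). All constructors return a simple
## undirected igraph whose vertex names are taxon IDs; edge attribute
## `weight` carries the association strength where one is defined.

#' Pearson correlation matrix over taxa
#'
#' @param table an [OTUTable] with at least 3 samples.
#' @param log_transform log-transform abundances first (zeros replaced by
#'   `pseudo_count`).
#' @param pseudo_count value substituted for zeros before the log.
#' @return symmetric matrix with unit diagonal, entries in `[-1, 1]`;
#'   correlations involving a constant taxon are 0 (with a warning), never
#'   `NaN`.
#' @export
pearson_matrix <- function(table, log_transform = FALSE, pseudo_count = 1) {
  x <- table$values
  if (nrow(x) < 3) stop("correlation undefined below 3 samples")
  if (log_transform) {
    if (pseudo_count <= 0 && any(x == 0))
      stop("log transform with zeros requires pseudo_count > 0")
    x[x == 0] <- pseudo_count
    x <- log(x)
  }
  const <- apply(x, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning("constant taxon column(s): ",
            paste(colnames(x)[const], collapse = ", "),
            "; correlations set to 0")
    r[const, ] <- 0
    r[, const] <- 0
  }
  r[is.na(r)] <- 0
  diag(r) <- 1
  pmin(pmax(r, -1), 1)
}

## Build an igraph from a symmetric association matrix and a logical
## adjacency, keeping matrix values as edge weights.
graph_from_assoc <- function(adj, assoc = NULL) {
  adj <- adj | t(adj)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (!is.null(assoc)) {
    el <- igraph::as_edgelist(g)
    if (nrow(el)) igraph::E(g)$weight <- assoc[cbind(el[, 1], el[, 2])]
  }
  g
}

#' k-nearest-neighbour proximity network
#'
#' Uses the distance `d(u, v) = 1 - |pearson(u, v)|` between taxon
#' abundance vectors. Each taxon contributes edges to its `k_neighbors`
#' nearest taxa; under the default union rule an edge exists when either
#' endpoint lists the other (so every vertex has degree at least
#' `k_neighbors`); the mutual rule requires both. Distance ties are broken
#' lexicographically by taxon ID. By the package's convention abundances
#' are log-transformed before correlating (raw-scale Pearson on
#' heavy-tailed abundance vectors is dominated by a handful of extreme
#' samples); set `log_transform = FALSE` for plain Pearson.
#'
#' @param table an [OTUTable].
#' @param k_neighbors neighbourhood size (default 7).
#' @param rule `"union"` (default) or `"mutual"` neighbourhood merge.
#' @param log_transform correlate log abundances (default) or raw values.
#' @param pseudo_count zero replacement before the log.
#' @return undirected igraph; edge weight = `|r|`.
#' @export
build_proxi <- function(table, k_neighbors = 7L, rule = c("union", "mutual"),
                        log_transform = TRUE, pseudo_count = 1) {
  rule <- match.arg(rule)
  p <- ncol(table$values)
  if (p <= k_neighbors) stop("need n_taxa > k_neighbors")
  r <- pearson_matrix(table, log_transform = log_transform,
                      pseudo_count = pseudo_count)
  d <- 1 - abs(r)
  ids <- colnames(d)
  lists <- matrix(FALSE, p, p, dimnames = dimnames(d))
  for (i in seq_len(p)) {
    ord <- order(d[i, -i], ids[-i])
    lists[i, ids[-i][ord[seq_len(k_neighbors)]]] <- TRUE
  }
  adj <- if (rule == "union") lists | t(lists) else lists & t(lists)
  graph_from_assoc(adj, abs(r))
}

#' SparCC basis correlations
#'
#' Estimates correlations between latent (basis) log abundances from
#' compositional data. Values are first reduced to per-sample fractions;
#' zero fractions are replaced by a pseudo-fraction (`pseudo_count` times
#' half the smallest nonzero fraction in the table), so the estimate
#' depends on the fractions alone and is exactly invariant to per-sample
#' rescaling (compositional invariance). The variation matrix
#' `t_uv = var(log(x_u / x_v))` is computed across samples; basis
#' variances are obtained from the sparsity-approximated linear system;
#' basis correlations follow as
#' `rho_uv = (w_u + w_v - t_uv) / (2 sqrt(w_u w_v))`, clipped to `[-1, 1]`.
#' The most correlated pair with `|rho|` above `exclusion_threshold` is
#' iteratively excluded from the system and the variances re-solved, up to
#' `n_exclusion_iters` times.
#'
#' @param table an [OTUTable] with at least 4 taxa.
#' @param pseudo_count multiplier of the half-minimum pseudo-fraction
#'   replacing zeros (default 1).
#' @param n_exclusion_iters maximum strongly-correlated pairs to exclude.
#' @param exclusion_threshold `|rho|` above which a pair may be excluded.
#' @param edge_threshold `|rho|` at or above which an edge is drawn.
#' @return undirected igraph; edge weight = basis correlation. The
#'   estimated correlation matrix is attached as graph attribute `rho`,
#'   the excluded pairs as attribute `excluded` (2-column matrix).
#' @export
build_sparcc <- function(table, pseudo_count = 1, n_exclusion_iters = 10L,
                         exclusion_threshold = 0.1, edge_threshold = 0.3) {
  fit <- sparcc_correlation(table, pseudo_count, n_exclusion_iters,
                            exclusion_threshold)
  rho <- fit$rho
  adj <- abs(rho) >= edge_threshold
  g <- graph_from_assoc(adj, rho)
  g <- igraph::set_graph_attr(g, "rho", rho)
  igraph::set_graph_attr(g, "excluded", fit$excluded)
}

## Core SparCC estimator; returns list(rho, omega, excluded).
sparcc_correlation <- function(table, pseudo_count = 1,
                               n_exclusion_iters = 10L,
                               exclusion_threshold = 0.1) {
  p <- ncol(table$values)
  if (p < 4) stop("SparCC requires at least 4 taxa")
  rs <- rowSums(table$values)
  if (any(rs <= 0)) stop("sample with all-zero abundance: ",
                         rownames(table$values)[which(rs <= 0)[1]])
  x <- table$values / rs
  pos <- x[x > 0]
  if (length(pos) < length(x))
    x[x == 0] <- pseudo_count * min(pos) / 2
  lx <- log(x)
  # variation matrix: var over samples of log-ratio for every pair
  tv <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    v <- stats::var(lx[, i] - lx[, j])
    tv[i, j] <- tv[j, i] <- v
  }
  included <- matrix(TRUE, p, p)
  diag(included) <- FALSE
  excluded <- matrix(character(0), ncol = 2,
                     dimnames = list(NULL, c("taxon_a", "taxon_b")))
  solve_omega <- function(incl) {
    M <- diag(rowSums(incl)) + incl
    t_i <- rowSums(tv * incl)
    omega <- tryCatch(solve(M, t_i), error = function(e) NULL)
    omega
  }
  rho_from <- function(omega) {
    omega <- pmax(omega, 1e-12)  # guard: variance estimates can go negative
    s <- sqrt(omega)
    rho <- (outer(omega, omega, "+") - tv) / (2 * outer(s, s))
    diag(rho) <- 1
    pmin(pmax(rho, -1), 1)
  }
  omega <- solve_omega(included)
  if (is.null(omega)) return(sparcc_fallback(table, pseudo_count, excluded))
  rho <- rho_from(omega)
  for (it in seq_len(n_exclusion_iters)) {
    a <- abs(rho) * included
    m <- max(a)
    if (m <= exclusion_threshold) break
    idx <- which(a == m, arr.ind = TRUE)[1, ]
    included[idx[1], idx[2]] <- included[idx[2], idx[1]] <- FALSE
    excluded <- rbind(excluded, sort(colnames(tv)[idx]))
    if (any(rowSums(included) < 2)) break  # keep the system well posed
    omega <- solve_omega(included)
    if (is.null(omega)) return(sparcc_fallback(table, pseudo_count, excluded))
    rho <- rho_from(omega)
  }
  list(rho = rho, omega = omega, excluded = excluded)
}

sparcc_fallback <- function(table, pseudo_count, excluded) {
  warning("SparCC basis system singular; falling back to Pearson on log fractions")
  fr <- table$values / rowSums(table$values)
  pos <- fr[fr > 0]
  if (length(pos) < length(fr))
    fr[fr == 0] <- pseudo_count * min(pos) / 2
  rho <- pearson_matrix(OTUTable(log(fr) - min(log(fr)) + 1))
  list(rho = rho, omega = NULL, excluded = excluded)
}

#' Meinshausen-Buhlmann neighbourhood selection network
#'
#' Regresses each taxon's centred log-ratio (clr) abundance on all others
#' with an L1 penalty; a taxon's neighbourhood is the set of predictors
#' with nonzero coefficient. The penalty is chosen per graph as the
#' smallest value on `lambda_grid` whose resulting graph density does not
#' exceed `density_target` (i.e. the densest graph within the sparsity
#' budget). Neighbourhoods are merged into undirected edges by the OR rule
#' (either endpoint selects the other) or the AND rule (both must).
#'
#' @param table an [OTUTable].
#' @param lambda_grid decreasing-density grid of penalties (default
#'   `10^seq(0, -3, length.out = 25)`).
#' @param merge_rule `"OR"` (default) or `"AND"`.
#' @param density_target maximum admissible edge density (default 0.05).
#' @param pseudo_count zero replacement before the clr transform.
#' @return undirected igraph.
#' @export
build_mb <- function(table, lambda_grid = 10^seq(0, -3, length.out = 25),
                     merge_rule = c("OR", "AND"), density_target = 0.05,
                     pseudo_count = 1) {
  merge_rule <- match.arg(merge_rule)
  if (!length(lambda_grid)) stop("lambda_grid must be non-empty")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  x <- table$values
  x[x == 0] <- pseudo_count
  lx <- log(x)
  clr <- lx - rowMeans(lx)
  p <- ncol(clr)
  ids <- colnames(clr)
  # nonzero-coefficient indicator per (target, lambda)
  nb <- array(FALSE, dim = c(p, p, length(lambda_grid)))
  for (i in seq_len(p)) {
    fit <- glmnet::glmnet(clr[, -i, drop = FALSE], clr[, i],
                          family = "gaussian", lambda = lambda_grid,
                          standardize = TRUE)
    beta <- as.matrix(fit$beta)  # (p-1) x n_lambda
    for (l in seq_along(fit$lambda)) {
      sel <- rownames(beta)[beta[, l] != 0]
      nb[i, match(sel, ids), l] <- TRUE
    }
  }
  merge <- function(l) {
    m <- nb[, , l]
    if (merge_rule == "OR") m | t(m) else m & t(m)
  }
  density <- function(adj) sum(adj) / (p * (p - 1))
  chosen <- NULL
  for (l in seq_along(lambda_grid)) {        # largest lambda first
    if (density(merge(l)) <= density_target) chosen <- l else break
  }
  if (is.null(chosen)) chosen <- 1L
  adj <- merge(chosen)
  dimnames(adj) <- list(ids, ids)
  g <- graph_from_assoc(adj)
  igraph::set_graph_attr(g, "lambda", lambda_grid[chosen])
}

#' Random-matrix-theory thresholded correlation network
#'
#' Applies a prevalence filter, computes Pearson correlations of
#' log-transformed abundances, and connects taxa whose `|r|` reaches a
#' threshold. In `auto_rmt` mode the threshold is chosen by scanning a grid
#' upward and testing, at each candidate, whether the nearest-neighbour
#' spacing distribution of the eigenvalues of the thresholded correlation
#' matrix (restricted to non-isolated taxa, rank/ECDF-spline unfolded)
#' is consistent with the Poisson (exponential) law by a chi-square
#' goodness-of-fit test; the smallest non-rejected threshold is used.
#'
#' @param table an [OTUTable].
#' @param prevalence prevalence filter fraction (default 0.25).
#' @param threshold_mode `"auto_rmt"` (default) or `"fixed"`.
#' @param fixed_threshold threshold used in fixed mode.
#' @param grid candidate thresholds for the scan.
#' @param alpha chi-square significance level (default 0.05).
#' @param n_bins target bin count for the spacing histogram.
#' @param pseudo_count zero replacement before the log.
#' @return undirected igraph over the prevalence-retained taxa; edge
#'   weight = correlation; chosen threshold as graph attribute `threshold`.
#' @export
build_rmt <- function(table, prevalence = 0.25,
                      threshold_mode = c("auto_rmt", "fixed"),
                      fixed_threshold = 0.6,
                      grid = seq(0.30, 0.95, by = 0.01), alpha = 0.05,
                      n_bins = 20L, pseudo_count = 1) {
  threshold_mode <- match.arg(threshold_mode)
  ft <- prevalence_filter(table, prevalence)
  if (ncol(ft$values) < 10) stop("fewer than 10 taxa after prevalence filter")
  r <- pearson_matrix(ft, log_transform = TRUE, pseudo_count = pseudo_count)
  thr <- if (threshold_mode == "fixed") fixed_threshold else {
    sel <- rmt_select_threshold(r, grid, alpha, n_bins)
    if (is.na(sel)) {
      warning("no threshold accepted by the spacing test; using grid maximum")
      max(grid)
    } else sel
  }
  adj <- abs(r) >= thr
  g <- graph_from_assoc(adj, r)
  igraph::set_graph_attr(g, "threshold", thr)
}

## Scan thresholds ascending; return the smallest at which the unfolded
## nearest-neighbour eigenvalue spacings are not rejected against Exp(1).
rmt_select_threshold <- function(r, grid, alpha, n_bins) {
  for (thr in sort(grid)) {
    m <- r
    m[abs(m) < thr] <- 0
    diag(m) <- 1
    keep <- colSums(abs(m) > 0) > 1  # non-isolated (diag always > 0)
    if (sum(keep) < 15) next
    ev <- eigen(m[keep, keep], symmetric = TRUE, only.values = TRUE)$values
    s <- unfold_spacings(ev)
    if (length(s) < 20) next
    p <- poisson_spacing_pvalue(s, n_bins)
    if (!is.na(p) && p >= alpha) return(thr)
  }
  NA_real_
}

## Unfold eigenvalues with a smoothing spline through the empirical
## cumulative count, then return consecutive spacings (mean-normalized).
unfold_spacings <- function(ev) {
  ev <- sort(ev)
  ev <- ev[!duplicated(round(ev, 10))]
  n <- length(ev)
  if (n < 5) return(numeric(0))
  cum <- seq_len(n)
  df <- max(4, min(10, floor(n / 4)))
  sp <- tryCatch(stats::smooth.spline(ev, cum, df = df), error = function(e) NULL)
  unfolded <- if (is.null(sp)) cum else stats::predict(sp, ev)$y
  s <- diff(sort(unfolded))
  s <- s[s > 0]
  if (!length(s)) return(numeric(0))
  s / mean(s)
}

## Chi-square goodness of fit of spacings against Exp(1) using
## equal-probability bins; returns the p-value.
poisson_spacing_pvalue <- function(s, n_bins) {
  n <- length(s)
  k <- max(5L, min(n_bins, floor(n / 5)))
  breaks <- stats::qexp(seq(0, 1, length.out = k + 1))
  breaks[k + 1] <- Inf
  obs <- table(cut(s, breaks, include.lowest = TRUE))
  expd <- rep(n / k, k)
  stat <- sum((as.numeric(obs) - expd)^2 / expd)
  stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
}

#' Write a network as an edge-list TSV
#'
#' Columns `taxon_a`, `taxon_b`, `weight` (1 when the graph is unweighted);
#' endpoints canonically ordered, rows sorted, so output is reproducible.
#'
#' @param g igraph with named vertices.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight
       else rep(1, nrow(el))
  if (nrow(el)) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    ord <- order(el[, 1], el[, 2])
    el <- el[ord, , drop = FALSE]
    w <- w[ord]
  }
  utils::write.table(
    data.frame(taxon_a = el[, 1], taxon_b = el[, 2], weight = w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge-list TSV written by [write_edge_list()]
#'
#' @param path edge-list path.
#' @param vertices optional full vertex set (isolated vertices included).
#' @return undirected igraph.
#' @export
read_edge_list <- function(path, vertices = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
  g
}
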