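## Traditional feature-selection baselines (information gain, ANOVA
## F-statistic, RFE-LASSO, random-forest feature importance), the hybrid
## RFFI x NTPS score, and deterministic top-k selection.

require_labels <- function(table) {
  if (is.null(table$labels)) stop("table has no phenotype labels")
  lev <- sort(unique(table$labels))
  if (length(lev) != 2) stop("expected a binary phenotype, found ",
                             length(lev), " label value(s)")
  factor(table$labels, levels = lev)
}

#' Rank taxa by information gain
#'
#' Each taxon's abundance is discretized into `n_bins` equal-width bins
#' over its observed range; the score is the mutual information between
#' bin and phenotype label, `IG = H(label) - H(label | bin)`, in bits.
#' Constant taxa fall into a single bin and score 0.
#'
#' @param table a labeled [OTUTable].
#' @param n_bins number of equal-width bins (default 10).
#' @return named non-negative numeric vector of scores per taxon.
#' @export
rank_information_gain <- function(table, n_bins = 10L) {
  y <- require_labels(table)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h_y <- h(table(y) / length(y))
  apply(table$values, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) return(0)
    bins <- cut(x, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                include.lowest = TRUE)
    h_cond <- 0
    for (b in levels(bins)) {
      idx <- bins == b
      if (!any(idx)) next
      h_cond <- h_cond + mean(idx) * h(table(y[idx]) / sum(idx))
    }
    max(0, h_y - h_cond)
  })
}

#' Rank taxa by one-way ANOVA F-statistic
#'
#' For a binary phenotype, per taxon:
#' `F = (between-group SS / (g - 1)) / (within-group SS / (n - g))` with
#' `g = 2`. A taxon with zero within-group variance but unequal group means
#' receives the largest finite score (with a warning); identical group
#' distributions give 0.
#'
#' @param table a labeled [OTUTable] with at least 2 samples per group.
#' @return named non-negative numeric vector of F scores.
#' @export
rank_f_statistic <- function(table) {
  y <- require_labels(table)
  if (any(table(y) < 2)) stop("each group needs at least 2 samples")
  x <- table$values
  n <- nrow(x)
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  grand <- colMeans(x)
  ssb <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  ssw <- colSums((t(t(x[g1, , drop = FALSE]) - m1))^2) +
         colSums((t(t(x[!g1, , drop = FALSE]) - m2))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  degenerate <- ssw == 0 & ssb > 0
  if (any(degenerate)) {
    warning("zero within-group variance with unequal means for: ",
            paste(names(f)[degenerate], collapse = ", "))
    f[degenerate] <- .Machine$double.xmax
  }
  f[ssw == 0 & ssb == 0] <- 0
  f
}

#' Recursive feature elimination with a LASSO estimator
#'
#' Iteratively fits an L1-penalized logistic model of the phenotype on the
#' remaining taxa, ranks them by absolute coefficient, and drops the
#' `step` lowest-ranked per iteration (fewer on the last, so exactly `k`
#' survive). Survivors are returned ranked by their final absolute
#' coefficient; the full ranking appends eliminated taxa in reverse
#' elimination order.
#'
#' @param table a labeled [OTUTable].
#' @param k number of features to retain (`<= n_taxa`; with `k = n_taxa`
#'   no elimination happens and taxa are ranked by one fit).
#' @param step features eliminated per iteration (default 10).
#' @param lambda fixed L1 penalty for each fit (default 0.01).
#' @return list with `selected` (character, length `k`), `ranking` (all
#'   taxa, best first) and `scores` (final |coefficient| of survivors).
#' @export
rfe_lasso <- function(table, k, step = 10L, lambda = 0.01) {
  y <- require_labels(table)
  p <- ncol(table$values)
  if (k > p) stop("k must not exceed the number of taxa")
  if (k < 1) stop("k must be >= 1")
  remaining <- colnames(table$values)
  eliminated <- character(0)
  coefs <- NULL
  repeat {
    x <- table$values[, remaining, drop = FALSE]
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = lambda,
                          standardize = TRUE)
    beta <- abs(as.matrix(fit$beta)[, 1])
    coefs <- sort(beta, decreasing = TRUE)
    if (length(remaining) == k) break
    drop_n <- min(step, length(remaining) - k)
    # lowest |coef|, ties broken lexicographically for determinism
    ord <- order(beta, names(beta))
    out <- names(beta)[ord[seq_len(drop_n)]]
    eliminated <- c(out, eliminated)  # latest eliminations rank higher
    remaining <- setdiff(remaining, out)
  }
  selected <- names(coefs)
  list(selected = selected,
       ranking = c(selected, eliminated),
       scores = coefs)
}

#' Random-forest feature importance (RFFI)
#'
#' Trains a random forest on the labeled table and returns mean
#' impurity-decrease importances, normalized to sum to one. Deterministic
#' given the seed.
#'
#' @param table a labeled [OTUTable].
#' @param n_trees forest size (default 500).
#' @param seed integer seed.
#' @param type `"impurity"` (default) or `"permutation"` importance.
#' @return named non-negative numeric vector summing to 1.
#' @export
rffi <- function(table, n_trees = 500L, seed = 1L,
                 type = c("impurity", "permutation")) {
  type <- match.arg(type)
  y <- require_labels(table)
  x <- as.data.frame(table$values)
  colnames(x) <- make.names(colnames(x))
  fit <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees,
                               importance = (type == "permutation")))
  imp <- if (type == "impurity")
    randomForest::importance(fit, type = 2)[, 1]
  else
    randomForest::importance(fit, type = 1)[, 1]
  imp <- pmax(imp, 0)
  names(imp) <- colnames(table$values)
  if (sum(imp) == 0) {
    warning("all importances are zero; returning a uniform score")
    return(stats::setNames(rep(1 / length(imp), length(imp)), names(imp)))
  }
  imp / sum(imp)
}

#' Hybrid feature score: RFFI x NTPS
#'
#' Elementwise product of random-forest importance and the differential
#' network topology score, on the intersection of the two taxon sets; a
#' taxon missing from either input has no hybrid score (it is excluded,
#' not zero-filled).
#'
#' @param rffi_scores,ntps_scores named numeric score vectors.
#' @return named numeric vector over the shared taxa.
#' @export
hybrid_score <- function(rffi_scores, ntps_scores) {
  shared <- sort(intersect(names(rffi_scores), names(ntps_scores)))
  if (!length(shared)) stop("score vectors share no taxa")
  rffi_scores[shared] * ntps_scores[shared]
}

#' Select the top-k taxa from a score vector
#'
#' Orders by score descending; ties (including at the k boundary) are
#' broken lexicographically by taxon ID, so selection is deterministic and
#' monotone in `k`.
#'
#' @param scores named numeric vector.
#' @param k number of taxa to keep (`1 <= k <= length(scores)`).
#' @return character vector of `k` taxon IDs in rank order.
#' @export
select_top_k <- function(scores, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(scores)) stop("k exceeds the number of scored taxa (",
                               length(scores), ")")
  names(scores)[order(-scores, names(scores))][seq_len(k)]
}
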