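## Classifier harness: random-forest training on selected taxa, the five
## evaluation metrics (ACC, Sn, Sp, MCC, AUC), the FSDS-size x k
## experiment grid, and a Kruskal-Wallis differential-abundance check.

#' Train a random forest on selected taxa
#'
#' Fits a forest on the feature-restricted relative-abundance matrix of a
#' labeled table. The positive class is the lexicographically larger label
#' (e.g. "IBD" over "Healthy") unless given.
#'
#' @param train a labeled [OTUTable] (counts are converted to relative
#'   abundances internally).
#' @param features character vector of taxon IDs to use (non-empty, all
#'   present in the table).
#' @param n_trees forest size (default 500).
#' @param seed integer seed (reproducible fits).
#' @param positive label treated as the positive class.
#' @return object of class `"nbbd_rf"` wrapping the fitted forest, the
#'   feature list and the positive class.
#' @export
train_rf <- function(train, features, n_trees = 500L, seed = 1L,
                     positive = NULL) {
  y <- require_labels(train)
  if (!length(features)) stop("empty feature list")
  missing <- setdiff(features, taxon_ids(train))
  if (length(missing)) stop("feature not in table: ",
                            paste(missing, collapse = ", "))
  if (is.null(positive)) positive <- levels(y)[2]
  if (!positive %in% levels(y)) stop("positive class '", positive,
                                     "' not a label value")
  xtab <- if (train$normalized) train else to_relative_abundance(train)
  x <- as.data.frame(xtab$values[, features, drop = FALSE])
  colnames(x) <- make.names(features)
  fit <- with_seed(seed,
    randomForest::randomForest(x, y, ntree = n_trees))
  structure(list(forest = fit, features = features, positive = positive,
                 levels = levels(y)),
            class = "nbbd_rf")
}

predict_prob <- function(model, table) {
  xtab <- if (table$normalized) table else to_relative_abundance(table)
  x <- as.data.frame(xtab$values[, model$features, drop = FALSE])
  colnames(x) <- make.names(model$features)
  p <- stats::predict(model$forest, x, type = "prob")
  p[, model$positive]
}

#' Classification metrics from a confusion matrix
#'
#' `ACC = (TP + TN) / n`, `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the
#' convention `MCC = 0` when any factor of the denominator is zero.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return named list `acc`, `sn`, `sp`, `mcc`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  den <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(den == 0)) 0 else
    (tp * tn - fp * fn) / sqrt(prod(den))
  list(acc = (tp + tn) / n,
       sn = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       sp = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
       mcc = mcc)
}

#' Area under the ROC curve by the rank statistic
#'
#' Midrank (Mann-Whitney) estimator, handling tied probabilities; `NA`
#' when the truth vector has a single class.
#'
#' @param prob numeric predicted positive-class probabilities.
#' @param truth logical (or 0/1) vector: is the sample positive?
#' @return AUC in `[0, 1]`, or `NA`.
#' @export
auc_score <- function(prob, truth) {
  truth <- as.logical(truth)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(prob, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a trained model on a labeled test table
#'
#' Thresholds the predicted positive-class probability at 0.5 for the
#' confusion counts; AUC uses the midrank statistic on the probabilities.
#'
#' @param model an `"nbbd_rf"` from [train_rf()].
#' @param test a labeled [OTUTable] containing the model's features.
#' @param threshold probability cut for the confusion matrix (default 0.5).
#' @return list of class `"eval_report"`: `acc`, `sn`, `sp`, `mcc`, `auc`,
#'   `confusion` (tp, fp, tn, fn) and `n_features`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  y <- require_labels(test)
  prob <- predict_prob(model, test)
  truth <- y == model$positive
  pred <- prob >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  m <- metrics_from_confusion(tp, fp, tn, fn)
  structure(c(m, list(auc = auc_score(prob, truth),
                      confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                      n_features = length(model$features))),
            class = "eval_report")
}

#' @export
#' @method print eval_report
print.eval_report <- function(x, ...) {
  cat(sprintf("ACC %.3f  Sn %.3f  Sp %.3f  MCC %.3f  AUC %s  (%d features)\n",
              x$acc, x$sn, x$sp, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$n_features))
  invisible(x)
}

#' Feature-selection experiment grid
#'
#' For every combination of feature-selection data-set size, method and
#' `k`: rank taxa on the FSDS only, train a random forest on the *full*
#' training table restricted to the selected taxa, and evaluate on the
#' held-out test table. The `"none"` baseline (all taxa) appears once per
#' FSDS; `"cass"` methods choose their own adaptive feature count, so `k`
#' is reported as `NA`. Cell failures (e.g. an empty shared attack set)
#' become status rows and the grid continues.
#'
#' @param train labeled training [OTUTable] (also the FSDS source).
#' @param test labeled held-out [OTUTable].
#' @param fsds_sizes per-group FSDS sizes (strictly increasing; nested
#'   subsets drawn with `seed`).
#' @param methods character vector among `"none"`, `"ig"`, `"fstat"`,
#'   `"rfe"`, `"rffi"`, `"ntps"`, `"cass"`, `"hybrid"`.
#' @param k_grid feature counts to try (default `c(10,20,30,40,50,60)`).
#' @param seed integer seed for subsetting, forests and selectors.
#' @param n_trees forest size.
#' @param control list of network/scoring options for the network-based
#'   methods: `net_method` (`"proxi"`, `"sparcc"`, `"mb"`, `"rmt"`),
#'   `property` (NTPS property) and `measure` (CASS measure).
#' @return data.frame with one row per grid cell: `fsds`, `method`, `k`,
#'   `n_features`, `acc`, `sn`, `sp`, `mcc`, `auc`, `status`.
#' @export
experiment_grid <- function(train, test, fsds_sizes,
                            methods = c("none", "rffi"),
                            k_grid = c(10L, 20L, 30L, 40L, 50L, 60L),
                            seed = 1L, n_trees = 500L,
                            control = list(net_method = "proxi",
                                           property = "btw",
                                           measure = "integrity")) {
  subsets <- nested_subsets(train, fsds_sizes, seed = seed)
  rows <- list()
  add <- function(fsds, method, k, rep, status = "ok") {
    rows[[length(rows) + 1]] <<- data.frame(
      fsds = fsds, method = method, k = if (is.null(k)) NA_integer_ else k,
      n_features = if (is.null(rep)) NA_integer_ else rep$n_features,
      acc = if (is.null(rep)) NA_real_ else rep$acc,
      sn = if (is.null(rep)) NA_real_ else rep$sn,
      sp = if (is.null(rep)) NA_real_ else rep$sp,
      mcc = if (is.null(rep)) NA_real_ else rep$mcc,
      auc = if (is.null(rep)) NA_real_ else rep$auc,
      status = status, stringsAsFactors = FALSE)
  }
  fit_eval <- function(features) {
    model <- train_rf(train, features, n_trees = n_trees, seed = seed)
    evaluate_model(model, test)
  }
  for (i in seq_along(fsds_sizes)) {
    fsds_tag <- sprintf("DS%d", 2L * fsds_sizes[i])
    fsds <- subsets[[i]]
    for (method in methods) {
      res <- tryCatch({
        if (method == "none") {
          add(fsds_tag, method, NULL, fit_eval(taxon_ids(train)))
        } else if (method == "cass") {
          sel <- cass_scores(fsds, control, seed)
          if (!length(sel)) add(fsds_tag, method, NULL, NULL, "empty_feature_set")
          else add(fsds_tag, method, NULL, fit_eval(sel))
        } else {
          scores <- method_scores(method, fsds, control, seed)
          for (k in k_grid) {
            if (k > length(scores)) {
              add(fsds_tag, method, k, NULL, "k_exceeds_taxa"); next
            }
            add(fsds_tag, method, k, fit_eval(select_top_k(scores, k)))
          }
        }
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) add(fsds_tag, method, NULL, NULL, paste0("error: ", res))
    }
  }
  do.call(rbind, rows)
}

## Score vector for one ranking method on the FSDS.
method_scores <- function(method, fsds, control, seed) {
  switch(method,
    ig = rank_information_gain(fsds),
    fstat = rank_f_statistic(fsds),
    rfe = {
      r <- rfe_lasso(fsds, k = ncol(fsds$values))
      stats::setNames(rev(seq_along(r$ranking)), r$ranking)  # rank order
    },
    rffi = rffi(fsds, seed = seed),
    ntps = ntps_scores(fsds, control),
    hybrid = hybrid_score(rffi(fsds, seed = seed), ntps_scores(fsds, control)),
    stop("unknown method '", method, "'"))
}

ntps_scores <- function(fsds, control) {
  nets <- phenotype_networks(fsds, control$net_method)
  ntps_score(nets[[1]], nets[[2]], control$property)
}

cass_scores <- function(fsds, control, seed) {
  nets <- phenotype_networks(fsds, control$net_method)
  suppressWarnings(as.character(cass_select(nets[[1]], nets[[2]],
                                            control$measure)))
}

## Build the two phenotype networks of a labeled table.
phenotype_networks <- function(table, net_method = c("proxi", "sparcc",
                                                     "mb", "rmt"), ...) {
  net_method <- match.arg(net_method)
  builder <- switch(net_method, proxi = build_proxi, sparcc = build_sparcc,
                    mb = build_mb, rmt = build_rmt)
  lapply(split_by_phenotype(table), builder, ...)
}

#' Summarize an experiment grid by the best model per method
#'
#' For each (fsds, method), keeps the row with the highest AUC and, on
#' ties, the smallest feature count.
#'
#' @param grid data.frame from [experiment_grid()].
#' @return data.frame with one row per (fsds, method).
#' @export
top_per_method <- function(grid) {
  ok <- grid[grid$status == "ok" & !is.na(grid$auc), , drop = FALSE]
  keys <- unique(ok[, c("fsds", "method")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    rows <- ok[ok$fsds == keys$fsds[i] & ok$method == keys$method[i], ,
               drop = FALSE]
    rows[order(-rows$auc, rows$n_features), ][1, ]
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis differential-abundance test for one taxon
#'
#' Rank-based two-group comparison of a taxon's abundance between the
#' phenotype groups (tie-corrected H statistic; for two groups the test is
#' a monotone transform of Mann-Whitney).
#'
#' @param table a labeled [OTUTable].
#' @param taxon taxon ID.
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis <- function(table, taxon) {
  y <- require_labels(table)
  if (any(table(y) < 2)) stop("each group needs at least 2 samples")
  if (!taxon %in% taxon_ids(table)) stop("unknown taxon: ", taxon)
  x <- table$values[, taxon]
  if (length(unique(x)) == 1) return(list(statistic = 0, p.value = 1))
  kt <- stats::kruskal.test(x, y)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}
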