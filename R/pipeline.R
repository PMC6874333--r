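## End-to-end pipeline: simulate or ingest a labeled table, split it into
## training and test halves, fit the network-based selector on a (possibly
## small) feature-selection subset, train a random forest on the full
## training half, evaluate on the held-out half, and write every artifact
## plus a JSON manifest. Deterministic given the config.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @return named list understood by [run_pipeline()]. Fields: `simulate`
#'   (generator parameters, or `NULL` to read `table_path`/`metadata_path`),
#'   `table_path`, `metadata_path`, `net_method`, `scoring`, `property`,
#'   `measure`, `k`, `n_trees`, `fsds_per_group` (feature-selection subset
#'   size per group; `NULL` = full training half), `test_fraction`, `seed`,
#'   `out_dir`.
#' @export
default_config <- function(out_dir = tempfile("nbbd_run_"), seed = 7L) {
  list(simulate = list(n_taxa = 100L, n_planted = 10L, n_per_group = 100L,
                       depth = 10000L, zero_inflation = 0.3, seed = seed),
       table_path = NULL, metadata_path = NULL,
       net_method = "proxi", scoring = "ntps", property = "btw",
       measure = "integrity", k = 10L, n_trees = 500L,
       fsds_per_group = NULL, test_fraction = 0.5,
       seed = seed, out_dir = out_dir)
}

read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cfg[lengths(cfg) > 0]  # JSON nulls come back as empty elements
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' Run the full discovery pipeline
#'
#' Stages: simulate (or ingest) a labeled OTU table; split samples into
#' training and test halves (class-balanced, seeded); optionally shrink
#' the feature-selection subset; build the two phenotype networks; score
#' and select taxa; train a random forest on the full training half;
#' evaluate on the test half. Writes the table, metadata, both edge lists,
#' the score table, the selected-taxon list, the evaluation report and a
#' JSON manifest into `config$out_dir`.
#'
#' @param config list from [default_config()] (or a path to a JSON file
#'   with the same fields).
#' @return invisible list with `fit` (the `"nbbd"` object), `report`
#'   (the `"eval_report"`) and `paths` of all written artifacts.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  required <- c("net_method", "scoring", "k", "seed", "out_dir")
  miss <- setdiff(required, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  if (is.null(config$simulate)) {
    if (is.null(config$table_path) || !file.exists(config$table_path))
      stop("config error: table_path missing or not found")
    if (is.null(config$metadata_path) || !file.exists(config$metadata_path))
      stop("config error: metadata_path missing or not found")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  table <- if (!is.null(config$simulate)) {
    sim <- config$simulate
    bench <- make_benchmark(n_taxa = sim$n_taxa, n_planted = sim$n_planted,
                            n_per_group = sim$n_per_group,
                            depth = sim$depth,
                            zero_inflation = sim$zero_inflation,
                            seed = sim$seed)
    paths$truth <- write_benchmark(bench, file.path(config$out_dir, "benchmark"))
    bench$table
  } else {
    read_metadata(read_otu_table(config$table_path), config$metadata_path)
  }
  paths$table <- write_otu_table(table, file.path(config$out_dir, "table.tsv"))
  utils::write.table(
    data.frame(sample_id = sample_ids(table), label = table$labels),
    paths$metadata <- file.path(config$out_dir, "metadata.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  halves <- train_test_split(table, test_fraction = config$test_fraction,
                             seed = config$seed)
  fs_table <- halves$train
  if (!is.null(config$fsds_per_group))
    fs_table <- nested_subsets(halves$train, config$fsds_per_group,
                               seed = config$seed)[[1]]

  fit <- nbbd(fs_table, net_method = config$net_method,
              scoring = config$scoring, property = config$property,
              measure = config$measure, k = config$k, seed = config$seed)
  for (i in seq_along(fit$networks))
    paths[[paste0("network_", names(fit$networks)[i])]] <-
      write_edge_list(fit$networks[[i]],
                      file.path(config$out_dir,
                                sprintf("network_%s.tsv", names(fit$networks)[i])))
  if (!is.null(fit$scores)) {
    s <- scores(fit)
    utils::write.table(
      data.frame(taxon_id = names(s), score = s),
      paths$scores <- file.path(config$out_dir, "scores.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(fit$selected,
             paths$selected <- file.path(config$out_dir, "selected_taxa.txt"))

  if (!length(fit$selected)) {
    report <- NULL
    status <- "empty_feature_set"
  } else {
    model <- train_rf(halves$train, fit$selected, n_trees = config$n_trees,
                      seed = config$seed)
    report <- evaluate_model(model, halves$test)
    status <- "ok"
    utils::write.table(
      data.frame(n_features = report$n_features, acc = report$acc,
                 sn = report$sn, sp = report$sp, mcc = report$mcc,
                 auc = report$auc),
      paths$report <- file.path(config$out_dir, "report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(config = config[order(names(config))], status = status,
                   selected = fit$selected,
                   package_version = as.character(utils::packageVersion("nbbd")))
  jsonlite::write_json(manifest,
                       paths$manifest <- file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fit = fit, report = report, paths = paths, status = status))
}

#' Class-balanced train/test split
#'
#' @param table a labeled [OTUTable].
#' @param test_fraction fraction of each group held out for testing.
#' @param seed integer seed.
#' @return list with `train` and `test` [OTUTable]s.
#' @export
train_test_split <- function(table, test_fraction = 0.5, seed = 1L) {
  groups <- split_by_phenotype(table)
  test_ids <- with_seed(seed, unlist(lapply(groups, function(g) {
    ids <- sample_ids(g)
    sample(ids, max(1L, round(test_fraction * length(ids))))
  }), use.names = FALSE))
  all_ids <- sample_ids(table)
  list(train = subset_otu(table, samples = setdiff(all_ids, test_ids)),
       test = subset_otu(table, samples = all_ids[all_ids %in% test_ids]))
}
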