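#' OTU abundance table
#'
#' Lightweight samples-by-taxa container used throughout the package. Rows
#' are samples, columns are taxa (OTUs); values are non-negative counts or
#' relative abundances. An optional per-sample binary phenotype label (e.g.
#' disease vs. healthy) rides along with the matrix.
#'
#' @param values numeric matrix, samples in rows and taxa in columns, with
#'   unique non-empty rownames (sample IDs) and colnames (taxon IDs).
#' @param labels optional character/factor vector of per-sample phenotype
#'   labels, length `nrow(values)`, or a named vector matching sample IDs.
#' @param normalized logical; `TRUE` when every row sums to 1 (relative
#'   abundances) rather than raw counts.
#'
#' @return An object of class `"OTUTable"`: a list with elements `values`,
#'   `labels` (possibly `NULL`) and `normalized`.
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("g__A", "g__B")))
#' tab <- OTUTable(m, labels = c("IBD", "Healthy", "IBD"))
#' tab
OTUTable <- function(values, labels = NULL, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample IDs as rownames and taxon IDs as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ID: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ID: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundances must be finite and non-negative")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (!is.null(names(labels))) {
      if (!all(rownames(values) %in% names(labels)))
        stop("labels are named but do not cover all sample IDs")
      labels <- labels[rownames(values)]
    } else if (length(labels) != nrow(values)) {
      stop("`labels` must have one entry per sample")
    }
    names(labels) <- rownames(values)
  }
  if (normalized) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9))
      stop("normalized table has a row not summing to 1: ",
           rownames(values)[which.max(abs(rs - 1))])
  }
  structure(list(values = values, labels = labels, normalized = normalized),
            class = "OTUTable")
}

#' @export
#' @method print OTUTable
print.OTUTable <- function(x, ...) {
  cat(sprintf("OTUTable: %d samples x %d taxa (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "relative abundances" else "counts/raw"))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("labels: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method dim OTUTable
dim.OTUTable <- function(x) dim(x$values)

sample_ids <- function(table) rownames(table$values)
taxon_ids <- function(table) colnames(table$values)

## Subset an OTUTable by sample IDs and/or taxon IDs (internal helper).
subset_otu <- function(table, samples = NULL, taxa = NULL) {
  v <- table$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(taxa)) v <- v[, taxa, drop = FALSE]
  lab <- if (is.null(table$labels)) NULL else table$labels[rownames(v)]
  OTUTable(v, labels = lab, normalized = table$normalized)
}

#' Read an OTU table from delimited text
#'
#' Reads a TSV/CSV abundance table. In `samples_as_rows` orientation the
#' first column holds sample IDs and the header row holds taxon IDs;
#' `taxa_as_rows` is the transpose. The returned table is always in
#' samples-as-rows orientation.
#'
#' @param path path to a TSV (default) or CSV file; `sep` is inferred from
#'   the file extension unless given.
#' @param orientation `"samples_as_rows"` (default) or `"taxa_as_rows"`.
#' @param sep field separator; `NULL` means infer (`","` for `.csv`,
#'   otherwise tab).
#' @return An [OTUTable] (without labels; see [read_metadata()]).
#' @export
read_otu_table <- function(path, orientation = c("samples_as_rows", "taxa_as_rows"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  # parse the header ourselves: read.table silently uniquifies duplicate
  # column names, which must instead be a validation error
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("duplicate taxon ID in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  df <- utils::read.table(path, header = FALSE, skip = 1L, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) != length(header) + 1L)
    stop("header and data rows disagree on the number of columns")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  colnames(body) <- header
  m <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
              dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    x <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(x) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1]], colnames(body)[j], body[[j]][bad[1]]))
    m[, j] <- x
  }
  if (orientation == "taxa_as_rows") m <- t(m)
  OTUTable(m)
}

#' Write an OTU table to delimited text
#'
#' Inverse of [read_otu_table()] (samples-as-rows orientation, first column
#' `sample_id`).
#'
#' @param table an [OTUTable].
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_otu_table <- function(table, path, sep = "\t") {
  df <- data.frame(sample_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table and attach phenotype labels
#'
#' @param table an [OTUTable].
#' @param path metadata TSV/CSV with (at least) a sample-ID column and a
#'   label column.
#' @param sample_col,label_col column names in the metadata file.
#' @param sep separator; inferred from extension when `NULL`.
#' @return The table with `labels` attached.
#' @export
read_metadata <- function(table, path, sample_col = "sample_id",
                          label_col = "label", sep = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  md <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c(sample_col, label_col) %in% colnames(md)))
    stop("metadata must contain columns '", sample_col, "' and '", label_col, "'")
  lab <- stats::setNames(as.character(md[[label_col]]), md[[sample_col]])
  missing <- setdiff(sample_ids(table), names(lab))
  if (length(missing))
    stop("metadata lacks labels for samples: ", paste(utils::head(missing, 3), collapse = ", "))
  OTUTable(table$values, labels = lab[sample_ids(table)], normalized = table$normalized)
}

#' Optional BIOM reader
#'
#' Reads a (JSON or HDF5) BIOM file through the `biomformat` package and
#' returns the same samples-as-rows [OTUTable] as [read_otu_table()].
#'
#' @param path path to a BIOM file.
#' @return An [OTUTable].
#' @export
read_otu_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("read_otu_biom() requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")  # taxa x samples in BIOM
  OTUTable(t(m))
}

#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one. Every row must
#' have a positive total.
#'
#' @param table an [OTUTable].
#' @return A normalized [OTUTable].
#' @export
to_relative_abundance <- function(table) {
  rs <- rowSums(table$values)
  if (any(rs <= 0))
    stop("sample has all-zero abundance: ",
         rownames(table$values)[which(rs <= 0)[1]])
  OTUTable(table$values / rs, labels = table$labels, normalized = TRUE)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa with strictly positive abundance in at least
#' `ceiling(min_fraction * n_samples)` samples; the sample set is unchanged.
#'
#' @param table an [OTUTable].
#' @param min_fraction required prevalence in `(0, 1]` (default 0.25, the
#'   conventional cut for building correlation networks from genus tables).
#' @return The filtered [OTUTable].
#' @export
prevalence_filter <- function(table, min_fraction = 0.25) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * nrow(table$values))
  keep <- colSums(table$values > 0) >= need
  if (!any(keep)) stop("prevalence filter removed every taxon")
  subset_otu(table, taxa = colnames(table$values)[keep])
}

#' Split a labeled table into its two phenotype groups
#'
#' @param table an [OTUTable] with exactly two distinct labels.
#' @return A named list of two [OTUTable]s (names = sorted label values),
#'   partitioning the samples; the taxon set is unchanged in both.
#' @export
split_by_phenotype <- function(table) {
  if (is.null(table$labels)) stop("table has no phenotype labels")
  lev <- sort(unique(table$labels))
  if (length(lev) != 2)
    stop("expected exactly 2 label values, found ", length(lev), ": ",
         paste(lev, collapse = ", "))
  out <- lapply(lev, function(l)
    subset_otu(table, samples = names(table$labels)[table$labels == l]))
  stats::setNames(out, lev)
}

#' Draw nested, class-balanced feature-selection subsets
#'
#' Emulates a chain of nested feature-selection data sets: each subset has
#' `n` samples per phenotype group and every sample of a smaller subset is
#' contained in all larger ones. Nesting is guaranteed by taking prefixes of
#' one seeded shuffle per class.
#'
#' @param table a labeled [OTUTable] with two phenotype groups.
#' @param sizes strictly increasing vector of per-group sample counts.
#' @param seed integer seed; the same seed reproduces the same chain.
#' @return A list of [OTUTable]s, one per size, each with `2 * size` samples.
#' @export
nested_subsets <- function(table, sizes, seed = 1L) {
  if (is.unsorted(sizes, strictly = TRUE))
    stop("`sizes` must be strictly increasing")
  groups <- split_by_phenotype(table)
  n_min <- min(vapply(groups, function(g) nrow(g$values), 0L))
  if (max(sizes) > n_min)
    stop("largest size ", max(sizes), " infeasible: smallest group has ",
         n_min, " samples")
  shuffles <- with_seed(seed, lapply(groups, function(g)
    sample(sample_ids(g))))
  lapply(sizes, function(n) {
    keep <- unlist(lapply(shuffles, function(s) s[seq_len(n)]), use.names = FALSE)
    # preserve the parent table's sample order for determinism
    subset_otu(table, samples = sample_ids(table)[sample_ids(table) %in% keep])
  })
}

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}
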