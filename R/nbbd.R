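#' Fit the network-based biomarker selector
#'
#' The core estimator of the package: splits a labeled OTU table by
#' phenotype, infers one microbial ecology network per group, scores the
#' shared taxa by differential node topology (NTPS), by shared critical
#' attack sets (CASS), or by the hybrid product of random-forest
#' importance and NTPS, and ranks the taxa as candidate biomarkers.
#'
#' @param table a labeled [OTUTable] with two phenotype groups.
#' @param net_method network constructor: `"proxi"` (default), `"sparcc"`,
#'   `"mb"` or `"rmt"`.
#' @param scoring `"ntps"` (default), `"cass"` or `"hybrid"`.
#' @param property NTPS node property (default `"btw"`); see
#'   [compute_property()].
#' @param measure CASS resilience measure (default `"integrity"`).
#' @param k number of top taxa to report (ignored by `"cass"`, whose
#'   attack-set intersection fixes its own feature count).
#' @param seed integer seed (random-forest importance in hybrid scoring).
#' @param ... further arguments passed to the network constructor.
#' @return object of class `"nbbd"` with elements `networks` (named list
#'   of two igraphs), `scores` (named numeric vector, or `NULL` for CASS),
#'   `selected` (character vector of chosen taxa), `method` descriptors
#'   and `call`.
#' @export
#' @examples
#' bench <- make_benchmark(n_taxa = 40, n_planted = 5, n_per_group = 30,
#'                         seed = 1)
#' fit <- nbbd(bench$table, net_method = "proxi", scoring = "ntps",
#'             property = "btw", k = 5)
#' print(fit)
#' head(scores(fit))
nbbd <- function(table, net_method = c("proxi", "sparcc", "mb", "rmt"),
                 scoring = c("ntps", "cass", "hybrid"),
                 property = "btw", measure = "integrity", k = 10L,
                 seed = 1L, ...) {
  net_method <- match.arg(net_method)
  scoring <- match.arg(scoring)
  nets <- phenotype_networks(table, net_method, ...)
  if (scoring == "cass") {
    sel <- cass_select(nets[[1]], nets[[2]], measure)
    sc <- NULL
    selected <- as.character(sel)
  } else {
    sc <- ntps_score(nets[[1]], nets[[2]], property)
    if (scoring == "hybrid")
      sc <- hybrid_score(rffi(table, seed = seed), sc)
    selected <- select_top_k(sc, min(k, length(sc)))
  }
  structure(list(networks = nets, scores = sc, selected = selected,
                 method = list(net_method = net_method, scoring = scoring,
                               property = property, measure = measure,
                               k = k, seed = seed),
                 n_taxa = ncol(table$values), call = match.call()),
            class = "nbbd")
}

#' Extract taxon scores from an nbbd fit
#'
#' @param x an `"nbbd"` object.
#' @param ... unused.
#' @return named numeric vector sorted by decreasing score (`NULL` for
#'   CASS fits, which select a set rather than a ranking).
#' @export
scores <- function(x, ...) UseMethod("scores")

#' @rdname scores
#' @export
#' @method scores nbbd
scores.nbbd <- function(x, ...) {
  if (is.null(x$scores)) return(NULL)
  x$scores[order(-x$scores, names(x$scores))]
}

#' @export
#' @method print nbbd
print.nbbd <- function(x, ...) {
  m <- x$method
  cat(sprintf("nbbd fit: %s networks, %s scoring%s\n", m$net_method,
              m$scoring,
              if (m$scoring == "cass") sprintf(" (%s)", m$measure)
              else sprintf(" (%s)", m$property)))
  cat(sprintf("  %d taxa scored from two networks of %d and %d edges\n",
              x$n_taxa, igraph::ecount(x$networks[[1]]),
              igraph::ecount(x$networks[[2]])))
  cat(sprintf("  selected %d taxa: %s%s\n", length(x$selected),
              paste(utils::head(x$selected, 5), collapse = ", "),
              if (length(x$selected) > 5) ", ..." else ""))
  invisible(x)
}

#' @export
#' @method summary nbbd
summary.nbbd <- function(object, n = 10L, ...) {
  print(object)
  if (!is.null(object$scores)) {
    cat("\ntop scores:\n")
    print(utils::head(scores(object), n))
  }
  invisible(object)
}

#' Plot an nbbd fit
#'
#' Barplot of the top-scoring taxa (selected taxa highlighted), or the two
#' phenotype networks side by side with `which = "networks"`.
#'
#' @param x an `"nbbd"` object.
#' @param which `"scores"` (default) or `"networks"`.
#' @param n number of taxa shown in the score barplot.
#' @param ... further arguments passed to the underlying plot.
#' @export
#' @method plot nbbd
plot.nbbd <- function(x, which = c("scores", "networks"), n = 20L, ...) {
  which <- match.arg(which)
  if (which == "scores") {
    if (is.null(x$scores)) stop("CASS fits have no score ranking to plot")
    s <- utils::head(scores(x), n)
    op <- graphics::par(mar = c(9, 4, 2, 1)); on.exit(graphics::par(op))
    cols <- ifelse(names(s) %in% x$selected, "steelblue", "grey70")
    graphics::barplot(s, las = 2, col = cols,
                      ylab = sprintf("%s score (%s)", x$method$scoring,
                                     x$method$property), ...)
  } else {
    op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
    for (nm in names(x$networks)) {
      g <- x$networks[[nm]]
      igraph::plot.igraph(g, vertex.size = 4, vertex.label = NA,
                          main = nm, ...)
    }
  }
  invisible(x)
}
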