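## CASS: node-based resilience measures (vertex attack tolerance,
## integrity, tenacity), the Greedy-BC attack-set heuristic, an exhaustive
## oracle for small graphs, and shared-attack-set feature selection.

RESILIENCE_MEASURES <- c("VAT", "integrity", "tenacity")

#' Greedy betweenness-centrality removal ordering
#'
#' Repeatedly removes the node with maximal betweenness centrality in the
#' current residual graph (recomputed after every removal; when removals
#' disconnect the residual graph, betweenness is computed over the whole
#' residual graph, per component). Ties are broken lexicographically by
#' node ID. If the input graph is disconnected its largest connected
#' component is used, with a warning.
#'
#' @param g undirected igraph with named vertices.
#' @return character vector: the full node-removal sequence.
#' @export
greedy_bc_ordering <- function(g) {
  if (igraph::vcount(g) == 0) stop("graph is empty")
  g <- strip_weights(g)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph is disconnected; using its largest component (",
            max(comp$csize), " of ", igraph::vcount(g), " nodes)")
    keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    g <- igraph::induced_subgraph(g, keep)
  }
  ordering <- character(0)
  res <- g
  while (igraph::vcount(res) > 0) {
    b <- igraph::betweenness(res, directed = FALSE, normalized = FALSE)
    nm <- igraph::V(res)$name
    pick <- nm[order(-b, nm)][1]
    ordering <- c(ordering, pick)
    res <- igraph::delete_vertices(res, pick)
  }
  ordering
}

#' Evaluate a resilience measure at one attack set
#'
#' For an attack set `S` of graph `G = (V, E)` with `Cmax` the order of the
#' largest connected component of `V - S` and `omega` the number of
#' components of `V - S`:
#' \describe{
#'   \item{VAT}{`|S| / (|V - S| - Cmax + 1)` (requires `S` non-empty).}
#'   \item{integrity}{`|S| + Cmax`.}
#'   \item{tenacity}{`(|S| + Cmax) / omega`.}
#' }
#' When `S = V`, `Cmax = 0` and `omega` is treated as 1.
#'
#' @param g undirected igraph with named vertices.
#' @param s character vector of attack-set node IDs (subset of `V`).
#' @param measure `"VAT"`, `"integrity"` or `"tenacity"`.
#' @return the measure value.
#' @export
measure_value <- function(g, s, measure = RESILIENCE_MEASURES) {
  measure <- match.arg(measure)
  ids <- igraph::V(g)$name
  if (!all(s %in% ids)) stop("attack set contains nodes not in the graph: ",
                             paste(setdiff(s, ids), collapse = ", "))
  if (measure == "VAT" && length(s) == 0) stop("VAT requires a non-empty attack set")
  rest <- setdiff(ids, s)
  if (length(rest) == 0) {
    cmax <- 0; omega <- 1
  } else {
    comp <- igraph::components(igraph::induced_subgraph(g, rest))
    cmax <- max(comp$csize); omega <- comp$no
  }
  switch(measure,
         VAT = length(s) / (length(rest) - cmax + 1),
         integrity = length(s) + cmax,
         tenacity = (length(s) + cmax) / omega)
}

#' Minimize a resilience measure along the Greedy-BC ordering
#'
#' Computes the Greedy-BC removal ordering once and evaluates the measure
#' at every non-empty prefix (sizes 1 to `|V| - 1`; the empty set, although
#' [measure_value()] accepts it for integrity and tenacity, is not a
#' candidate attack set — admitting it would let dense graphs return an
#' empty integrity attack set and break the nesting relation below). The
#' minimizing prefix is the critical attack set; on ties the smallest
#' prefix wins. Because all three measures share the ordering, their attack
#' sets are nested: `S_VAT` within `S_integrity` within `S_tenacity`.
#'
#' @param g undirected igraph with at least 2 nodes.
#' @param measure `"VAT"`, `"integrity"` or `"tenacity"`.
#' @param ordering optional precomputed removal ordering (so the three
#'   measures can share one Greedy-BC pass).
#' @return object of class `"attack_set_result"`: list with `measure`,
#'   `attack_set`, `value`, `ordering`, `profile` (value at each evaluated
#'   prefix, named by prefix size).
#' @export
optimize_measure <- function(g, measure = RESILIENCE_MEASURES, ordering = NULL) {
  measure <- match.arg(measure)
  if (igraph::vcount(g) < 2) stop("graph must have at least 2 nodes")
  if (is.null(ordering)) ordering <- greedy_bc_ordering(g)
  g_used <- if (length(ordering) < igraph::vcount(g))
    igraph::induced_subgraph(g, ordering) else g
  sizes <- seq_len(length(ordering) - 1)
  profile <- vapply(sizes, function(k)
    measure_value(g_used, ordering[seq_len(k)], measure), 0)
  names(profile) <- sizes
  best <- which.min(profile)  # first minimum = smallest prefix on ties
  structure(list(measure = measure,
                 attack_set = ordering[seq_len(sizes[best])],
                 value = unname(profile[best]),
                 ordering = ordering,
                 profile = profile),
            class = "attack_set_result")
}

#' @export
#' @method print attack_set_result
print.attack_set_result <- function(x, ...) {
  cat(sprintf("%s attack set: %d node(s), value %.4g\n",
              x$measure, length(x$attack_set), x$value))
  if (length(x$attack_set))
    cat("  {", paste(x$attack_set, collapse = ", "), "}\n")
  invisible(x)
}

#' Exhaustive minimum of a resilience measure (test oracle)
#'
#' Enumerates every admissible attack set (all non-empty proper subsets of
#' `V`; the empty set can never be strictly optimal since
#' `|S| + Cmax(V - S) <= |V|` for every `S`) and returns the true minimum. Intended as an
#' oracle for small graphs; refuses graphs with more than 16 nodes. Ties
#' are broken by smaller set size, then lexicographically.
#'
#' @param g undirected igraph with named vertices, at most 16 nodes.
#' @param measure `"VAT"`, `"integrity"` or `"tenacity"`.
#' @return list with `value` and `optimal_set`.
#' @export
brute_force_measure <- function(g, measure = RESILIENCE_MEASURES) {
  measure <- match.arg(measure)
  ids <- sort(igraph::V(g)$name)
  n <- length(ids)
  if (n > 16) stop("brute force limited to 16 nodes (got ", n, ")")
  best_val <- Inf; best_set <- NULL
  for (k in seq_len(n - 1)) {
    sets <- utils::combn(ids, k, simplify = FALSE)
    for (s in sets) {
      v <- measure_value(g, s, measure)
      if (v < best_val - 1e-12) {
        best_val <- v; best_set <- s
      }
      # equal value: keep the earlier (smaller, then lexicographic) set;
      # combn enumerates lexicographically within a size, sizes ascend.
    }
  }
  list(value = best_val, optimal_set = best_set)
}

#' Shared critical-attack-set feature selection (CASS)
#'
#' Optimizes the chosen resilience measure on each phenotype network via
#' Greedy-BC and returns the intersection of the two critical attack sets.
#' An empty intersection is a valid (warned-about) outcome.
#'
#' @param g_a,g_b undirected igraphs (the two phenotype networks).
#' @param measure `"VAT"`, `"integrity"` or `"tenacity"`.
#' @return character vector of selected taxon IDs (possibly empty), with
#'   the two `attack_set_result`s attached as attributes `result_a`,
#'   `result_b`.
#' @export
cass_select <- function(g_a, g_b, measure = RESILIENCE_MEASURES) {
  measure <- match.arg(measure)
  r_a <- optimize_measure(g_a, measure)
  r_b <- optimize_measure(g_b, measure)
  sel <- sort(intersect(r_a$attack_set, r_b$attack_set))
  if (!length(sel))
    warning("critical attack sets share no nodes (", measure,
            "); empty feature set")
  structure(sel, result_a = r_a, result_b = r_b)
}
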