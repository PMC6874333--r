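## NTPS: score each taxon by the absolute difference of one of six node
## topological properties between the two phenotype networks.

NODE_PROPERTIES <- c("btw", "cls", "and", "cc", "ncn", "cn")

#' Node topological properties
#'
#' Computes one of six per-node properties of an undirected graph:
#' \describe{
#'   \item{btw}{betweenness centrality, the unnormalized sum over unordered
#'     vertex pairs of the fraction of shortest paths through the node.}
#'   \item{cls}{closeness centrality, `(n - 1) / sum(d(u, v))` where `n`
#'     counts the nodes that can reach `v` (isolated nodes score 0).}
#'   \item{and}{average neighbour degree (isolated nodes score 0).}
#'   \item{cc}{local clustering coefficient
#'     `2 T(v) / (deg(v) (deg(v) - 1))`; 0 for degree below 2.}
#'   \item{ncn}{node clique number: size of the largest maximal clique
#'     containing the node.}
#'   \item{cn}{core number: largest `k` of a `k`-core containing the node.}
#' }
#' Edge weights are ignored throughout.
#'
#' @param g undirected igraph with named vertices.
#' @param property_name one of `"btw"`, `"cls"`, `"and"`, `"cc"`, `"ncn"`,
#'   `"cn"`.
#' @return named numeric vector over all vertices of `g`.
#' @export
compute_property <- function(g, property_name) {
  if (igraph::vcount(g) == 0) stop("graph is empty")
  if (!property_name %in% NODE_PROPERTIES)
    stop("unknown property '", property_name, "'; expected one of ",
         paste(NODE_PROPERTIES, collapse = ", "))
  gu <- strip_weights(g)
  ids <- igraph::V(gu)$name
  out <- switch(property_name,
    btw = igraph::betweenness(gu, directed = FALSE, normalized = FALSE),
    cls = closeness_reachable(gu),
    and = {
      k <- igraph::knn(gu)$knn
      k[is.nan(k) | is.na(k)] <- 0
      k
    },
    cc = igraph::transitivity(gu, type = "localundirected", isolates = "zero",
                              vids = igraph::V(gu)),
    ncn = node_clique_number(gu),
    cn = igraph::coreness(gu))
  out <- as.numeric(out)
  names(out) <- ids
  out
}

strip_weights <- function(g) {
  if ("weight" %in% igraph::edge_attr_names(g))
    igraph::delete_edge_attr(g, "weight") else g
}

## Reachable-set closeness: (#nodes reaching v) / (sum of their distances),
## counting v itself in n so the numerator is n - 1; isolated vertices -> 0.
closeness_reachable <- function(g) {
  d <- igraph::distances(g)
  apply(d, 2, function(col) {
    finite <- is.finite(col) & col > 0
    if (!any(finite)) 0 else sum(finite) / sum(col[finite])
  })
}

node_clique_number <- function(g) {
  cl <- igraph::max_cliques(g)
  out <- stats::setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  for (c in cl) {
    sz <- length(c)
    nm <- igraph::V(g)$name[as.integer(c)]
    out[nm] <- pmax(out[nm], sz)
  }
  out
}

#' Differential node topology score (NTPS)
#'
#' Scores every node shared by the two phenotype networks as the absolute
#' difference of a topological property between them:
#' `score(v) = |f_P(v, G_a) - f_P(v, G_b)|`. Nodes present in only one
#' graph receive no score.
#'
#' @param g_a,g_b undirected igraphs with named vertices (non-empty
#'   intersection).
#' @param property_name see [compute_property()].
#' @return named numeric vector of non-negative scores over the shared
#'   vertex set, sorted by vertex name.
#' @export
ntps_score <- function(g_a, g_b, property_name) {
  shared <- sort(intersect(igraph::V(g_a)$name, igraph::V(g_b)$name))
  if (!length(shared))
    stop("graphs share no nodes (", igraph::vcount(g_a), " vs ",
         igraph::vcount(g_b), " vertices)")
  f_a <- compute_property(g_a, property_name)[shared]
  f_b <- compute_property(g_b, property_name)[shared]
  abs(f_a - f_b)
}
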