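#' Path-length neighborhood of a gene set
#'
#' All network nodes within shortest-path distance `k` of any seed gene,
#' including the seed genes present in the network (distance 0). Distance
#' is measured on the undirected skeleton (`mode = "undirected"`), along
#' edges (`"downstream"`) or against edges (`"upstream"`). Seed genes
#' absent from the network are reported via the `"missing"` attribute, not
#' treated as errors.
#'
#' @param net a [gene_network].
#' @param seed character vector of seed gene ids.
#' @param k maximum path length (>= 1).
#' @param mode `"undirected"`, `"downstream"` or `"upstream"`.
#' @return character vector of gene ids (sorted); attribute `"missing"`
#'   lists seed genes absent from the network.
#' @export
neighborhood <- function(net, seed, k,
                         mode = c("undirected", "downstream", "upstream")) {
  stopifnot_network(net)
  mode <- match.arg(mode)
  if (k < 1) stop("k must be >= 1")
  seed <- unique(as.character(seed))
  present <- intersect(seed, net$nodes)
  missing <- setdiff(seed, net$nodes)
  if (length(present) == 0L)
    stop("no seed genes present in the network; check gene identifiers")
  d <- igraph::distances(net$graph, v = present, mode = .mode_of(mode),
                         weights = NA) # hop count, not edge weight
  reach <- colnames(d)[apply(d, 2, min) <= k]
  structure(sort(unique(c(present, reach))), missing = missing)
}

#' Induced subgraph restricted to its largest weakly connected component
#'
#' Induces the subgraph of `net` on `nodes`, takes weakly connected
#' components and returns the largest; ties are broken deterministically
#' toward the component containing the lexicographically smallest node id.
#'
#' @param net a [gene_network].
#' @param nodes character vector of node ids, all present in `net`.
#' @param provenance optional list recording how `nodes` was derived.
#' @return an object of class `subnetwork`: list with `nodes`, `edges`
#'   (induced edge data.frame), `network` (a [gene_network] of the
#'   component) and `provenance`.
#' @export
largest_connected <- function(net, nodes, provenance = list()) {
  stopifnot_network(net)
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0L) stop("empty node set")
  if (!all(nodes %in% net$nodes))
    stop("nodes not in network: ",
         paste(utils::head(setdiff(nodes, net$nodes), 5), collapse = ", "))
  sub <- igraph::induced_subgraph(net$graph, nodes)
  comp <- igraph::components(sub, mode = "weak")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie: pick the component holding the smallest node id
    first_node <- vapply(best, function(ci)
      min(igraph::V(sub)$name[comp$membership == ci]), character(1))
    best <- best[order(first_node)][1L]
  }
  keep <- igraph::V(sub)$name[comp$membership == best]
  e <- net$edges[net$edges$parent %in% keep & net$edges$child %in% keep, ,
                 drop = FALSE]
  structure(list(nodes = sort(keep),
                 edges = e,
                 network = gene_network(e, nodes = keep),
                 provenance = provenance),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork:", length(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (length(x$provenance))
    cat(" (seed=", x$provenance$seed %||% "?",
        ", k=", x$provenance$k %||% "?",
        ", mode=", x$provenance$mode %||% "?", ")", sep = "")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project a seed gene set onto a directed network
#'
#' The network-instantiation step: intersect the seed set with the network
#' nodes, expand to all nodes within path length `k` of that overlap
#' (undirected), and keep the largest connected subgraph with all induced
#' edges. `k = 2` is the default whole-tissue setting; `k = 3` suits
#' smaller cell-type-specific seed signatures.
#'
#' @param net a [gene_network].
#' @param seed a [gene_set] (or character vector).
#' @param k path length bound (>= 1).
#' @return a `subnetwork` with provenance recorded.
#' @export
project_seed <- function(net, seed, k = 2) {
  stopifnot_network(net)
  genes <- if (inherits(seed, "gene_set")) seed$genes else as.character(seed)
  seed_name <- if (inherits(seed, "gene_set")) seed$name else "seed"
  overlap <- intersect(genes, net$nodes)
  if (length(overlap) == 0L)
    stop("seed set '", seed_name,
         "' shares no genes with the network; check gene identifiers")
  nb <- neighborhood(net, overlap, k, mode = "undirected")
  largest_connected(net, nb,
                    provenance = list(seed = seed_name, k = k,
                                      mode = "undirected"))
}

#' Subnetwork around a set of key driver genes
#'
#' Identical construction to [project_seed()] but seeded on key drivers:
#' drivers plus all genes within path length `k`, restricted to the
#' largest connected component. `k = 3` annotates driver-centered local
#' structure; `k = 2` is the validation window.
#'
#' @param net a [gene_network].
#' @param kdgs character vector of driver gene ids.
#' @param k path length bound.
#' @return a `subnetwork`.
#' @export
kdg_subnetwork <- function(net, kdgs, k = 3) {
  project_seed(net, gene_set("kdg_set", kdgs), k)
}
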