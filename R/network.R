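#' Directed gene network
#'
#' Container for a directed causal gene network: nodes are opaque,
#' case-sensitive gene identifiers; edges are parent -> child causal
#' relations with an optional real weight. Self-loops are rejected and
#' duplicate edges are collapsed (with a warning), so a valid network
#' always has a simple edge set whose endpoints are all registered nodes.
#'
#' @param edges data.frame with columns `parent`, `child` and optionally
#'   `weight`; one row per directed edge.
#' @param nodes optional character vector of node ids; defaults to the ids
#'   appearing in `edges`. Extra ids give isolated nodes.
#' @return An object of class `gene_network` with elements `nodes` (character),
#'   `edges` (data.frame `parent`, `child`, `weight`) and `graph` (the igraph
#'   representation used internally).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (!all(c("parent", "child") %in% names(edges)))
    stop("`edges` must have columns 'parent' and 'child'")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (is.null(edges$weight)) edges$weight <- rep(NA_real_, nrow(edges))
  loops <- edges$parent == edges$child
  if (any(loops))
    stop("self-loop edge(s) not allowed: ",
         paste(unique(edges$parent[loops]), collapse = ", "))
  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) collapsed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, edges$parent, edges$child)))
  if (length(nodes) == 0L) stop("network must contain at least one node")
  g <- igraph::graph_from_data_frame(
    edges[, c("parent", "child", "weight")], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  structure(list(nodes = nodes,
                 edges = edges[, c("parent", "child", "weight")],
                 graph = g),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Directed gene network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

is_gene_network <- function(x) inherits(x, "gene_network")

stopifnot_network <- function(net) {
  if (!is_gene_network(net)) stop("expected a `gene_network` object")
  invisible(net)
}

# igraph mode string for a direction keyword
.mode_of <- function(direction) {
  switch(direction,
         undirected = "all",
         downstream = "out",
         upstream = "in",
         stop("unknown direction: ", direction))
}

#' In-degrees of network nodes
#'
#' @param net a `gene_network`.
#' @return named integer vector of in-degrees over all nodes.
#' @keywords internal
network_indegree <- function(net) {
  stopifnot_network(net)
  d <- igraph::degree(net$graph, mode = "in")
  d[net$nodes]
}
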