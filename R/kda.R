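#' Key driver analysis configuration
#'
#' @param h_max upper bound H of the layer search grid h = 1..H.
#' @param alpha significance level applied to adjusted p-values.
#' @param correction multiple-testing correction across candidates within
#'   one analysis: `"bonferroni"` (default) or `"BH"`.
#' @param direction layer direction for the candidate neighborhoods:
#'   `"downstream"` (default; regulatory control flows along edges) or
#'   `"undirected"`.
#' @param expand_k layers used to expand the input gene set into the
#'   candidate pool NG (0 = the overlap itself).
#' @param statistic enrichment statistic maximized over the layer grid:
#'   `"significance"` (default; -log hypergeometric tail p, so the
#'   optimal layer is the most significant one) or `"fold"` (raw fold
#'   enrichment; small layers with noisy high folds can then win).
#' @return list of class `kda_config`.
#' @export
kda_config <- function(h_max = 3, alpha = 0.05,
                       correction = c("bonferroni", "BH"),
                       direction = c("downstream", "undirected"),
                       expand_k = 1,
                       statistic = c("significance", "fold")) {
  if (h_max < 1) stop("h_max must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (expand_k < 0) stop("expand_k must be >= 0")
  structure(list(h_max = as.integer(h_max), alpha = alpha,
                 correction = match.arg(correction),
                 direction = match.arg(direction),
                 expand_k = as.integer(expand_k),
                 statistic = match.arg(statistic)),
            class = "kda_config")
}

#' Candidate pool NG around an input gene set
#'
#' NG is the set of network nodes no more than `expand_k` (undirected)
#' layers away from the input genes; with `expand_k = 0` it is the
#' set-network overlap itself.
#'
#' @param net a [gene_network].
#' @param g_set character vector of input gene ids.
#' @param expand_k non-negative layer count.
#' @return sorted character vector of candidate gene ids.
#' @export
build_ng <- function(net, g_set, expand_k = 1) {
  stopifnot_network(net)
  overlap <- intersect(unique(as.character(g_set)), net$nodes)
  if (length(overlap) == 0L)
    stop("input gene set shares no genes with the network")
  if (expand_k == 0) return(sort(overlap))
  as.character(neighborhood(net, overlap, expand_k, mode = "undirected"))
}

#' h-layer neighborhood of a single gene
#'
#' Nodes at (directed or undirected) shortest-path distance 1..h from `g`,
#' excluding `g` itself (excluding the candidate prevents self-counting
#' from inflating its own enrichment).
#'
#' @param net a [gene_network].
#' @param g gene id present in the network.
#' @param h layer bound (>= 1).
#' @param direction `"downstream"` or `"undirected"`.
#' @return character vector of gene ids.
#' @export
hln <- function(net, g, h, direction = c("downstream", "undirected")) {
  stopifnot_network(net)
  direction <- match.arg(direction)
  if (!g %in% net$nodes) stop("unknown gene: ", g)
  if (h < 1) stop("h must be >= 1")
  d <- igraph::distances(net$graph, v = g, mode = .mode_of(direction),
                         weights = NA)[1, ]
  sort(names(d)[d >= 1 & d <= h])
}

#' Key driver analysis on a directed gene network
#'
#' Identifies candidate master regulators (key driver genes) of an input
#' gene set G on a directed network N. Candidates are the nodes of the pool
#' NG ([build_ng()]). For each candidate g and each layer h = 1..H the
#' h-layer neighborhood HLN(g, h) ([hln()]) is scored by its overlap
#' enrichment for G against the full network's node universe; the optimal
#' layer h* maximizes the configured enrichment statistic over the h grid
#' (ties go to the smaller h; by default the statistic is the significance
#' of the one-sided hypergeometric overlap, see [kda_config()]), and the
#' candidate's p-value and fold enrichment are reported at h*, so either
#' convention can be compared. P-values are corrected across candidates and
#' significant candidates are classified as **global** drivers when they
#' have no parent node in the full network (root nodes) and **local**
#' drivers otherwise; non-significant candidates are classed `"none"`.
#'
#' @param net a [gene_network].
#' @param g_set a [gene_set] or character vector: the gene set whose
#'   regulators are sought (it is intersected with the network nodes).
#' @param config a [kda_config()].
#' @return An object of class `kda`: list with `results` (data.frame with
#'   columns `gene`, `h_star`, `es`, `p`, `p_adjusted`,
#'   `neighborhood_size`, `overlap`, `driver_class`, sorted by
#'   (`p_adjusted`, -`es`, `gene`)), `config`, `g_size` (genes of G in the
#'   network), `universe_size`, and `drivers` (significant driver ids).
#'   Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' edges <- data.frame(parent = "R", child = paste0("m", 1:10))
#' net <- gene_network(edges)
#' fit <- kda(net, paste0("m", 1:8), kda_config(h_max = 2))
#' fit
#' @export
kda <- function(net, g_set, config = kda_config()) {
  stopifnot_network(net)
  stopifnot(inherits(config, "kda_config"))
  genes <- if (inherits(g_set, "gene_set")) g_set$genes else as.character(g_set)
  G <- intersect(unique(genes), net$nodes)
  if (length(G) == 0L) stop("input gene set shares no genes with the network")
  candidates <- build_ng(net, G, config$expand_k)
  universe <- net$nodes
  U <- length(universe)
  nG <- length(G)
  # distance matrix candidates x all nodes, one shot
  d <- igraph::distances(net$graph, v = candidates,
                         mode = .mode_of(config$direction), weights = NA)
  in_G <- colnames(d) %in% G
  h_star <- integer(length(candidates)); es <- numeric(length(candidates))
  pval <- numeric(length(candidates))
  nb_size <- integer(length(candidates)); ov <- integer(length(candidates))
  for (i in seq_along(candidates)) {
    di <- d[i, ]
    best <- list(stat = -Inf, es = 0, h = 1L, size = 0L, overlap = 0L, p = 1)
    for (h in seq_len(config$h_max)) {
      inside <- di >= 1 & di <= h
      size <- sum(inside)
      o <- sum(inside & in_G)
      expected <- size * nG / U
      e <- if (expected > 0) o / expected else 0
      p <- if (o == 0L) 1 else
        stats::phyper(o - 1L, nG, U - nG, size, lower.tail = FALSE)
      stat <- if (config$statistic == "fold") e else -log(p)
      if (stat > best$stat + 1e-12) # strict improvement: ties keep smaller h
        best <- list(stat = stat, es = e, h = h, size = size, overlap = o, p = p)
    }
    h_star[i] <- best$h; es[i] <- best$es
    nb_size[i] <- best$size; ov[i] <- best$overlap
    pval[i] <- best$p
  }
  padj <- adjust_pvalues(pval, config$correction)
  indeg <- network_indegree(net)[candidates]
  cls <- ifelse(padj < config$alpha,
                ifelse(indeg == 0L, "global", "local"), "none")
  res <- data.frame(gene = candidates, h_star = h_star, es = es, p = pval,
                    p_adjusted = padj, neighborhood_size = nb_size,
                    overlap = ov, driver_class = cls,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_adjusted, -res$es, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, config = config, g_size = nG,
                 universe_size = U,
                 drivers = res$gene[res$driver_class != "none"]),
            class = "kda")
}

#' @export
print.kda <- function(x, n = 6L, ...) {
  cat("Key driver analysis: |G| =", x$g_size, "genes on a network of",
      x$universe_size, "nodes\n")
  cat("  candidates:", nrow(x$results),
      " significant drivers:", length(x$drivers),
      sprintf("(%d global, %d local)\n",
              sum(x$results$driver_class == "global"),
              sum(x$results$driver_class == "local")))
  print(utils::head(x$results, n), digits = 3)
  if (nrow(x$results) > n) cat("  ...", nrow(x$results) - n, "more rows\n")
  invisible(x)
}

#' @export
summary.kda <- function(object, ...) {
  r <- object$results
  structure(list(
    n_candidates = nrow(r),
    n_global = sum(r$driver_class == "global"),
    n_local = sum(r$driver_class == "local"),
    config = object$config,
    top = utils::head(r[r$driver_class != "none", ], 10)),
    class = "summary.kda")
}

#' @export
print.summary.kda <- function(x, ...) {
  cat("KDA summary:", x$n_candidates, "candidates;",
      x$n_global, "global and", x$n_local, "local drivers\n")
  cat("  (H =", x$config$h_max, ", direction =", x$config$direction,
      ", correction =", x$config$correction, ", alpha =", x$config$alpha, ")\n")
  if (nrow(x$top)) {
    cat("Top drivers:\n")
    print(x$top, digits = 3)
  }
  invisible(x)
}

#' @export
as.data.frame.kda <- function(x, ...) x$results

#' @export
plot.kda <- function(x, n = 20L, ...) {
  r <- utils::head(x$results, n)
  op <- graphics::par(mar = c(4, 6, 2, 1)); on.exit(graphics::par(op))
  graphics::barplot(rev(-log10(pmax(r$p_adjusted, 1e-300))),
                    names.arg = rev(r$gene), horiz = TRUE, las = 1,
                    col = rev(ifelse(r$driver_class == "global", "firebrick",
                                     ifelse(r$driver_class == "local",
                                            "steelblue", "grey70"))),
                    xlab = expression(-log[10] ~ "adjusted p"),
                    main = "Key driver candidates", ...)
  invisible(x)
}

#' Predicted regulatory signature of a key driver
#'
#' The genes the network predicts to be under the driver's control: all
#' nodes within directed path length `k` downstream of the driver,
#' excluding the driver itself. `k = 2` is the validation window used when
#' testing perturbation signatures against network predictions.
#'
#' @param net a [gene_network].
#' @param driver gene id present in the network.
#' @param k downstream path-length bound.
#' @return sorted character vector of predicted target genes.
#' @export
kdg_signature <- function(net, driver, k = 2) {
  hln(net, driver, k, direction = "downstream")
}
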