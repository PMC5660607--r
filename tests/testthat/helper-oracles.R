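# Independent oracles used across tests; deliberately avoid the code paths
# (igraph, phyper) they are checking.

# exhaustive hypergeometric upper-tail sum via log-binomials:
# P(X >= o), X ~ Hyper(|a| white, U - |a| black, |b| drawn)
hyper_tail_oracle <- function(o, na, nb, U) {
  if (o == 0) return(1)
  ks <- o:min(na, nb)
  ks <- ks[ks >= max(0, na + nb - U)]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(na, ks) + lchoose(U - na, nb - ks) - lchoose(U, nb)))
}

# adjacency matrix of a gene_network in a fixed node order
adj_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges))
    A[cbind(match(net$edges$parent, net$nodes),
            match(net$edges$child, net$nodes))] <- 1
  A
}

# brute-force "within k hops" reachability filter by boolean matrix powers
reach_oracle <- function(net, k, mode = c("undirected", "downstream", "upstream")) {
  mode <- match.arg(mode)
  A <- adj_matrix(net)
  A <- switch(mode, undirected = pmax(A, t(A)), downstream = A, upstream = t(A))
  R <- A
  P <- A
  if (k > 1) for (i in 2:k) {
    P <- (P %*% A > 0) * 1
    R <- pmax(R, P)
  }
  R # R[i, j] == 1 iff 1 <= dist(i, j) <= k
}

neighborhood_oracle <- function(net, seed, k, mode) {
  R <- reach_oracle(net, k, mode)
  seed <- intersect(seed, net$nodes)
  reached <- colnames(R)[colSums(R[seed, , drop = FALSE]) > 0]
  sort(unique(c(seed, reached)))
}

# random DAG-ish directed graph (may contain cycles) for oracle comparisons
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%d", seq_len(n))
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  idx <- which(A == 1, arr.ind = TRUE)
  gene_network(data.frame(parent = ids[idx[, 1]], child = ids[idx[, 2]],
                          stringsAsFactors = FALSE), nodes = ids)
}

# depth-first cycle detection, independent of igraph
has_cycle_oracle <- function(net) {
  adj <- split(net$edges$child, net$edges$parent)
  state <- new.env()
  for (v in net$nodes) assign(v, 0L, envir = state) # 0 white 1 grey 2 black
  visit <- function(v) {
    assign(v, 1L, envir = state)
    for (w in adj[[v]]) {
      s <- get(w, envir = state)
      if (s == 1L) return(TRUE)
      if (s == 0L && visit(w)) return(TRUE)
    }
    assign(v, 2L, envir = state)
    FALSE
  }
  for (v in net$nodes)
    if (get(v, envir = state) == 0L && visit(v)) return(TRUE)
  FALSE
}

chain_network <- function(ids = c("A", "B", "C", "D"), weight = 1) {
  n <- length(ids)
  gene_network(data.frame(parent = ids[-n], child = ids[-1], weight = weight,
                          stringsAsFactors = FALSE))
}

star_network <- function(hub = "R", n_leaves = 10) {
  gene_network(data.frame(parent = hub,
                          child = sprintf("m%d", seq_len(n_leaves)),
                          stringsAsFactors = FALSE))
}

# minimal fake enrichment evidence for ranking tests (composite_rank only
# reads the $p element)
fake_evidence <- function(p_matrix) {
  ev <- lapply(seq_len(nrow(p_matrix)), function(i)
    lapply(stats::setNames(seq_len(ncol(p_matrix)), colnames(p_matrix)),
           function(j) list(p = p_matrix[i, j])))
  names(ev) <- rownames(p_matrix)
  ev
}
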