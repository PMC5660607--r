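#' @title Synthetic causal-network data with planted ground truth
#' @description Generators for sparse hub DAGs, linear structural-equation
#'   expression, knockout signatures, cis genetic effects and per-cohort
#'   module collections. Every generator is bit-reproducible from its
#'   parameters and `rng_seed`, and the planted truth (hub drivers, seed
#'   module, cis effects) is carried alongside so downstream recovery can
#'   be scored.
#' @name kdnet-synthetic
NULL

#' Generate a sparse DAG with enforced hub root regulators
#'
#' Nodes are created in a fixed topological order (`g1 ... gN`, hubs first)
#' and edges only run from earlier to later nodes, so acyclicity holds by
#' construction. Non-hub genes are wired preferential-attachment-style
#' (each later node draws a Poisson number of parents from earlier
#' non-hub nodes, out-degree-weighted), producing emergent secondary
#' regulators. The first `n_hubs` nodes are then placed as roots (no
#' incoming edges) on top of this hierarchy: each hub regulates at least
#' `3 * mean_out_degree` targets drawn preferentially from the secondary
#' regulators, so hub influence cascades deep into the network — the
#' planted master regulators. Edge weights are signed: magnitude
#' uniform on `weight_range`, sign +/- with equal probability. Gene
#' intercepts are uniform on `intercept_range` (baseline expression) and
#' noise is homoscedastic Gaussian with standard deviation `noise_sd`.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_hubs number of hub roots (< `n_genes`, or equal when
#'   `n_genes == 1`).
#' @param mean_out_degree target mean out-degree (>= 1) controlling overall
#'   sparsity.
#' @param rng_seed integer seed; generation is reproducible from it.
#' @param weight_range magnitude range of edge weights.
#' @param intercept_range range of per-gene intercepts.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @return An object of class `sem_model`: list with `network`
#'   (a [gene_network] whose edge weights are the structural coefficients),
#'   `intercepts` (named numeric), `noise_sd`, `hubs` (character),
#'   `topo_order` (character).
#' @export
generate_dag <- function(n_genes, n_hubs, mean_out_degree = 2, rng_seed = 1,
                         weight_range = c(0.5, 1),
                         intercept_range = c(0.5, 2), noise_sd = 1) {
  if (n_genes < 1L) stop("n_genes must be positive")
  if (n_hubs < 0L) stop("n_hubs must be non-negative")
  if (n_genes == 1L) {
    if (n_hubs > 1L) stop("n_hubs must not exceed n_genes")
  } else if (n_hubs >= n_genes) stop("n_hubs must be smaller than n_genes")
  if (mean_out_degree < 1) stop("mean_out_degree must be >= 1")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  set.seed(rng_seed)
  ids <- sprintf("g%d", seq_len(n_genes))
  hubs <- if (n_hubs > 0L) ids[seq_len(n_hubs)] else character()
  parent <- character(); child <- character()
  if (n_genes > 1L) {
    nonhub_idx <- (n_hubs + 1L):n_genes
    # regulatory cascade among non-hub genes first: each later gene draws a
    # Poisson number of parents from earlier non-hub genes, preferentially
    # from genes that already regulate many targets, so secondary
    # regulators emerge below the hubs
    target_edges <- round(n_genes * mean_out_degree)
    n_child <- min(max(ceiling(3 * mean_out_degree), 3L), length(nonhub_idx))
    remaining <- max(0L, target_edges - n_hubs * n_child)
    outdeg <- stats::setNames(integer(n_genes), ids)
    if (length(nonhub_idx) > 1L && remaining > 0L) {
      lambda <- remaining / (length(nonhub_idx) - 1L)
      for (j in nonhub_idx[-1L]) {
        k <- stats::rpois(1L, lambda)
        if (k == 0L) next
        cand <- nonhub_idx[nonhub_idx < j]
        k <- min(k, length(cand))
        w <- outdeg[cand] + 1
        pa <- if (length(cand) == 1L) cand else sample(cand, k, prob = w)
        parent <- c(parent, ids[pa]); child <- c(child, rep(ids[j], k))
        outdeg[pa] <- outdeg[pa] + 1L
      }
    }
    # hubs sit on top of the hierarchy: each hub regulates at least
    # 3 x mean_out_degree targets drawn preferentially from the secondary
    # regulators (out-degree-weighted), so hub influence cascades deep
    for (h in seq_len(n_hubs)) {
      w <- (outdeg[nonhub_idx] + 1)^2
      ch <- if (length(nonhub_idx) == 1L) nonhub_idx
            else sample(nonhub_idx, n_child, prob = w)
      parent <- c(parent, rep(ids[h], n_child)); child <- c(child, ids[ch])
    }
  }
  edges <- unique(data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE))
  edges$weight <- if (nrow(edges))
    sample(c(-1, 1), nrow(edges), replace = TRUE) *
      stats::runif(nrow(edges), weight_range[1], weight_range[2])
  else numeric()
  net <- gene_network(edges, nodes = ids)
  sem <- structure(list(
    network = net,
    intercepts = stats::setNames(
      stats::runif(n_genes, intercept_range[1], intercept_range[2]), ids),
    noise_sd = noise_sd,
    hubs = hubs,
    topo_order = ids), class = "sem_model")
  validate_sem(sem)
  sem
}

#' Construct a linear SEM from explicit parts
#'
#' Lower-level companion to [generate_dag()]: wraps an existing acyclic
#' [gene_network] (edge weights = structural coefficients) with intercepts
#' and a noise level. An edgeless network gives mutually independent genes
#' (useful as a calibration null).
#'
#' @param network a [gene_network] whose `weight` column holds structural
#'   coefficients (required when edges exist).
#' @param intercepts named numeric vector over all network nodes, or a
#'   single value recycled.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param hubs optional character vector of designated hub regulators.
#' @return a `sem_model`.
#' @export
sem_model <- function(network, intercepts = 1, noise_sd = 1,
                      hubs = character()) {
  stopifnot_network(network)
  if (length(intercepts) == 1L && is.null(names(intercepts)))
    intercepts <- stats::setNames(rep(as.numeric(intercepts),
                                      length(network$nodes)), network$nodes)
  if (!all(network$nodes %in% names(intercepts)))
    stop("intercepts must cover every network node")
  sem <- structure(list(network = network,
                        intercepts = intercepts[network$nodes],
                        noise_sd = noise_sd,
                        hubs = intersect(hubs, network$nodes),
                        topo_order = network$nodes),
                   class = "sem_model")
  validate_sem(sem)
  sem
}

#' @export
print.sem_model <- function(x, ...) {
  cat("Linear SEM on a DAG:", length(x$network$nodes), "genes,",
      nrow(x$network$edges), "edges,", length(x$hubs), "hub roots\n")
  invisible(x)
}

#' Validate a structural-equation model
#'
#' Checks acyclicity (topological sort), finite weights and positive noise.
#'
#' @param sem a `sem_model`.
#' @return `sem`, invisibly; errors if invalid.
#' @export
validate_sem <- function(sem) {
  stopifnot(inherits(sem, "sem_model"))
  if (!igraph::is_dag(sem$network$graph)) stop("SEM graph contains a cycle")
  if (nrow(sem$network$edges) && !all(is.finite(sem$network$edges$weight)))
    stop("all edge weights must be finite")
  if (!is.finite(sem$noise_sd) || sem$noise_sd <= 0)
    stop("noise_sd must be positive")
  invisible(sem)
}

# weight lookup and topological order shared by the simulators
.sem_parents <- function(sem) {
  e <- sem$network$edges
  split(data.frame(parent = e$parent, weight = e$weight,
                   stringsAsFactors = FALSE), e$child)
}

.sem_topo <- function(sem) {
  ord <- igraph::topo_sort(sem$network$graph, mode = "out")
  igraph::V(sem$network$graph)$name[as.integer(ord)]
}

#' Simulate expression from a linear SEM
#'
#' Each gene's expression is `intercept + sum(weight * parent) + N(0,
#' noise_sd^2)`, evaluated in topological order. Optionally a per-gene,
#' per-sample offset matrix is added to the intercepts (used to inject cis
#' genetic effects) and a set of genes can be clamped to a constant
#' (the knockout do-operator).
#'
#' @param sem a `sem_model`.
#' @param n_samples number of samples (columns).
#' @param rng_seed integer seed, or `NULL` to continue from the current RNG
#'   state (used when several cohorts must come from one seeded stream).
#' @param offsets optional genes x samples matrix of intercept offsets
#'   (rownames must be gene ids present in the model).
#' @param clamp optional named numeric vector: genes forced to the given
#'   constant value regardless of their structural equation.
#' @return genes x samples numeric matrix (all genes, model node order).
#' @export
simulate_expression <- function(sem, n_samples, rng_seed = 1, offsets = NULL,
                                clamp = NULL) {
  validate_sem(sem)
  if (n_samples < 1L) stop("n_samples must be positive")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  genes <- sem$network$nodes
  topo <- .sem_topo(sem)
  pa <- .sem_parents(sem)
  X <- matrix(0, nrow = length(genes), ncol = n_samples,
              dimnames = list(genes, sprintf("s%d", seq_len(n_samples))))
  # draw all noise up front in node order so clamping does not shift the
  # RNG stream of other genes (paired WT/KO cohorts stay comparable)
  eps <- matrix(stats::rnorm(length(genes) * n_samples, sd = sem$noise_sd),
                nrow = length(genes), dimnames = dimnames(X))
  for (g in topo) {
    if (!is.null(clamp) && g %in% names(clamp)) {
      X[g, ] <- clamp[[g]]
      next
    }
    mu <- rep(sem$intercepts[[g]], n_samples)
    if (!is.null(offsets) && g %in% rownames(offsets))
      mu <- mu + offsets[g, ]
    p <- pa[[g]]
    if (!is.null(p) && nrow(p))
      mu <- mu + as.vector(crossprod(p$weight, X[p$parent, , drop = FALSE]))
    X[g, ] <- mu + eps[g, ]
  }
  X
}

#' Simulate a gene-knockout differential-expression signature
#'
#' Simulates paired wild-type and knockout cohorts (`n_samples` each) from
#' the same SEM; in the knockout arm the target gene is clamped to 0 (the
#' do-operator — the intervention a genetic knockout performs, as opposed
#' to deleting outgoing edges). Per gene, a Welch two-sample t-test
#' compares the arms and Benjamini-Hochberg adjusts across genes.
#'
#' @param sem a `sem_model`.
#' @param target gene to knock out.
#' @param n_samples samples per arm.
#' @param rng_seed integer seed.
#' @return a `signature_table` data.frame: `gene`, `effect` (knockout minus
#'   wild-type mean), `p_value`, `adjusted_p`.
#' @export
simulate_knockout <- function(sem, target, n_samples = 200, rng_seed = 1) {
  validate_sem(sem)
  if (!target %in% sem$network$nodes) stop("unknown target gene: ", target)
  # both arms from one seeded stream: sequential set.seed(s), set.seed(s + 1)
  # calls yield correlated streams, which would bias the arm comparison
  set.seed(rng_seed)
  wt <- simulate_expression(sem, n_samples, rng_seed = NULL)
  ko <- simulate_expression(sem, n_samples, rng_seed = NULL,
                            clamp = stats::setNames(0, target))
  genes <- rownames(wt)
  eff <- rowMeans(ko) - rowMeans(wt)
  p <- vapply(genes, function(g) {
    if (stats::sd(ko[g, ]) == 0 && stats::sd(wt[g, ]) == 0)
      return(if (eff[[g]] == 0) 1 else 0)
    stats::t.test(ko[g, ], wt[g, ])$p.value
  }, numeric(1))
  signature_table(data.frame(
    gene = genes, effect = as.numeric(eff), p_value = as.numeric(p),
    adjusted_p = adjust_pvalues(as.numeric(p), "BH"),
    stringsAsFactors = FALSE))
}

#' Simulate genotype dosages with cis effects on expression
#'
#' Draws biallelic dosages (0/1/2) binomially at per-variant minor-allele
#' frequencies uniform on `maf_range`. A fraction `cis_fraction` of
#' variants is assigned a cis target gene and placed within the cis window
#' of that gene on a synthetic coordinate system (genes laid out on one
#' linear chromosome, 1-based, 2 Mb apart); the remaining variants are
#' placed on a second chromosome and are therefore trans to every gene.
#' Expression is regenerated with `beta * dosage` added to the target
#' gene's intercept per sample; effect magnitudes are uniform on
#' `beta_range` with random sign.
#'
#' @param sem a `sem_model`.
#' @param n_variants number of variants.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param beta_range cis effect-size magnitude range (use `c(0, 0)` for a
#'   global null).
#' @param n_samples number of samples.
#' @param rng_seed integer seed.
#' @param cis_fraction fraction of variants assigned a cis target gene.
#' @param cis_window half-width (bases) within which a cis variant is
#'   placed around its target gene.
#' @return list of class `genetic_sim`: `genotypes` (variants x samples),
#'   `expression` (genes x samples, cis effects injected),
#'   `gene_coords` (data.frame gene/chrom/start/end),
#'   `variant_coords` (data.frame variant/chrom/pos),
#'   `cis_effects` (data.frame variant/gene/beta).
#' @export
simulate_genotypes_and_cis <- function(sem, n_variants, maf_range = c(0.1, 0.5),
                                       beta_range = c(0.3, 0.8),
                                       n_samples = 200, rng_seed = 1,
                                       cis_fraction = 0.5,
                                       cis_window = 1e6) {
  validate_sem(sem)
  if (n_variants < 1L) stop("n_variants must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("minor-allele frequencies must lie in (0, 0.5]")
  set.seed(rng_seed)
  genes <- sem$network$nodes
  gene_len <- 1e4
  gene_coords <- data.frame(
    gene = genes, chrom = "chr1",
    start = 2e6 * seq_along(genes),
    end = 2e6 * seq_along(genes) + gene_len,
    stringsAsFactors = FALSE)
  vids <- sprintf("v%d", seq_len(n_variants))
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  G <- matrix(stats::rbinom(n_variants * n_samples, 2L, rep(maf, n_samples)),
              nrow = n_variants,
              dimnames = list(vids, sprintf("s%d", seq_len(n_samples))))
  n_cis <- round(cis_fraction * n_variants)
  cis_idx <- if (n_cis > 0L) sort(sample(n_variants, n_cis)) else integer()
  target <- if (n_cis > 0L) sample(genes, n_cis, replace = TRUE) else character()
  beta <- if (n_cis > 0L)
    sample(c(-1, 1), n_cis, replace = TRUE) *
      stats::runif(n_cis, beta_range[1], beta_range[2])
  else numeric()
  pos <- numeric(n_variants)
  chrom <- rep("chr2", n_variants)
  if (n_cis > 0L) {
    tstart <- gene_coords$start[match(target, gene_coords$gene)]
    tend <- gene_coords$end[match(target, gene_coords$gene)]
    # place inside the closed cis window, away from its outer edge
    pos[cis_idx] <- round(stats::runif(n_cis, tstart - 0.9 * cis_window,
                                       tend + 0.9 * cis_window))
    chrom[cis_idx] <- "chr1"
  }
  trans_idx <- setdiff(seq_len(n_variants), cis_idx)
  pos[trans_idx] <- round(stats::runif(length(trans_idx), 1, 2e6 * length(genes)))
  offsets <- NULL
  cis_effects <- data.frame(variant = character(), gene = character(),
                            beta = numeric(), stringsAsFactors = FALSE)
  if (n_cis > 0L) {
    cis_effects <- data.frame(variant = vids[cis_idx], gene = target,
                              beta = beta, stringsAsFactors = FALSE)
    offsets <- matrix(0, nrow = length(unique(target)), ncol = n_samples,
                      dimnames = list(unique(target), colnames(G)))
    for (i in seq_len(n_cis))
      offsets[target[i], ] <- offsets[target[i], ] + beta[i] * G[cis_idx[i], ]
  }
  # same stream as the genotype draw (consecutive seeds are not independent)
  expr <- simulate_expression(sem, n_samples, rng_seed = NULL,
                              offsets = offsets)
  structure(list(genotypes = G, expression = expr,
                 gene_coords = gene_coords,
                 variant_coords = data.frame(variant = vids, chrom = chrom,
                                             pos = pos, stringsAsFactors = FALSE),
                 cis_effects = cis_effects),
            class = "genetic_sim")
}

#' Assemble planted ground truth
#'
#' @param sem a `sem_model` (its hubs become the planted drivers).
#' @param seed_module character vector of genes forming the planted seed
#'   module; defaults to a sample of the hubs' descendants.
#' @param seed_size number of genes sampled into the default seed module.
#' @param rng_seed integer seed.
#' @return object of class `synthetic_truth`: `sem`, `planted_drivers`,
#'   `seed_module`, `cis_effects`, `rng_seed`.
#' @export
make_truth <- function(sem, seed_module = NULL, seed_size = 40, rng_seed = 1) {
  validate_sem(sem)
  if (is.null(seed_module)) {
    set.seed(rng_seed)
    desc <- hub_descendants(sem)
    if (length(desc) == 0L) desc <- sem$network$nodes
    seed_module <- sort(sample(desc, min(seed_size, length(desc))))
  }
  stopifnot(all(seed_module %in% sem$network$nodes))
  structure(list(sem = sem, planted_drivers = sem$hubs,
                 seed_module = seed_module,
                 cis_effects = data.frame(variant = character(),
                                          gene = character(), beta = numeric(),
                                          stringsAsFactors = FALSE),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_truth")
}

#' Union of all descendants of the model's hub roots
#'
#' @param sem a `sem_model`.
#' @return character vector of genes reachable from any hub (hubs excluded).
#' @export
hub_descendants <- function(sem) {
  validate_sem(sem)
  if (length(sem$hubs) == 0L) return(character())
  res <- unique(unlist(lapply(sem$hubs, function(h)
    igraph::V(sem$network$graph)$name[as.integer(
      igraph::subcomponent(sem$network$graph, h, mode = "out"))])))
  setdiff(res, sem$hubs)
}

#' Generate per-cohort module collections around a planted seed module
#'
#' Each cohort receives (i) a "seeded" module: the planted seed module with
#' a fraction `contamination` of its members replaced by random
#' non-seed genes (emulating imperfect coexpression module recovery), and
#' (ii) `n_decoys` decoy modules of random genes of the same size. Cohort
#' universes are jittered copies of the full gene set (a fraction
#' `universe_jitter` of non-seed genes dropped per cohort), emulating
#' platform differences.
#'
#' @param truth a `synthetic_truth`.
#' @param n_cohorts number of cohorts.
#' @param contamination fraction of seed-module members replaced, in [0, 1).
#' @param rng_seed integer seed.
#' @param n_decoys decoy modules per cohort.
#' @param universe_jitter fraction of non-seed genes dropped from each
#'   cohort's universe (0 gives identical universes).
#' @return list of [module_collection], one per cohort.
#' @export
generate_module_collections <- function(truth, n_cohorts = 3,
                                        contamination = 0.3, rng_seed = 1,
                                        n_decoys = 8, universe_jitter = 0.02) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (contamination < 0 || contamination >= 1)
    stop("contamination must be in [0, 1)")
  if (n_cohorts < 1L) stop("n_cohorts must be positive")
  set.seed(rng_seed)
  all_genes <- truth$sem$network$nodes
  seed <- truth$seed_module
  lapply(seq_len(n_cohorts), function(ci) {
    nonseed <- setdiff(all_genes, seed)
    drop_n <- round(universe_jitter * length(nonseed))
    universe <- sort(setdiff(all_genes,
                             if (drop_n > 0) sample(nonseed, drop_n) else character()))
    pool <- setdiff(universe, seed)
    n_repl <- round(contamination * length(seed))
    kept <- if (n_repl > 0) sample(seed, length(seed) - n_repl) else seed
    contam <- if (n_repl > 0) sample(pool, min(n_repl, length(pool))) else character()
    mods <- list(gene_set(sprintf("cohort%d_M1", ci), c(kept, contam),
                          "seeded module"))
    for (k in seq_len(n_decoys)) {
      mods[[k + 1L]] <- gene_set(
        sprintf("cohort%d_M%d", ci, k + 1L),
        sample(pool, min(length(seed), length(pool))), "decoy module")
    }
    module_collection(sprintf("cohort%d", ci), mods, universe)
  })
}

#' Generate disease-trait gene sets from the planted truth
#'
#' Emulates disease signatures (GWAS gene lists, case/control expression
#' signatures, clinical-trait correlates): each trait set is an independent
#' sample of the hub-descendant union at the given rate.
#'
#' @param truth a `synthetic_truth`.
#' @param n_traits number of trait sets.
#' @param rate sampling rate of the hub-descendant union per trait.
#' @param rng_seed integer seed.
#' @return list of [gene_set].
#' @export
make_trait_sets <- function(truth, n_traits = 4, rate = 0.6, rng_seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(rng_seed)
  desc <- hub_descendants(truth$sem)
  lapply(seq_len(n_traits), function(i)
    gene_set(sprintf("trait%d", i),
             sample(desc, round(rate * length(desc))),
             "synthetic disease trait signature"))
}
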