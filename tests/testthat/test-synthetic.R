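test_that("DAG generation is reproducible and respects hub constraints", {
  sem1 <- generate_dag(300, 8, 2, rng_seed = 7)
  sem2 <- generate_dag(300, 8, 2, rng_seed = 7)
  expect_identical(sem1$network$edges, sem2$network$edges)
  expect_identical(sem1$intercepts, sem2$intercepts)
  sem3 <- generate_dag(300, 8, 2, rng_seed = 8)
  expect_false(identical(sem1$network$edges, sem3$network$edges))

  indeg <- table(factor(sem1$network$edges$child, levels = sem1$network$nodes))
  expect_true(all(indeg[sem1$hubs] == 0)) # hubs are roots
  outdeg <- table(factor(sem1$network$edges$parent, levels = sem1$network$nodes))
  expect_true(all(outdeg[sem1$hubs] >= 3 * 2))
})

test_that("generated graphs are acyclic (depth-first search oracle)", {
  for (s in c(1, 2, 3)) {
    sem <- generate_dag(200, 5, 2.5, rng_seed = s)
    expect_false(has_cycle_oracle(sem$network))
  }
})

test_that("degenerate sizes are handled and bad parameters rejected", {
  sem <- generate_dag(1, 0, 1, rng_seed = 1)
  expect_equal(length(sem$network$nodes), 1)
  expect_equal(nrow(sem$network$edges), 0)
  expect_equal(nrow(generate_dag(1, 1, 1, rng_seed = 1)$network$edges), 0)
  expect_error(generate_dag(0, 0, 1), "positive")
  expect_error(generate_dag(10, 10, 1), "smaller")
  expect_error(generate_dag(10, 2, 0.5), "mean_out_degree")
  expect_error(generate_dag(10, 2, 2, noise_sd = 0), "noise_sd")
})

test_that("expression follows the linear structural equations", {
  # near-deterministic limit: B ~= 2 A + intercept
  edges <- data.frame(parent = "A", child = "B", weight = 2)
  sem <- structure(list(network = gene_network(edges),
                        intercepts = c(A = 1, B = 0.5),
                        noise_sd = 1e-8, hubs = "A", topo_order = c("A", "B")),
                   class = "sem_model")
  X <- simulate_expression(sem, 25, rng_seed = 3)
  expect_equal(X["B", ], 2 * X["A", ] + 0.5, tolerance = 1e-6)
  expect_true(all(is.finite(X)))
  # determinism
  expect_identical(X, simulate_expression(sem, 25, rng_seed = 3))
})

test_that("an edgeless model gives mutually uncorrelated genes", {
  ids <- sprintf("g%d", 1:12)
  sem <- structure(list(network = gene_network(NULL, nodes = ids),
                        intercepts = stats::setNames(rep(0, 12), ids),
                        noise_sd = 1, hubs = character(), topo_order = ids),
                   class = "sem_model")
  X <- simulate_expression(sem, 10000, rng_seed = 5)
  r <- stats::cor(t(X))
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("knockout signatures match the path-product closed form", {
  edges <- data.frame(parent = c("A", "B"), child = c("B", "C"),
                      weight = c(2, 3))
  sem <- structure(list(network = gene_network(edges),
                        intercepts = c(A = 1, B = 0, C = 0),
                        noise_sd = 1, hubs = "A",
                        topo_order = c("A", "B", "C")),
                   class = "sem_model")
  sig <- simulate_knockout(sem, "A", n_samples = 5000, rng_seed = 11)
  eff <- stats::setNames(sig$effect, sig$gene)
  # clamping A to 0 removes its mean E[A] = 1; descendants shift by
  # -(path product) * E[A]
  expect_equal(eff[["A"]], -1, tolerance = 0.1)
  expect_equal(eff[["B"]], -2, tolerance = 0.1)
  expect_equal(eff[["C"]], -6, tolerance = 0.2)
  expect_true(all(sig$adjusted_p[sig$gene %in% c("B", "C")] < 0.05))
  # the clamped target carries the strongest standardized signal
  expect_lt(sig$p_value[sig$gene == "A"],
            min(sig$p_value[sig$gene != "A"]) + 1e-300)
  expect_error(simulate_knockout(sem, "Z"), "unknown target")
})

test_that("knocking out a sink gene leaves other genes at the nominal rate", {
  # genes share ancestral noise, so the per-replicate false-positive
  # fraction is overdispersed; its average should sit near the nominal rate
  sem <- generate_dag(150, 4, 2, rng_seed = 21)
  outdeg <- table(factor(sem$network$edges$parent, levels = sem$network$nodes))
  sink <- names(which(outdeg == 0))[1]
  frac <- vapply(1:5, function(r) {
    sig <- simulate_knockout(sem, sink, n_samples = 100, rng_seed = 21 + 7 * r)
    others <- sig[sig$gene != sink, ]
    mean(others$p_value < 0.05)
  }, numeric(1))
  expect_lt(mean(frac), 0.10)
  expect_gt(mean(frac), 0.01)
})

test_that("genotype simulation honours MAF and places cis variants in window", {
  sem <- generate_dag(40, 2, 2, rng_seed = 31)
  gs <- simulate_genotypes_and_cis(sem, n_variants = 60,
                                   maf_range = c(0.5, 0.5),
                                   beta_range = c(0.5, 0.5),
                                   n_samples = 3000, rng_seed = 32,
                                   cis_fraction = 0.5)
  expect_true(all(gs$genotypes %in% 0:2))
  expect_equal(mean(gs$genotypes), 1, tolerance = 0.05)
  expect_equal(nrow(gs$cis_effects), 30)
  # every assigned cis variant lies inside the +-1 Mb window of its target
  gc <- gs$gene_coords; vc <- gs$variant_coords
  for (i in seq_len(nrow(gs$cis_effects))) {
    g <- gs$cis_effects$gene[i]
    pos <- vc$pos[vc$variant == gs$cis_effects$variant[i]]
    lo <- gc$start[gc$gene == g] - 1e6; hi <- gc$end[gc$gene == g] + 1e6
    expect_true(pos >= lo && pos <= hi)
  }
  expect_error(
    simulate_genotypes_and_cis(sem, 10, maf_range = c(0, 0.6), n_samples = 50),
    "frequencies")
})

test_that("module collections recover the planted seed when uncontaminated", {
  sem <- generate_dag(200, 5, 2, rng_seed = 41)
  truth <- make_truth(sem, seed_size = 30, rng_seed = 42)
  cols <- generate_module_collections(truth, n_cohorts = 3, contamination = 0,
                                      rng_seed = 43, universe_jitter = 0)
  supers <- lapply(cols, function(mc) super_module(tag_modules(mc, gene_set(
    "seed", truth$seed_module))))
  core <- core_module(supers)
  expect_setequal(core$genes, truth$seed_module)
})

test_that("contaminated collections still nest core inside every super-module", {
  sem <- generate_dag(200, 5, 2, rng_seed = 51)
  truth <- make_truth(sem, seed_size = 30, rng_seed = 52)
  cols <- generate_module_collections(truth, n_cohorts = 3, contamination = 0.3,
                                      rng_seed = 53)
  seed <- gene_set("seed", truth$seed_module)
  supers <- lapply(cols, function(mc) super_module(tag_modules(mc, seed)))
  core <- core_module(supers)
  for (s in supers) expect_true(all(core$genes %in% s$genes))
  expect_gt(length(core$genes), 0)
})

test_that("decoy modules are tagged at no more than the nominal rate", {
  tagged_decoys <- 0L; total_decoys <- 0L
  for (r in 1:15) {
    sem <- generate_dag(150, 4, 2, rng_seed = 60 + r)
    truth <- make_truth(sem, seed_size = 25, rng_seed = 80 + r)
    mc <- generate_module_collections(truth, n_cohorts = 1,
                                      contamination = 0.2,
                                      rng_seed = 100 + r, n_decoys = 8)[[1]]
    tg <- tag_modules(mc, gene_set("seed", truth$seed_module))
    tab <- attr(tg, "all")
    decoys <- tab[grepl("_M[2-9]$", tab$module), ]
    tagged_decoys <- tagged_decoys + sum(decoys$tagged)
    total_decoys <- total_decoys + nrow(decoys)
  }
  expect_lt(tagged_decoys / total_decoys, 0.1)
})
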