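test_that("candidate pool expansion behaves at its boundaries", {
  net <- chain_network(c("A", "B", "C", "D"))
  expect_setequal(build_ng(net, c("B", "C"), expand_k = 0), c("B", "C"))
  expect_setequal(build_ng(net, "B", expand_k = 1), c("A", "B", "C"))
  expect_setequal(build_ng(net, "A", expand_k = 10), net$nodes) # saturation
  expect_error(build_ng(net, "ghost"), "no genes")
  net2 <- random_digraph(30, 0.08, seed = 3)
  set.seed(3)
  g <- sample(net2$nodes, 4)
  expect_setequal(build_ng(net2, g, 2),
                  neighborhood_oracle(net2, g, 2, "undirected"))
})

test_that("the star-graph hub is the unique global driver with the exact p", {
  # hub -> 10 leaves inside a 101-gene universe (90 isolated background genes)
  net <- gene_network(data.frame(parent = "R", child = sprintf("m%d", 1:10)),
                      nodes = c("R", sprintf("m%d", 1:10), sprintf("b%d", 1:90)))
  g <- sprintf("m%d", 1:8)
  fit <- kda(net, g, kda_config(h_max = 2, expand_k = 1))
  res <- fit$results
  expect_equal(fit$drivers, "R")
  r <- res[res$gene == "R", ]
  expect_equal(r$driver_class, "global")
  expect_equal(r$neighborhood_size, 10)
  expect_equal(r$overlap, 8)
  # exact hypergeometric tail on the 101-gene universe
  expect_equal(r$p, hyper_tail_oracle(8, 8, 10, 101), tolerance = 1e-12)
  # leaves have empty downstream neighborhoods
  leaf <- res[res$gene == "m1", ]
  expect_equal(leaf$p, 1)
  expect_equal(leaf$driver_class, "none")
  expect_equal(leaf$neighborhood_size, 0)
})

test_that("the optimal layer maximizes the selection statistic", {
  net <- random_digraph(60, 0.05, seed = 21)
  set.seed(21)
  g <- sample(net$nodes, 15)
  for (statistic in c("significance", "fold")) {
    cfg <- kda_config(h_max = 3, statistic = statistic)
    fit <- kda(net, g, cfg)
    U <- length(net$nodes); nG <- fit$g_size
    for (i in seq_len(nrow(fit$results))) {
      row <- fit$results[i, ]
      stats_h <- vapply(1:3, function(h) {
        nb <- hln(net, row$gene, h, "downstream")
        o <- length(intersect(nb, intersect(g, net$nodes)))
        if (statistic == "fold") {
          if (length(nb) == 0) 0 else o / (length(nb) * nG / U)
        } else {
          if (o == 0) 0 else
            -log(phyper(o - 1, nG, U - nG, length(nb), lower.tail = FALSE))
        }
      }, numeric(1))
      expect_gte(stats_h[row$h_star] + 1e-9, max(stats_h))
      # reported overlap/size agree with an independent recomputation
      nb <- hln(net, row$gene, row$h_star, "downstream")
      expect_equal(row$neighborhood_size, length(nb))
      expect_equal(row$overlap,
                   length(intersect(nb, intersect(g, net$nodes))))
    }
  }
})

test_that("driver classes partition by in-degree among significant candidates", {
  sem <- generate_dag(200, 5, 2, rng_seed = 31)
  set.seed(31)
  desc <- hub_descendants(sem)
  g <- sample(desc, round(0.6 * length(desc)))
  fit <- kda(sem$network, g)
  indeg <- table(factor(sem$network$edges$child, levels = sem$network$nodes))
  sig <- fit$results[fit$results$driver_class != "none", ]
  expect_gt(nrow(sig), 0)
  expect_true(all(indeg[sig$gene[sig$driver_class == "global"]] == 0))
  expect_true(all(indeg[sig$gene[sig$driver_class == "local"]] > 0))
  # output ordering is deterministic: (p_adjusted, -es, gene)
  r <- fit$results
  ord <- order(r$p_adjusted, -r$es, r$gene)
  expect_equal(ord, seq_len(nrow(r)))
  # rerun is identical
  expect_identical(fit$results, kda(sem$network, g)$results)
})

test_that("planted hub regulators are recovered on a small synthetic network", {
  sem <- generate_dag(250, 6, 2, rng_seed = 41)
  set.seed(41)
  desc <- hub_descendants(sem)
  g <- sample(desc, round(0.6 * length(desc)))
  fit <- kda(sem$network, g)
  glob <- fit$results$gene[fit$results$driver_class == "global"]
  expect_gte(sum(sem$hubs %in% glob), 5)
})

test_that("configuration bounds are enforced", {
  expect_error(kda_config(h_max = 0), "h_max")
  expect_error(kda_config(alpha = 0), "alpha")
  expect_error(kda_config(expand_k = -1), "expand_k")
  net <- star_network()
  expect_error(kda(net, "ghost"), "no genes")
})

test_that("kda methods print, summarize and convert", {
  net <- star_network("R", 8)
  fit <- kda(net, sprintf("m%d", 1:6), kda_config(h_max = 2))
  expect_output(print(fit), "Key driver analysis")
  s <- summary(fit)
  expect_s3_class(s, "summary.kda")
  expect_output(print(s), "global")
  expect_identical(as.data.frame(fit), fit$results)
})
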