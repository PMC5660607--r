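test_that("inverse normal transform is rank-based and symmetric", {
  z <- inverse_normal(c(1, 2, 3))
  expect_equal(z[2], 0)
  expect_equal(z[1], -z[3])
  # invariance under monotone transforms of the input
  set.seed(1)
  x <- rlnorm(50)
  expect_equal(inverse_normal(x), inverse_normal(log(x)))
  expect_equal(mean(inverse_normal(x)), 0, tolerance = 1e-10)
  # large-sample standard normality
  y <- inverse_normal(rnorm(1000))
  expect_gt(stats::ks.test(y, "pnorm")$p.value, 0.05)
  expect_error(inverse_normal(c(1, 1, 1)), "identical")
  expect_error(inverse_normal(c(1, 2)), "at least 3")
})

make_coords <- function(genes, variants, vpos, gstart = 5e6, glen = 1e4) {
  list(gc = data.frame(gene = genes, chrom = "chr1",
                       start = gstart + seq_along(genes) * 0,
                       end = gstart + glen),
       vc = data.frame(variant = variants, chrom = "chr1", pos = vpos))
}

test_that("a perfect linear relation is recovered on the raw scale", {
  set.seed(5)
  x <- sample(0:2, 60, replace = TRUE)
  expr <- matrix(2 * x + 1, nrow = 1,
                 dimnames = list("gA", sprintf("s%d", 1:60)))
  geno <- matrix(x, nrow = 1, dimnames = list("v1", sprintf("s%d", 1:60)))
  co <- make_coords("gA", "v1", 5e6)
  r <- fit_eqtl(expr, geno, co$gc, co$vc, transform = FALSE)
  expect_equal(r$beta_hat, 2, tolerance = 1e-10)
  expect_lt(r$wald_p, 1e-50)
})

test_that("cis classification uses a closed +-1 Mb window on the same chromosome", {
  expr <- matrix(rnorm(3 * 30), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:30)))
  set.seed(6)
  geno <- matrix(rbinom(4 * 30, 2, 0.4), nrow = 4,
                 dimnames = list(sprintf("v%d", 1:4), sprintf("s%d", 1:30)))
  gc <- data.frame(gene = c("g1", "g2", "g3"), chrom = "chr1",
                   start = 5e6, end = 5.01e6)
  vc <- data.frame(variant = sprintf("v%d", 1:4),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   pos = c(5e6 - 999999,      # inside the window
                           5e6 - 1000000,     # exactly on the closed boundary
                           5e6 - 1000001,     # one base outside
                           5e6))              # other chromosome
  r <- fit_eqtl(expr, geno, gc, vc)
  cis <- r$cis[r$gene == "g1"][match(sprintf("v%d", 1:4),
                                     r$variant[r$gene == "g1"])]
  expect_equal(cis, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("monomorphic variants are skipped and dosage range enforced", {
  expr <- matrix(rnorm(60), nrow = 2,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:30)))
  geno <- rbind(v1 = rep(2, 30), v2 = rbinom(30, 2, 0.5))
  colnames(geno) <- sprintf("s%d", 1:30)
  co <- make_coords(c("g1", "g2"), c("v1", "v2"), c(5e6, 5e6))
  expect_message(r <- fit_eqtl(expr, geno, co$gc, co$vc), "monomorphic")
  expect_setequal(unique(r$variant), "v2")
  expect_error(fit_eqtl(expr, geno * 2, co$gc, co$vc), "\\[0, 2\\]")
  expect_error(fit_eqtl(expr[, 1:5], geno[, 1:5], co$gc, co$vc), "at least 10")
})

test_that("null data give uniform Wald p-values", {
  sem <- generate_dag(50, 2, 2, rng_seed = 61)
  gs <- simulate_genotypes_and_cis(sem, n_variants = 40,
                                   beta_range = c(0, 0),
                                   n_samples = 100, rng_seed = 62)
  r <- fit_eqtl(gs$expression, gs$genotypes, gs$gene_coords, gs$variant_coords)
  expect_gt(stats::ks.test(r$wald_p, "punif")$p.value, 0.01)
  expect_equal(mean(r$wald_p < 0.05), 0.05, tolerance = 0.4)
})

test_that("planted cis effects are detected with the right sign", {
  # unit-noise gene with beta = 0.8, maf = 0.3, n = 200
  hits <- 0
  for (rep in 1:10) {
    set.seed(300 + rep)
    beta <- 0.8 * sample(c(-1, 1), 1)
    x <- rbinom(200, 2, 0.3)
    y <- beta * x + rnorm(200)
    expr <- matrix(y, nrow = 1, dimnames = list("gA", sprintf("s%d", 1:200)))
    geno <- matrix(x, nrow = 1, dimnames = list("v1", sprintf("s%d", 1:200)))
    co <- make_coords("gA", "v1", 5e6)
    r <- fit_eqtl(expr, geno, co$gc, co$vc)
    if (sign(r$beta_hat) == sign(beta) && r$wald_p < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("generator cis effects surface as cis associations", {
  sem <- generate_dag(30, 2, 2, rng_seed = 71)
  gs <- simulate_genotypes_and_cis(sem, n_variants = 20,
                                   maf_range = c(0.3, 0.4),
                                   beta_range = c(1.5, 2),
                                   n_samples = 300, rng_seed = 72)
  r <- fit_eqtl(gs$expression, gs$genotypes, gs$gene_coords, gs$variant_coords)
  planted <- merge(r, gs$cis_effects, by = c("gene", "variant"))
  expect_true(all(planted$cis))
  expect_true(all(sign(planted$beta_hat) == sign(planted$beta)))
  expect_gt(mean(planted$wald_p < 1e-3), 0.7)
})

test_that("permutation null is reproducible and calibrates empirical FDR", {
  sem <- generate_dag(40, 2, 2, rng_seed = 81)
  gs <- simulate_genotypes_and_cis(sem, n_variants = 30,
                                   beta_range = c(0, 0),
                                   n_samples = 80, rng_seed = 82)
  pn1 <- permutation_null(gs$expression, gs$genotypes, gs$gene_coords,
                          gs$variant_coords, n_rounds = 3, rng_seed = 9)
  pn2 <- permutation_null(gs$expression, gs$genotypes, gs$gene_coords,
                          gs$variant_coords, n_rounds = 3, rng_seed = 9)
  expect_identical(pn1$null_p, pn2$null_p)
  expect_length(pn1$null_p, 3 * nrow(pn1$observed))
  # global null: empirical FDR near 1 wherever defined
  for (t in c(0.01, 0.05, 0.2))
    if (!is.na(pn1$fdr(t))) expect_gt(pn1$fdr(t), 0.5)

  # strong planted signals: small FDR at their p-values
  gs2 <- simulate_genotypes_and_cis(sem, n_variants = 30,
                                    beta_range = c(1.5, 1.5),
                                    n_samples = 150, rng_seed = 83,
                                    cis_fraction = 0.5)
  pn3 <- permutation_null(gs2$expression, gs2$genotypes, gs2$gene_coords,
                          gs2$variant_coords, n_rounds = 3, rng_seed = 10)
  expect_lt(pn3$fdr(1e-6), 0.1)
})

test_that("polygenic scores are coefficient-weighted dosage sums", {
  geno <- matrix(c(2, 1,
                   0, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("v1", "v2"), c("s1", "s2")))
  m <- prs_model(data.frame(variant = c("v1", "v2"),
                            effect_allele = c("A", "G"),
                            coefficient = c(0.5, -0.2)))
  s <- prs_score(m, geno)
  expect_equal(unname(s["s1"]), 0.5 * 2 - 0.2 * 0)
  expect_equal(unname(s["s2"]), 0.5 * 1 - 0.2 * 2)
  expect_equal(attr(s, "n_variants_used"), 2)
  # all-zero dosages score zero
  expect_equal(as.numeric(prs_score(m, geno * 0)), c(0, 0))
  # a zero-coefficient variant changes nothing
  m2 <- prs_model(data.frame(variant = c("v1", "v2", "v3"),
                             effect_allele = c("A", "G", "T"),
                             coefficient = c(0.5, -0.2, 0)))
  expect_equal(as.numeric(prs_score(m2, geno)), as.numeric(s))
  # linear in the dosage matrix
  expect_equal(as.numeric(prs_score(m, geno)) * 2,
               as.numeric(prs_score(m, geno * 2) ))
  expect_error(prs_score(prs_model(data.frame(variant = "zz",
                                              effect_allele = "A",
                                              coefficient = 1)), geno),
               "no PRS model variants")
  expect_error(prs_model(data.frame(variant = c("v1", "v1"),
                                    effect_allele = "A", coefficient = 1)),
               "duplicate")
})
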