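# kdnet — key driver analysis on directed causal gene networks

kdnet identifies and prioritizes **key driver genes (KDGs)** — predicted
master regulators of disease-associated gene sets — on directed causal gene
networks, for computational biologists working with cohort-level network
models of complex disease.

Given per-cohort coexpression module collections, a curated seed gene set,
and directed (e.g. Bayesian) gene networks, the pipeline:

1. **derives a core module** — tag each cohort's modules by one-sided
   hypergeometric enrichment for the seed (*P* < 0.05 against the cohort's
   own universe), union the tagged modules into a per-cohort super-module,
   and intersect the super-modules across cohorts;
2. **projects** the core module onto each network: all nodes within path
   length *k* (default 2) of the overlap, restricted to the largest
   connected subgraph;
3. **runs key driver analysis**: for each candidate gene *g* in the
   neighborhood NG of the input set *G*, search the directed *h*-layer
   neighborhoods HLN<sub>g,h</sub> (*h* = 1..*H*) for the layer *h\**
   maximizing the enrichment statistic, ES<sub>h\*</sub> =
   max<sub>h</sub>(ES<sub>h,g</sub>); candidates whose HLN is significantly
   enriched for *G* (Fisher/hypergeometric, Bonferroni across candidates)
   are drivers — **global** if they are network roots (no parents), else
   **local**;
4. **rank-orders drivers** by a composite score: mean normalized rank of
   each driver's predicted signature enrichment across disease-evidence
   gene sets;
5. **validates** drivers against perturbation data: the knockout/knockdown
   signature is tested for enrichment in the driver's predicted signature
   (downstream nodes within two path lengths).

Supporting statistics: fold enrichment (observed / |A||B|/|U|), cis/trans
eQTL detection (*y* = α + β*x* + ε on inverse-normal expression, Wald test,
±1 Mb cis window, permutation null over 3 rounds with empirical FDR), and
coefficient-weighted polygenic risk scores. A synthetic-data module
generates hub-rooted DAGs, linear-SEM expression, knockout signatures,
genotypes with planted cis effects, and contaminated module collections —
with ground truth, so every stage is calibrated against planted answers.

## Worked example

```r
library(kdnet)

sem    <- generate_dag(n_genes = 500, n_hubs = 10, mean_out_degree = 2, rng_seed = 7)
truth  <- make_truth(sem, seed_size = 40, rng_seed = 8)
seed   <- gene_set("immune_seed", truth$seed_module)
cohorts <- generate_module_collections(truth, n_cohorts = 3,
                                       contamination = 0.3, rng_seed = 9)

supers <- lapply(cohorts, function(mc) super_module(tag_modules(mc, seed, alpha = 0.05)))
core   <- core_module(supers)
sub    <- project_seed(sem$network, core, k = 2)
fit    <- kda(sem$network, sub$nodes, kda_config(h_max = 3))
fit
#> Key driver analysis: |G| = 326 genes on a network of 500 nodes
#>   candidates: 425  significant drivers: 20 (10 global, 10 local)
#>   gene h_star   es        p p_adjusted neighborhood_size overlap driver_class
#> 1  g11      2 1.53 3.20e-54   1.36e-51               205     205        local
#> 2   g3      3 1.32 4.29e-47   1.82e-44               342     294       global
#> 3   g5      2 1.53 7.42e-46   3.16e-43               182     182       global
#> ...
```

All 10 planted hub regulators come back as global drivers (`es` is the fold
enrichment at the optimal layer `h_star`; `p` the one-sided hypergeometric
tail; roots of the network are `global`). Ranking and validation:

```r
traits <- make_trait_sets(truth, n_traits = 4, rng_seed = 10)
rk  <- rank_drivers(sem$network, fit$drivers, traits, k = 2)
drv <- rk$gene[1]                                    # top-ranked driver, "g8"
sig <- simulate_knockout(sem, drv, n_samples = 200, rng_seed = 11)
validate_prediction(kdg_signature(sem$network, drv, k = 2), sig, sem$network$nodes)
#> Overlap 105 of |A|=182, |B|=186 in U=500: fold=1.55, p=8.69e-13
```

The knockout signature of the top-ranked driver is 1.55-fold enriched
(*P* ≈ 9×10⁻¹³) in the 182 genes the network predicted to sit under its
control — the in-silico analogue of validating a predicted master regulator
with a knockout experiment.

The whole pipeline also runs from a single configuration:

```r
run_pipeline(list(simulate = list(n_genes = 500, n_hubs = 10, seed = 7)), "run1")
pipeline_report("run1")
```

which writes every intermediate artifact (core-module GMT, projected
subnetwork, KDA table, ranked drivers, validation enrichments) plus an md5
manifest; reruns with the same seed are byte-identical.

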