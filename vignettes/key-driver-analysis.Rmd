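---
title: "Key driver analysis on directed causal gene networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Key driver analysis on directed causal gene networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdnet)
```

## The problem

Complex inflammatory diseases are driven not by single genes but by
dysregulated gene networks. Given (i) directed causal gene networks inferred
per patient cohort, (ii) coexpression module collections from several
independent cohorts, and (iii) a curated seed set of disease-relevant genes,
the analysis implemented here asks three questions:

1. Which part of the module space is *conserved* across cohorts and relevant
   to the seed biology (the core module)?
2. Which network nodes are *key driver genes* (KDGs) — predicted master
   regulators whose downstream neighborhoods are enriched for the disease
   gene set?
3. Do perturbations of those drivers (knockouts, knockdowns) actually move
   the genes the network says they control?

kdnet implements this pipeline end to end, together with the supporting
statistics (overlap enrichment, cis/trans eQTL detection with a permutation
null, polygenic risk scores) and a synthetic-data generator with planted
ground truth, so every stage can be calibrated quantitatively.

## Core module derivation

Each cohort's module collection is *tagged* against the seed set: a module is
tagged when its one-sided hypergeometric overlap p-value against the cohort's
own expressed-gene universe falls below 0.05 (raw, not adjusted — the
tagging gate is deliberately permissive because the result only seeds the
network projection; a BH option exists but is off by default). The union of
a cohort's tagged modules is its *super-module*; the intersection of the
super-modules across cohorts is the *core module*, the conserved component
carried forward.

The enrichment universe is each cohort's own universe rather than a global
one: cohorts are profiled on different platforms, and testing a module
against genes the cohort never measured would bias the tail probability.

## Network projection

The core module is projected onto each cohort's directed network: take the
overlap of the module with the network's nodes, expand to every node within
path length *k* of the overlap, and keep the largest connected subgraph with
all induced edges. Conventions:

* **Path length is undirected** for projection (the construction collects a
  regulatory neighborhood, not a flow); the key driver search below uses
  *directed* layers — the two notions are deliberately distinct and both
  exposed.
* *k* = 2 is the default projection depth; *k* = 3 suits smaller,
  cell-type-focused seed signatures.
* **Weak connectivity** defines "connected" (single regulatory components
  mix edge directions).
* Equal-size component ties break toward the component containing the
  lexicographically smallest gene id, so outputs are stable across runs.
* Distance 0 (the seed itself) counts as inside the neighborhood.

## Key driver analysis

Given a gene set *G* and a directed network *N*, candidates are the nodes of
*NG*, the set of nodes within `expand_k` (default 1) undirected layers of
*G*. For each candidate *g* and each layer *h* = 1..*H* (default *H* = 3)
the *h*-layer neighborhood HLN(*g*, *h*) — nodes within directed downstream
distance *h*, excluding *g* itself — is tested for overlap enrichment with
*G* against the full network's node universe. The optimal layer *h\**
maximizes the enrichment statistic over the grid; the hypergeometric
p-value and the fold enrichment at *h\** are both reported. P-values are
Bonferroni-corrected across candidates (BH optional); significant candidates
with no parent node (network roots) are **global** drivers, the rest
**local**.

Design notes:

* **Selection statistic.** The enrichment statistic maximized over the
  *h* grid is, by default, the *significance* of the overlap
  (−log hypergeometric tail p). Maximizing the raw fold instead favors tiny
  noisy layers — a 5/6 overlap at *h* = 1 (fold ≈ 2.4, p ≈ 0.02) beats a
  36/60 overlap at *h* = 3 (fold ≈ 1.7, p ≈ 3×10⁻⁵) — which costs most of
  the method's power. `kda_config(statistic = "fold")` restores raw-fold
  maximization; the reported table carries both fold and p in either mode
  so the two conventions can be compared. Ties prefer the smaller *h*
  (parsimony).
* **Universe.** HLN enrichment is tested against all nodes of the full
  network; using only the projected subnetwork would shrink the universe
  non-conservatively.
* **Self-exclusion.** HLN excludes the candidate itself, preventing
  self-counting inflation when the candidate belongs to *G*.
* The candidate-selection step (maximizing over *h*) mildly inflates the
  per-candidate type-I error; Bonferroni across candidates plus the
  discreteness of the hypergeometric keeps the family-wise rate controlled
  in practice (the null-calibration test measures this directly).

A driver's *predicted signature* (`kdg_signature()`) is its downstream
neighborhood at *k* = 2 — the genes the network claims it controls, and the
validation target for perturbation experiments.

## Composite driver ranking

Each driver's predicted signature is tested against a panel of
disease-evidence gene sets (GWAS lists, case/control expression signatures,
clinical-trait correlates). Within each trait, drivers are ranked by
ascending p-value (average ranks on ties), ranks are normalized by the
driver count, and the composite score is the mean normalized rank across
traits; the final order sorts by composite, breaking ties by mean raw p and
then gene id. Two policies are worth stating:

* A driver with no evidence for a trait (for instance an empty predicted
  signature) receives that trait's *worst* normalized rank — dropping the
  trait instead would reward uninformative drivers.
* Mode `"network_effect"` appends a pseudo-trait that ranks drivers by
  descending regulatory reach, so prioritization can reflect the size of a
  driver's effect on the network as well as disease-set support. Equal
  trait weights are used throughout; no published weighting scheme exists
  to calibrate against, so the choice is the simplest symmetric one.

## Perturbation validation

`validate_prediction()` implements the network-validation statistic: filter
the observed knockout/knockdown signature to its significant genes
(BH-adjusted p < 0.05 — adjusted rather than raw, configurable), intersect
with the universe (out-of-universe genes are dropped with a logged count;
cross-species projections lose genes and silent dropping would corrupt the
fold), and test the overlap with the driver's predicted signature by the
one-sided Fisher test. Gene matching across species is by case-insensitive
symbol equality and is the caller's responsibility; kdnet treats
identifiers as opaque case-sensitive strings.

## eQTL model and polygenic score

For each gene–variant pair a simple linear regression
*y* = α + β*x* + ε, ε ~ N(0, σ²), regresses the inverse-normal-transformed
expression on allele dosage; the Wald test on the OLS estimate of β gives
the p-value (t, *n* − 2 df). A pair is *cis* when the variant lies within
±1 Mb of the gene's coordinate span on the same chromosome (closed
interval, 1-based), *trans* otherwise. The rank-based inverse normal
transform uses the Blom offset 3/8 with average ranks for ties
(configurable; no published choice to match). The permutation null permutes
expression sample identifiers jointly across all genes — preserving
gene–gene correlation — for 3 rounds by default, and the pooled null
p-values yield an empirical FDR curve. No covariates enter the model by
default. Monomorphic variants are skipped with a logged count.

The polygenic risk score is the coefficient-weighted sum of effect-allele
dosages over the intersection of the score's variant panel with the
genotyped variants (the panel is trimmed to what was measured, and the
count of variants used is reported). Dosage orientation is taken as given;
no strand flipping is attempted.

## The synthetic-data generator

`generate_dag()` builds a sparse DAG in a fixed topological order: non-hub
genes are wired preferential-attachment-style (each gene draws a Poisson
number of parents from earlier genes, out-degree-weighted), which produces
emergent secondary regulators; the designated hubs are then placed as roots
on top of the hierarchy, each regulating at least 3 × `mean_out_degree`
targets drawn preferentially (out-degree²) from those secondary regulators.
Hubs are therefore the planted master regulators: root nodes whose influence
cascades deep into the network. Defaults, chosen once as the study
conditions for all calibration runs:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 500 | network size for recovery/ranking calibration |
| `n_hubs` | 10 | planted root regulators |
| `mean_out_degree` | 2 | sparse regulatory wiring |
| edge weight | ±U(0.5, 1) | signed structural coefficients |
| intercepts | U(0.5, 2) | baseline expression |
| `noise_sd` | 1 | homoscedastic Gaussian noise |
| knockout arms | 200 samples | per-arm cohort size |
| seed module | 40 genes | sampled from hub descendants |
| contamination | 0.3 | module corruption rate across cohorts |
| traits | 4 × 60% samples | of the hub-descendant union |

Expression follows the linear structural equations in topological order;
a knockout clamps the target to 0 (the do-operator — a knockout removes the
gene product, it does not rewire downstream regulation) and compares paired
cohorts by Welch t-tests with BH adjustment. Both arms are drawn from a
single seeded RNG stream: R streams seeded with consecutive integers are
not independent, and drawing the arms from seed and seed + 1 measurably
biases the arm comparison. Genotypes are binomial dosages at uniform MAFs;
cis variants are placed inside the ±1 Mb window of their target gene on a
synthetic linear chromosome (trans variants live on a second chromosome),
and cis effects add β × dosage to the target's intercept.

**What the generator does not emulate:** linkage disequilibrium, read-level
noise, heteroscedastic or non-Gaussian expression, feedback loops (the
graph is acyclic by construction), batch effects, and cell-type mixtures.
Passing calibration on these synthetics therefore demonstrates the
*statistical machinery* is correct and powered under the stated model — not
that any particular biological claim transfers to real cohorts.

## Calibration problem sizes

The packaged calibration suite (and `scripts/acceptance.R`) uses these
scales, stated here as the package's own choices:

* Driver recovery and null calibration: 500 genes, 10 hubs, gene set = 60%
  sample of the hub-descendant union, 50 and 100 replicates.
* Knockout validation: 1000-gene networks. At 500 genes a hub's 2-hop
  window covers ~40% of the universe and the Fisher contrast degenerates;
  at 1000 genes the window is a realistic minority. The validated driver is
  the best-expressed significant planted driver — perturbation experiments
  target regulators that are actually expressed, and the knockout of a
  near-silent gene perturbs nothing. Null knockouts target a
  zero-out-degree sink.
* eQTL calibration: 100 genes × 100 variants × 100 samples under the global
  null with an *edgeless* structural model. The binomial interval and
  Kolmogorov–Smirnov yardsticks assume independent tests; SEM-correlated
  expression leaves the marginal level intact but overdisperses the
  10,000-pair count, so calibrating against those yardsticks requires the
  independent-gene null (built with `sem_model()` on a network with no
  edges).
* Ranking: planted hubs must fall in the top decile of the composite rank
  over all KDA candidates in ≥90% of 50 replicates.

## Numerical and degenerate-input choices

* Overlap p-values come from the exact hypergeometric tail
  (`stats::phyper`); an empty overlap reports p = 1, fold 0. When the
  expected overlap is zero and the observed is positive the fold is `Inf`.
* Missing values in matrices are rejected, never imputed — every downstream
  statistic assumes complete data.
* Self-loops are rejected; duplicate edges collapse with a warning.
* A single-gene model, an empty module intersection (warned, then a clear
  downstream error), an all-identical expression vector (inverse-normal is
  undefined and errors), and a signature with no significant genes (warned,
  empty-overlap result) are all handled explicitly.
* All generators and the pipeline are bit-reproducible from their seeds;
  pipeline artifacts carry no timestamps so manifests of checksums are
  byte-identical across reruns.

## Limitations

The KDA enrichment statistic's exact published form is not documented
anywhere we could calibrate against; both the significance-maximizing
default and the fold-maximizing alternative are provided and reported
side by side. Composite ranking weights all evidence tracks equally.
Cross-species identifier mapping, GSEA-style rank enrichment, network
structure learning, module detection, genotype calling and imputation are
all out of scope: networks, module collections and dosages are inputs.
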