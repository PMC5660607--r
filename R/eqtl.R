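#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles by rank: `qnorm((rank - c) / (n + 1 -
#' 2c))` with the Blom offset `c = 3/8`; ties receive average ranks.
#'
#' @param values numeric vector (>= 3 finite values, not all identical).
#' @param c rank offset constant (Blom 3/8 by default).
#' @return numeric vector of the same length.
#' @export
inverse_normal <- function(values, c = 3 / 8) {
  x <- as.numeric(values)
  if (length(x) < 3L || any(!is.finite(x)))
    stop("need at least 3 finite values")
  if (length(unique(x)) == 1L)
    stop("all values identical: ranks carry no information")
  n <- length(x)
  stats::qnorm((rank(x, ties.method = "average") - c) / (n + 1 - 2 * c))
}

#' Detect eQTLs by per-pair linear regression
#'
#' For every gene-variant pair fits the simple linear model
#' \deqn{y_i = \alpha + \beta x_i + \epsilon_i, \quad \epsilon_i \sim
#' N(0, \sigma^2)} where `x` is the effective allele copy number (dosage)
#' and `y` the inverse-normal-transformed expression of the gene; the
#' Wald test on the OLS estimate of beta gives the p-value (t distribution,
#' n - 2 df). A pair is *cis* when the variant lies within
#' `cis_window` bases of the gene's coordinate span on the same
#' chromosome (closed interval, 1-based); all other pairs are *trans*.
#' Monomorphic variants are skipped with a message.
#'
#' @param expression genes x samples matrix.
#' @param genotypes variants x samples dosage matrix, values in [0, 2].
#' @param gene_coords data.frame `gene`, `chrom`, `start`, `end`.
#' @param variant_coords data.frame `variant`, `chrom`, `pos`.
#' @param cis_window half-width of the cis window in bases.
#' @param transform apply [inverse_normal()] per gene (default); set
#'   `FALSE` to regress on the raw scale (e.g. to read `beta_hat` in the
#'   original units).
#' @return data.frame of class `eqtl_results`: `gene`, `variant`,
#'   `beta_hat`, `se`, `wald_p`, `cis`.
#' @export
fit_eqtl <- function(expression, genotypes, gene_coords, variant_coords,
                     cis_window = 1e6, transform = TRUE) {
  shared <- intersect(colnames(expression), colnames(genotypes))
  if (length(shared) < 10L)
    stop("need at least 10 shared sample ids between expression and genotypes")
  Y <- expression[, shared, drop = FALSE]
  X <- genotypes[, shared, drop = FALSE]
  if (any(X < 0 | X > 2)) stop("dosages must lie in [0, 2]")
  mono <- apply(X, 1, function(v) length(unique(v)) == 1L)
  if (any(mono)) {
    message(sum(mono), " monomorphic variant(s) skipped")
    X <- X[!mono, , drop = FALSE]
  }
  if (nrow(X) == 0L) stop("no polymorphic variants")
  n <- length(shared)
  if (transform) Y <- t(apply(Y, 1, inverse_normal))
  # OLS via correlations: beta = r * sy/sx, t = r * sqrt(n-2)/sqrt(1-r^2)
  Xc <- X - rowMeans(X); Yc <- Y - rowMeans(Y)
  sx <- sqrt(rowSums(Xc^2)); sy <- sqrt(rowSums(Yc^2))
  R <- (Yc %*% t(Xc)) / (sy %o% sx)
  R[R > 1] <- 1; R[R < -1] <- -1
  beta <- R * (sy %o% (1 / sx))
  tt <- R * sqrt(n - 2) / sqrt(pmax(1 - R^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  se <- beta / tt
  se[!is.finite(se)] <- NA_real_
  gi <- match(rownames(Y), gene_coords$gene)
  vi <- match(rownames(X), variant_coords$variant)
  if (any(is.na(gi))) stop("genes missing from gene_coords")
  if (any(is.na(vi))) stop("variants missing from variant_coords")
  same_chrom <- outer(gene_coords$chrom[gi], variant_coords$chrom[vi], "==")
  lo <- gene_coords$start[gi] - cis_window
  hi <- gene_coords$end[gi] + cis_window
  pos <- variant_coords$pos[vi]
  cis <- same_chrom &
    outer(lo, pos, `<=`) & outer(hi, pos, `>=`)
  out <- data.frame(
    gene = rep(rownames(Y), times = nrow(X)),
    variant = rep(rownames(X), each = nrow(Y)),
    beta_hat = as.vector(beta), se = as.vector(se),
    wald_p = pmin(as.vector(p), 1), cis = as.vector(cis),
    stringsAsFactors = FALSE)
  class(out) <- c("eqtl_results", class(out))
  out
}

#' Permutation null distribution and empirical FDR for eQTL p-values
#'
#' Re-runs [fit_eqtl()] on datasets in which the expression sample
#' identifiers are permuted jointly across all genes (preserving gene-gene
#' correlation), `n_rounds` times (default 3). Returns the pooled null
#' p-values and an empirical-FDR function: for a threshold t,
#' `FDR(t) = (mean null count <= t) / (observed count <= t)`.
#'
#' @param expression,genotypes,gene_coords,variant_coords,cis_window,transform
#'   as in [fit_eqtl()].
#' @param n_rounds number of permutation rounds (>= 1).
#' @param rng_seed integer seed for the permutations.
#' @return list of class `eqtl_perm`: `observed` (the `eqtl_results` on
#'   unpermuted data), `null_p` (pooled null p-values), `n_rounds`, and
#'   `fdr(t)` (vectorized empirical-FDR function).
#' @export
permutation_null <- function(expression, genotypes, gene_coords,
                             variant_coords, n_rounds = 3, rng_seed = 1,
                             cis_window = 1e6, transform = TRUE) {
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  observed <- fit_eqtl(expression, genotypes, gene_coords, variant_coords,
                       cis_window, transform)
  set.seed(rng_seed)
  shared <- intersect(colnames(expression), colnames(genotypes))
  null_p <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    perm <- sample(shared)
    ep <- expression[, shared, drop = FALSE]
    colnames(ep) <- perm # relabel sample identifiers
    null_p[[r]] <- suppressMessages(
      fit_eqtl(ep, genotypes, gene_coords, variant_coords,
               cis_window, transform))$wald_p
  }
  null_p <- unlist(null_p)
  obs_p <- observed$wald_p
  fdr <- function(t) {
    vapply(t, function(ti) {
      num <- sum(null_p <= ti) / n_rounds
      den <- sum(obs_p <= ti)
      if (den == 0L) NA_real_ else min(num / den, 1)
    }, numeric(1))
  }
  structure(list(observed = observed, null_p = null_p,
                 n_rounds = n_rounds, fdr = fdr),
            class = "eqtl_perm")
}

#' @export
print.eqtl_perm <- function(x, ...) {
  cat("eQTL permutation null:", length(x$null_p), "null p-values over",
      x$n_rounds, "round(s);", nrow(x$observed), "observed pairs\n")
  invisible(x)
}

#' Polygenic risk score model
#'
#' @param entries data.frame with columns `variant`, `effect_allele`,
#'   `coefficient` (unique variants, finite coefficients).
#' @return object of class `prs_model`.
#' @export
prs_model <- function(entries) {
  need <- c("variant", "effect_allele", "coefficient")
  if (!all(need %in% names(entries)))
    stop("PRS model needs columns: ", paste(need, collapse = ", "))
  entries$variant <- as.character(entries$variant)
  if (anyDuplicated(entries$variant)) stop("duplicate variants in PRS model")
  if (any(!is.finite(entries$coefficient)))
    stop("PRS coefficients must be finite")
  structure(list(entries = entries[, need]), class = "prs_model")
}

#' Score samples with a polygenic risk model
#'
#' `score_s = sum_j coefficient_j * dosage_js`, summed over the variants
#' shared between the model and the genotype matrix (the model is trimmed
#' to the genotyped panel; the effect-allele orientation of the dosages is
#' taken as given).
#'
#' @param model a [prs_model].
#' @param genotypes variants x samples dosage matrix.
#' @return named numeric vector of per-sample scores; attribute
#'   `"n_variants_used"` records the size of the trimmed panel.
#' @export
prs_score <- function(model, genotypes) {
  stopifnot(inherits(model, "prs_model"))
  shared <- intersect(model$entries$variant, rownames(genotypes))
  if (length(shared) == 0L)
    stop("no PRS model variants present in the genotype matrix")
  coefs <- model$entries$coefficient[match(shared, model$entries$variant)]
  s <- as.vector(crossprod(genotypes[shared, , drop = FALSE], coefs))
  names(s) <- colnames(genotypes)
  attr(s, "n_variants_used") <- length(shared)
  s
}
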