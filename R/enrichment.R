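#' One-sided overlap enrichment of two gene sets
#'
#' Computes the one-sided (over-enrichment) hypergeometric tail probability
#' of the observed overlap between two gene sets drawn from a common
#' universe — the classic Fisher's exact test on the 2x2 membership table —
#' together with the fold enrichment
#' \deqn{fold = overlap / (|A| |B| / |U|),}
#' observed over expected under independence. When the expected overlap is
#' zero the fold is 0 for an empty overlap and `Inf` otherwise.
#'
#' @param a,b character vectors of gene ids; both must be subsets of
#'   `universe`.
#' @param universe character vector: the background gene universe.
#' @return An object of class `enrichment_result`: a list with
#'   `set_a_size`, `set_b_size`, `universe_size`, `overlap`, `fold`, `p`
#'   and `p_adjusted` (`NA` until a correction is applied externally).
#' @examples
#' u <- paste0("g", 1:100)
#' fisher_overlap(u[1:10], u[6:15], u)
#' @export
fisher_overlap <- function(a, b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  a <- unique(as.character(a)); b <- unique(as.character(b))
  bad_a <- setdiff(a, universe); bad_b <- setdiff(b, universe)
  if (length(bad_a) || length(bad_b))
    stop("set members outside the universe: ",
         paste(utils::head(c(bad_a, bad_b), 10), collapse = ", "))
  o <- length(intersect(a, b))
  U <- length(universe); na <- length(a); nb <- length(b)
  expected <- na * nb / U
  fold <- if (expected > 0) o / expected else if (o > 0) Inf else 0
  # P(X >= o), X ~ Hypergeometric(white = na, black = U - na, drawn = nb)
  p <- if (o == 0L) 1 else stats::phyper(o - 1L, na, U - na, nb, lower.tail = FALSE)
  structure(list(set_a_size = na, set_b_size = nb, universe_size = U,
                 overlap = o, fold = fold, p = min(p, 1), p_adjusted = NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overlap %d of |A|=%d, |B|=%d in U=%d: fold=%.3g, p=%.3g\n",
              x$overlap, x$set_a_size, x$set_b_size, x$universe_size,
              x$fold, x$p))
  invisible(x)
}

#' Multiple-testing correction
#'
#' Bonferroni or Benjamini-Hochberg step-up adjustment, preserving order
#' and clipping to [0, 1].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"bonferroni"` or `"BH"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Validate a network prediction against an observed perturbation signature
#'
#' The network-validation statistic: filters the observed signature to its
#' significant genes (`adjusted_p < alpha`), restricts them to the universe
#' (dropping out-of-universe genes with a message; cross-species
#' projections lose genes and silent dropping would corrupt the fold), and
#' tests their overlap with the predicted gene set by [fisher_overlap()].
#'
#' @param predicted character vector: the network-predicted gene set (e.g. a
#'   driver's bounded downstream neighborhood); must be within `universe`.
#' @param observed_signature a `signature_table` (see [signature_table()]).
#' @param universe background gene universe.
#' @param alpha significance threshold applied to `adjusted_p`.
#' @return an `enrichment_result`.
#' @export
validate_prediction <- function(predicted, observed_signature, universe,
                                alpha = 0.05) {
  stopifnot(inherits(observed_signature, "signature_table"))
  universe <- unique(as.character(universe))
  sig <- observed_signature$gene[observed_signature$adjusted_p < alpha]
  dropped <- setdiff(sig, universe)
  if (length(dropped))
    message(length(dropped), " significant signature gene(s) absent from the ",
            "universe were dropped")
  sig <- intersect(sig, universe)
  if (length(sig) == 0L) {
    warning("no significant signature genes within the universe; ",
            "returning an empty-overlap result")
    return(fisher_overlap(predicted, character(), universe))
  }
  fisher_overlap(predicted, sig, universe)
}
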