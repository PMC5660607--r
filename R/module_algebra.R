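#' Tag a cohort's modules by seed enrichment
#'
#' Tests every module in the collection for one-sided overlap enrichment of
#' the seed gene set against the cohort's own universe and returns the
#' modules whose raw p-value falls below `alpha` (the module-tagging rule;
#' no multiple-testing correction by default, matching the raw P < 0.05
#' gate; set `correct = "BH"` to adjust across the cohort's modules).
#'
#' @param collection a [module_collection].
#' @param seed a [gene_set]: the seed (e.g. a curated immune network gene
#'   list) against which modules are tagged.
#' @param alpha tagging threshold on the (possibly adjusted) p-value.
#' @param correct `"none"` (default) or `"BH"`.
#' @return list with one element per tagged module: `list(set = gene_set,
#'   enrichment = enrichment_result)`; attribute `"all"` holds the full
#'   per-module result table.
#' @export
tag_modules <- function(collection, seed, alpha = 0.05,
                        correct = c("none", "BH")) {
  stopifnot(inherits(collection, "module_collection"),
            inherits(seed, "gene_set"))
  correct <- match.arg(correct)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  seed_in <- intersect(seed$genes, collection$universe)
  if (length(seed_in) == 0L)
    stop("seed set shares no genes with cohort '", collection$cohort,
         "' universe; check gene identifiers")
  res <- lapply(collection$modules, function(m)
    fisher_overlap(m$genes, seed_in, collection$universe))
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- if (correct == "BH") adjust_pvalues(p, "BH") else p
  for (i in seq_along(res)) res[[i]]$p_adjusted <- padj[i]
  tagged_flag <- if (alpha >= 1) rep(TRUE, length(padj)) else padj < alpha
  tab <- data.frame(
    module = vapply(collection$modules, `[[`, character(1), "name"),
    size = vapply(res, `[[`, numeric(1), "set_a_size"),
    overlap = vapply(res, `[[`, numeric(1), "overlap"),
    fold = vapply(res, `[[`, numeric(1), "fold"),
    p = p, p_adjusted = padj, tagged = tagged_flag,
    stringsAsFactors = FALSE)
  keep <- which(tab$tagged)
  out <- lapply(keep, function(i)
    list(set = collection$modules[[i]], enrichment = res[[i]]))
  attr(out, "all") <- tab
  attr(out, "cohort") <- collection$cohort
  out
}

#' Union of tagged modules: the cohort super-module
#'
#' @param tagged output of [tag_modules()] (or a plain list of [gene_set]).
#' @param cohort cohort label for the result name; defaults to the label
#'   recorded by [tag_modules()].
#' @return a [gene_set] named `"<cohort>_super"`.
#' @export
super_module <- function(tagged, cohort = NULL) {
  if (length(tagged) == 0L)
    stop("no tagged modules: cannot form a super-module")
  sets <- lapply(tagged, function(x) if (inherits(x, "gene_set")) x else x$set)
  if (is.null(cohort)) cohort <- attr(tagged, "cohort")
  if (is.null(cohort)) cohort <- "cohort"
  gene_set(paste0(cohort, "_super"),
           sort(unique(unlist(lapply(sets, `[[`, "genes")))),
           "union of seed-tagged modules")
}

#' Cross-cohort core module
#'
#' Intersects the per-cohort super-modules: the conserved component shared
#' by all cohorts, used as the seed set for network projection.
#'
#' @param supers list of at least two [gene_set] super-modules.
#' @param name name of the resulting set.
#' @return a [gene_set]; empty intersection is returned with a warning
#'   (downstream projection then fails with a clear message).
#' @export
core_module <- function(supers, name = "core_module") {
  if (length(supers) < 2L)
    stop("core module requires super-modules from at least 2 cohorts")
  stopifnot(all(vapply(supers, inherits, logical(1), "gene_set")))
  genes <- Reduce(intersect, lapply(supers, `[[`, "genes"))
  if (length(genes) == 0L)
    warning("super-modules have an empty intersection; core module is empty")
  gene_set(name, sort(genes), "cross-cohort intersection of super-modules")
}
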