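#' Named gene set
#'
#' @param name non-empty set name.
#' @param genes character vector of gene ids; duplicates are removed.
#' @param description free-text description (GMT column 2).
#' @return An object of class `gene_set` with elements `name`, `genes`,
#'   `description`.
#' @export
gene_set <- function(name, genes, description = "") {
  name <- as.character(name)
  if (length(name) != 1L || !nzchar(name)) stop("gene set needs a non-empty name")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) genes <- unique(genes)
  structure(list(name = name, genes = genes, description = as.character(description)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Per-cohort module collection
#'
#' A cohort's coexpression modules plus the cohort's own expressed-gene
#' universe. Every module must be contained in the universe and module names
#' must be unique within the cohort.
#'
#' @param cohort cohort label.
#' @param modules list of [gene_set] objects.
#' @param universe character vector: the cohort's gene universe.
#' @return An object of class `module_collection`.
#' @export
module_collection <- function(cohort, modules, universe) {
  cohort <- as.character(cohort)
  if (length(cohort) != 1L || !nzchar(cohort)) stop("cohort label required")
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (!all(vapply(modules, inherits, logical(1), "gene_set")))
    stop("`modules` must be a list of gene_set objects")
  nm <- vapply(modules, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("module names must be unique within a cohort")
  for (m in modules) {
    out <- setdiff(m$genes, universe)
    if (length(out))
      stop("module '", m$name, "' has genes outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }
  structure(list(cohort = cohort, modules = modules, universe = universe),
            class = "module_collection")
}

#' @export
print.module_collection <- function(x, ...) {
  cat("Module collection '", x$cohort, "': ", length(x$modules),
      " modules, universe of ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}
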