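#' Per-trait evidence for a single driver
#'
#' For each disease-evidence gene set (trait), tests the overlap of the
#' driver's predicted signature ([kdg_signature()], path length `k`) with
#' the trait set by [fisher_overlap()] against the shared universe.
#'
#' @param net a [gene_network].
#' @param driver gene id present in the network.
#' @param trait_sets list of [gene_set] disease-evidence sets.
#' @param universe background gene universe (defaults to the network
#'   nodes); trait genes outside it are dropped.
#' @param k downstream path-length bound for the driver signature.
#' @return named list of `enrichment_result`, one per trait.
#' @export
trait_evidence <- function(net, driver, trait_sets, universe = NULL, k = 2) {
  stopifnot_network(net)
  if (!driver %in% net$nodes) stop("unknown driver: ", driver)
  if (is.null(universe)) universe <- net$nodes
  sig <- intersect(kdg_signature(net, driver, k), universe)
  out <- lapply(trait_sets, function(ts)
    fisher_overlap(sig, intersect(ts$genes, universe), universe))
  names(out) <- vapply(trait_sets, `[[`, character(1), "name")
  out
}

#' Composite rank aggregation of key drivers across disease traits
#'
#' Within each trait, drivers are ranked by ascending enrichment p-value
#' (average ranks for ties) and ranks are normalized by the driver count
#' to [0, 1]; the composite score is the mean of the normalized per-trait
#' ranks and the final rank orders drivers by ascending composite (ties
#' broken by mean raw p, then gene id). Drivers with missing evidence for
#' a trait (e.g. an empty predicted signature) receive that trait's worst
#' normalized rank, so uninformative drivers are not rewarded.
#'
#' Mode `"network_effect"` adds one pseudo-trait ranking drivers by
#' descending regulatory reach (`sizes`, e.g. the KDA neighborhood size),
#' so prioritization also reflects the size of a driver's effect on the
#' network, not only disease-set support.
#'
#' @param evidence named list (per driver) of named lists (per trait) of
#'   `enrichment_result`, as built from [trait_evidence()].
#' @param mode `"equal"` (default) or `"network_effect"`.
#' @param sizes named numeric vector of per-driver regulatory reach;
#'   required for mode `"network_effect"`.
#' @return An object of class `ranked_drivers`: data.frame with one row
#'   per driver — `gene`, one `p_<trait>` and `rank_<trait>` column pair
#'   per trait, `composite`, `final_rank` — sorted by `final_rank`.
#' @export
composite_rank <- function(evidence, mode = c("equal", "network_effect"),
                           sizes = NULL) {
  mode <- match.arg(mode)
  if (length(evidence) == 0L) stop("empty evidence")
  drivers <- names(evidence)
  traits <- names(evidence[[1]])
  if (length(traits) == 0L) stop("no traits in evidence")
  P <- matrix(NA_real_, nrow = length(drivers), ncol = length(traits),
              dimnames = list(drivers, traits))
  for (g in drivers)
    for (tr in traits) {
      e <- evidence[[g]][[tr]]
      if (!is.null(e)) P[g, tr] <- e$p
    }
  n <- length(drivers)
  R <- apply(P, 2, function(p) {
    r <- rank(p, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- n # missing evidence gets the worst rank
    r / n
  })
  if (!is.matrix(R)) R <- matrix(R, nrow = n, dimnames = dimnames(P))
  if (mode == "network_effect") {
    if (is.null(sizes)) stop("mode 'network_effect' needs per-driver `sizes`")
    s <- sizes[drivers]
    s[is.na(s)] <- 0
    R <- cbind(R, network_effect = rank(-s, ties.method = "average") / n)
  }
  composite <- rowMeans(R)
  mean_p <- rowMeans(P, na.rm = TRUE)
  mean_p[is.nan(mean_p)] <- 1
  ord <- order(composite, mean_p, drivers)
  out <- data.frame(gene = drivers, stringsAsFactors = FALSE)
  for (tr in traits) {
    out[[paste0("p_", tr)]] <- P[, tr]
    out[[paste0("rank_", tr)]] <- R[, tr]
  }
  out$composite <- composite
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(n)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("ranked_drivers", class(out))
  out
}

#' Rank a set of drivers by trait evidence
#'
#' Convenience wrapper: computes [trait_evidence()] for every driver, then
#' [composite_rank()].
#'
#' @param net a [gene_network].
#' @param drivers character vector of driver gene ids.
#' @param trait_sets list of [gene_set] disease-evidence sets.
#' @param universe background universe; defaults to network nodes.
#' @param k driver-signature path-length bound.
#' @param mode,sizes passed to [composite_rank()]; for
#'   `"network_effect"`, `sizes` defaults to each driver's signature size.
#' @return a `ranked_drivers` data.frame.
#' @export
rank_drivers <- function(net, drivers, trait_sets, universe = NULL, k = 2,
                         mode = "equal", sizes = NULL) {
  drivers <- unique(as.character(drivers))
  ev <- lapply(drivers, function(g)
    trait_evidence(net, g, trait_sets, universe, k))
  names(ev) <- drivers
  if (identical(mode, "network_effect") && is.null(sizes))
    sizes <- stats::setNames(
      vapply(drivers, function(g) length(kdg_signature(net, g, k)), numeric(1)),
      drivers)
  composite_rank(ev, mode = mode, sizes = sizes)
}
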