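#' @title End-to-end analysis pipeline
#' @description Orchestrates simulate/ingest -> core module -> projection ->
#'   key driver analysis -> composite ranking -> perturbation validation
#'   under one YAML configuration, writing every intermediate artifact, a
#'   parameter-echo log and an md5 checksum manifest to a run directory.
#'   Stage contracts are file-based, so real cohort networks and module
#'   GMTs can be substituted for the simulated ones without code changes.
#' @name kdnet-pipeline
NULL

.pipeline_defaults <- list(
  simulate = list(n_genes = 500, n_hubs = 10, mean_out_degree = 2,
                  n_samples = 200, n_cohorts = 3, contamination = 0.3,
                  n_decoys = 8, universe_jitter = 0.02, seed_size = 40,
                  n_traits = 4, trait_rate = 0.6, seed = 1),
  core = list(alpha = 0.05),
  project = list(k = 2),
  kda = list(h_max = 3, alpha = 0.05, correction = "bonferroni",
             direction = "downstream", expand_k = 1),
  rank = list(k = 2, mode = "equal"),
  validate = list(k = 2, alpha = 0.05, top_n = 3))

.merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      .merge_config(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  defaults
}

.log_line <- function(con, ...) {
  line <- paste0(...)
  writeLines(line, con)
  message(line)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: `simulate` (generate network, module collections,
#' trait sets and truth from a seed — or ingest the files named in an
#' `inputs:` block), `core` (tag modules per cohort, form super-modules,
#' intersect into the core module), `project` (core module onto the
#' network, path length `k`), `kda` (key driver analysis on the projected
#' component's gene set), `rank` (composite rank across trait sets) and
#' `validate` (simulated knockout of the top drivers tested against their
#' predicted signatures). Each stage writes its artifacts before the next
#' starts, and a completed stage is skipped on rerun when `resume = TRUE`.
#' All parameters echo into `run.log` and `manifest.tsv` records an md5
#' checksum per artifact (logs excluded), so identical configurations and
#' seeds yield byte-identical manifests.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Any subset of the keys in the defaults may be given; a
#'   `simulate:` block (with its `seed`) drives synthetic runs, or an
#'   `inputs:` block (`network`, `modules` [vector of GMT paths],
#'   `seed_set`, `traits`) ingests real data.
#' @param out_dir run directory to create (default `kdnet_run` under the
#'   current directory).
#' @param resume skip stages whose artifacts already exist.
#' @return `out_dir`, invisibly; artifacts: `network.tsv`,
#'   `modules_<cohort>.gmt`, `traits.gmt`, `truth.txt`, `core_module.gmt`,
#'   `subnetwork.tsv`, `kda.tsv`, `ranked.tsv`, `validation.tsv`,
#'   `manifest.tsv`, `run.log`.
#' @export
run_pipeline <- function(config, out_dir = "kdnet_run", resume = FALSE) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- .merge_config(.pipeline_defaults, user)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, if (resume) "a" else "w")
  on.exit(close(con))
  .log_line(con, "kdnet pipeline v", .kdnet_version())
  .log_line(con, "config: ", paste(utils::capture.output(utils::str(cfg)),
                                   collapse = " | "))
  pth <- function(f) file.path(out_dir, f)
  done <- function(f) resume && file.exists(pth(f))
  artifacts <- character()
  fail <- function(stage, msg) stop("pipeline stage '", stage, "' failed: ",
                                    msg, call. = FALSE)

  # --- stage: simulate or ingest -------------------------------------
  simulate_mode <- is.null(cfg$inputs)
  if (simulate_mode) {
    s <- cfg$simulate
    if (!done("truth.txt")) {
      .log_line(con, "[simulate] n_genes=", s$n_genes, " n_hubs=", s$n_hubs,
                " seed=", s$seed)
      sem <- generate_dag(s$n_genes, s$n_hubs, s$mean_out_degree,
                          rng_seed = s$seed)
      truth <- make_truth(sem, seed_size = s$seed_size, rng_seed = s$seed + 1L)
      cols <- generate_module_collections(
        truth, n_cohorts = s$n_cohorts, contamination = s$contamination,
        rng_seed = s$seed + 2L, n_decoys = s$n_decoys,
        universe_jitter = s$universe_jitter)
      traits <- make_trait_sets(truth, n_traits = s$n_traits,
                                rate = s$trait_rate, rng_seed = s$seed + 3L)
      write_network(sem$network, pth("network.tsv"))
      for (mc in cols) {
        write_gmt(mc$modules, pth(sprintf("modules_%s.gmt", mc$cohort)))
        write_gmt(gene_set(paste0(mc$cohort, "_universe"), mc$universe),
                  pth(sprintf("universe_%s.gmt", mc$cohort)))
      }
      write_gmt(gene_set("seed_set", truth$seed_module), pth("seed_set.gmt"))
      write_gmt(traits, pth("traits.gmt"))
      write_truth(truth, pth("truth.txt"))
    } else .log_line(con, "[simulate] resumed, artifacts present")
    net <- read_network(pth("network.tsv"))
    cohorts <- sprintf("cohort%d", seq_len(cfg$simulate$n_cohorts))
    collections <- lapply(cohorts, function(cc)
      module_collection(cc, read_gmt(pth(sprintf("modules_%s.gmt", cc))),
                        read_gmt(pth(sprintf("universe_%s.gmt", cc)))[[1]]$genes))
    seed_set <- read_gmt(pth("seed_set.gmt"))[[1]]
    traits <- read_gmt(pth("traits.gmt"))
    sem <- NULL # reconstructed below only when validation needs it
    artifacts <- c(artifacts, "network.tsv", "seed_set.gmt", "traits.gmt",
                   "truth.txt",
                   sprintf("modules_%s.gmt", cohorts),
                   sprintf("universe_%s.gmt", cohorts))
  } else {
    ing <- cfg$inputs
    for (need in c("network", "modules", "seed_set", "traits"))
      if (is.null(ing[[need]])) fail("ingest", paste("missing input:", need))
    .log_line(con, "[ingest] network=", ing$network)
    net <- read_network(ing$network)
    collections <- lapply(seq_along(ing$modules), function(i) {
      mods <- read_gmt(ing$modules[[i]])
      module_collection(sprintf("cohort%d", i), mods,
                        unique(unlist(lapply(mods, `[[`, "genes"))))
    })
    seed_set <- read_gmt(ing$seed_set)[[1]]
    traits <- read_gmt(ing$traits)
  }

  # --- stage: core module --------------------------------------------
  if (!done("core_module.gmt")) {
    .log_line(con, "[core] alpha=", cfg$core$alpha)
    supers <- lapply(collections, function(mc) {
      tg <- tryCatch(tag_modules(mc, seed_set, alpha = cfg$core$alpha),
                     error = function(e) fail("core", conditionMessage(e)))
      if (length(tg) == 0L)
        fail("core", paste0("no modules tagged in ", mc$cohort))
      super_module(tg)
    })
    core <- core_module(supers)
    if (length(core$genes) == 0L)
      fail("core", "super-modules have an empty intersection")
    write_gmt(c(supers, list(core)), pth("core_module.gmt"))
    .log_line(con, "[core] core module size=", length(core$genes))
  }
  sets <- read_gmt(pth("core_module.gmt"))
  core <- sets[[length(sets)]]
  artifacts <- c(artifacts, "core_module.gmt")

  # --- stage: projection ---------------------------------------------
  if (!done("subnetwork.tsv")) {
    .log_line(con, "[project] k=", cfg$project$k)
    sub <- tryCatch(project_seed(net, core, k = cfg$project$k),
                    error = function(e) fail("project", conditionMessage(e)))
    write_network(sub$network, pth("subnetwork.tsv"))
    .log_line(con, "[project] component size=", length(sub$nodes))
  }
  sub_net <- read_network(pth("subnetwork.tsv"))
  artifacts <- c(artifacts, "subnetwork.tsv")

  # --- stage: key driver analysis ------------------------------------
  if (!done("kda.tsv")) {
    kcfg <- kda_config(cfg$kda$h_max, cfg$kda$alpha, cfg$kda$correction,
                       cfg$kda$direction, cfg$kda$expand_k)
    .log_line(con, "[kda] H=", kcfg$h_max, " correction=", kcfg$correction)
    fit <- tryCatch(kda(net, sub_net$nodes, kcfg),
                    error = function(e) fail("kda", conditionMessage(e)))
    utils::write.table(fit$results, pth("kda.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log_line(con, "[kda] significant drivers=", length(fit$drivers))
  }
  kda_tab <- utils::read.delim(pth("kda.tsv"), stringsAsFactors = FALSE)
  artifacts <- c(artifacts, "kda.tsv")

  # --- stage: composite ranking --------------------------------------
  if (!done("ranked.tsv")) {
    .log_line(con, "[rank] k=", cfg$rank$k, " mode=", cfg$rank$mode)
    drivers <- kda_tab$gene[kda_tab$driver_class != "none"]
    if (length(drivers) == 0L) {
      .log_line(con, "[rank] no significant drivers; empty ranking")
      utils::write.table(
        data.frame(gene = character(), composite = numeric(),
                   final_rank = integer()),
        pth("ranked.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      ranked <- rank_drivers(net, drivers, traits, k = cfg$rank$k,
                             mode = cfg$rank$mode)
      utils::write.table(as.data.frame(ranked), pth("ranked.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  ranked_tab <- utils::read.delim(pth("ranked.tsv"), stringsAsFactors = FALSE)
  artifacts <- c(artifacts, "ranked.tsv")

  # --- stage: perturbation validation (synthetic runs only) ----------
  if (!done("validation.tsv")) {
    if (simulate_mode && nrow(ranked_tab) > 0L) {
      s <- cfg$simulate
      sem <- generate_dag(s$n_genes, s$n_hubs, s$mean_out_degree,
                          rng_seed = s$seed)
      top <- utils::head(ranked_tab$gene, cfg$validate$top_n)
      .log_line(con, "[validate] knockouts: ", paste(top, collapse = ", "))
      rows <- lapply(seq_along(top), function(i) {
        g <- top[i]
        sig <- simulate_knockout(sem, g, n_samples = s$n_samples,
                                 rng_seed = s$seed + 10L + i)
        pred <- kdg_signature(net, g, k = cfg$validate$k)
        er <- suppressWarnings(
          validate_prediction(pred, sig, net$nodes, cfg$validate$alpha))
        data.frame(gene = g, predicted_size = length(pred),
                   overlap = er$overlap, fold = er$fold, p = er$p,
                   significant = er$p < cfg$validate$alpha,
                   stringsAsFactors = FALSE)
      })
      vt <- do.call(rbind, rows)
    } else {
      vt <- data.frame(gene = character(), predicted_size = integer(),
                       overlap = integer(), fold = numeric(), p = numeric(),
                       significant = logical())
    }
    utils::write.table(vt, pth("validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  artifacts <- c(artifacts, "validation.tsv")

  # --- manifest -------------------------------------------------------
  artifacts <- sort(unique(artifacts[file.exists(file.path(out_dir, artifacts))]))
  sums <- tools::md5sum(file.path(out_dir, artifacts))
  manifest <- data.frame(artifact = artifacts, md5 = unname(sums),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, pth("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .log_line(con, "pipeline complete: ", length(artifacts), " artifacts")
  invisible(out_dir)
}

#' Summarize a completed pipeline run
#'
#' One row per ranked driver: final rank, composite score, per-trait
#' significance flags (trait enrichment p < `alpha`), and the perturbation
#' validation outcome where available.
#'
#' @param run_dir a directory written by [run_pipeline()].
#' @param alpha significance threshold for the per-trait flags.
#' @return data.frame, one row per driver, ordered by final rank.
#' @export
pipeline_report <- function(run_dir, alpha = 0.05) {
  need <- c("ranked.tsv", "kda.tsv", "validation.tsv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("incomplete run directory; missing: ", paste(missing, collapse = ", "))
  ranked <- utils::read.delim(file.path(run_dir, "ranked.tsv"),
                              stringsAsFactors = FALSE)
  if (nrow(ranked) == 0L)
    return(data.frame(gene = character(), final_rank = integer(),
                      composite = numeric(), validated = logical()))
  kda_tab <- utils::read.delim(file.path(run_dir, "kda.tsv"),
                               stringsAsFactors = FALSE)
  val <- utils::read.delim(file.path(run_dir, "validation.tsv"),
                           stringsAsFactors = FALSE)
  pcols <- grep("^p_", names(ranked), value = TRUE)
  out <- data.frame(gene = ranked$gene, final_rank = ranked$final_rank,
                    composite = ranked$composite, stringsAsFactors = FALSE)
  for (pc in pcols)
    out[[sub("^p_", "sig_", pc)]] <- !is.na(ranked[[pc]]) & ranked[[pc]] < alpha
  out$driver_class <- kda_tab$driver_class[match(out$gene, kda_tab$gene)]
  out$validated <- ifelse(out$gene %in% val$gene,
                          val$significant[match(out$gene, val$gene)], NA)
  out[order(out$final_rank), , drop = FALSE]
}
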