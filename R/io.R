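#' @title File input/output for networks, gene sets, matrices and signatures
#' @description Readers validate strictly (malformed lines, self-loops,
#'   missing values and duplicate labels are errors); writers emit a `#`
#'   header comment carrying the tool version and the writer's parameters,
#'   which all readers skip.
#' @name kdnet-io
NULL

.kdnet_version <- function() {
  v <- tryCatch(as.character(utils::packageVersion("kdnet")),
                error = function(e) "0.0")
  v
}

.header_lines <- function(what, params = character()) {
  h <- paste0("# kdnet v", .kdnet_version(), " ", what)
  if (length(params))
    h <- c(h, paste0("# ", names(params), "=", unname(params)))
  h
}

.read_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", x)
  structure(x[keep], lineno = which(keep))
}

#' Read a directed network from an edge list or SIF file
#'
#' Edge-list dialect: one edge per line, `parent<TAB>child[<TAB>weight]`.
#' SIF dialect: `source<TAB>relation<TAB>target1[<TAB>target2 ...]` fans out
#' to one edge per target. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param dialect `"edgelist"` or `"sif"`.
#' @return a [gene_network].
#' @export
read_network <- function(path, dialect = c("edgelist", "sif")) {
  dialect <- match.arg(dialect)
  lines <- .read_lines(path)
  lineno <- attr(lines, "lineno")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0L) stop("no edges in ", path)
  parent <- character(); child <- character(); weight <- numeric()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "[\t ]+")[[1]]
    if (dialect == "edgelist") {
      if (length(f) < 2L)
        stop("malformed edge line ", lineno[i], " in ", path, ": ", lines[[i]])
      w <- if (length(f) >= 3L) suppressWarnings(as.numeric(f[3])) else NA_real_
      if (length(f) >= 3L && is.na(w))
        stop("non-numeric weight on line ", lineno[i], " in ", path)
      parent <- c(parent, f[1]); child <- c(child, f[2]); weight <- c(weight, w)
    } else {
      if (length(f) < 3L)
        stop("malformed SIF line ", lineno[i], " in ", path, ": ", lines[[i]])
      tg <- f[-(1:2)]
      parent <- c(parent, rep(f[1], length(tg)))
      child <- c(child, tg)
      weight <- c(weight, rep(NA_real_, length(tg)))
    }
  }
  net <- gene_network(data.frame(parent = parent, child = child,
                                 weight = weight, stringsAsFactors = FALSE))
  # the writer records isolated nodes (no incident edges) in the header
  iso_line <- grep("^# isolated=", readLines(path, warn = FALSE), value = TRUE)
  if (length(iso_line)) {
    iso <- strsplit(sub("^# isolated=", "", iso_line[1]), ",", fixed = TRUE)[[1]]
    iso <- iso[nzchar(iso)]
    if (length(iso))
      net <- gene_network(net$edges, nodes = c(net$nodes, iso))
  }
  net
}

#' Write a network as a tab-separated edge list
#'
#' @param net a [gene_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot_network(net)
  e <- net$edges
  w <- ifelse(is.na(e$weight), "", sprintf("%.10g", e$weight))
  body <- ifelse(nzchar(w),
                 paste(e$parent, e$child, w, sep = "\t"),
                 paste(e$parent, e$child, sep = "\t"))
  iso <- setdiff(net$nodes, c(e$parent, e$child))
  hdr <- .header_lines("edge list",
                       c(nodes = length(net$nodes), edges = nrow(e),
                         isolated = paste(iso, collapse = ",")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`, one set per line.
#' Duplicate genes within a line are deduplicated with a warning.
#'
#' @param path file path.
#' @return list of [gene_set].
#' @export
read_gmt <- function(path) {
  lines <- .read_lines(path)
  lineno <- attr(lines, "lineno")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", lineno[i], " in ", path, " has fewer than 3 fields")
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", f[1], "' deduplicated")
      genes <- unique(genes)
    }
    sets[[i]] <- gene_set(f[1], genes, f[2])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  body <- vapply(sets, function(s)
    paste(c(s$name, if (nzchar(s$description)) s$description else ".", s$genes),
          collapse = "\t"), character(1))
  writeLines(c(.header_lines("GMT", c(sets = length(sets))), body), path)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' First row: sample ids; first column: gene/variant ids. All cells must be
#' finite numbers (missing values are rejected, not imputed) and row/column
#' labels must be unique.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  lines <- .read_lines(path)
  if (length(lines) < 1L) stop("empty matrix file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  cols <- header[-1]
  if (anyDuplicated(cols)) stop("duplicate column label(s) in ", path)
  n <- length(lines) - 1L
  if (n < 1L) stop("matrix has no data rows: ", path)
  rows <- character(n)
  m <- matrix(NA_real_, nrow = n, ncol = length(cols))
  for (i in seq_len(n)) {
    f <- fields[[i + 1L]]
    if (length(f) != length(cols) + 1L)
      stop("row ", i, " of ", path, " has ", length(f) - 1L,
           " values; expected ", length(cols))
    rows[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or missing cell at row '", f[1], "', column '",
           cols[bad[1]], "' in ", path)
    m[i, ] <- v
  }
  if (anyDuplicated(rows)) stop("duplicate row label(s) in ", path)
  dimnames(m) <- list(rows, cols)
  m
}

#' Write a labeled numeric matrix to TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param what label for the header comment.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, what = "matrix") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- c(paste(c("id", colnames(m)), collapse = "\t"),
            vapply(seq_len(nrow(m)), function(i)
              paste(c(rownames(m)[i], sprintf("%.10g", m[i, ])), collapse = "\t"),
              character(1)))
  writeLines(c(.header_lines(what, c(rows = nrow(m), cols = ncol(m))), body), path)
  invisible(path)
}

#' Read a differential-expression signature table from TSV
#'
#' Columns: `gene`, `effect`, `p_value`, `adjusted_p`. Gene ids must be
#' unique and p-values in [0, 1].
#'
#' @param path file path.
#' @return data.frame of class `signature_table`.
#' @export
read_signature <- function(path) {
  lines <- .read_lines(path)
  con <- textConnection(lines)
  on.exit(close(con))
  d <- utils::read.delim(con, stringsAsFactors = FALSE)
  signature_table(d)
}

#' Construct/validate a signature table
#'
#' @param d data.frame with columns `gene`, `effect`, `p_value`, `adjusted_p`.
#' @return `d` with class `signature_table` prepended.
#' @export
signature_table <- function(d) {
  need <- c("gene", "effect", "p_value", "adjusted_p")
  if (!all(need %in% names(d)))
    stop("signature table needs columns: ", paste(need, collapse = ", "))
  d$gene <- as.character(d$gene)
  if (anyDuplicated(d$gene)) stop("duplicate gene ids in signature table")
  for (cc in c("p_value", "adjusted_p"))
    if (any(d[[cc]] < 0 | d[[cc]] > 1, na.rm = TRUE))
      stop(cc, " outside [0, 1]")
  class(d) <- unique(c("signature_table", class(d)))
  d
}

#' Write a signature table to TSV
#'
#' @param sig a `signature_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  body <- c(paste(c("gene", "effect", "p_value", "adjusted_p"), collapse = "\t"),
            vapply(seq_len(nrow(sig)), function(i)
              paste(c(sig$gene[i], sprintf("%.10g", sig$effect[i]),
                      sprintf("%.10g", sig$p_value[i]),
                      sprintf("%.10g", sig$adjusted_p[i])), collapse = "\t"),
              character(1)))
  writeLines(c(.header_lines("signature", c(genes = nrow(sig))), body), path)
  invisible(path)
}

#' Write planted ground truth to a key-value text file
#'
#' One `key<TAB>value` pair per line; set-valued fields are comma-joined.
#' Edge weights and coordinates are carried in their own files; this records
#' the identities needed to score recovery (planted drivers, seed module,
#' cis effects, the RNG seed).
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  kv <- c(
    rng_seed = as.character(truth$rng_seed),
    planted_drivers = paste(truth$planted_drivers, collapse = ","),
    seed_module = paste(truth$seed_module, collapse = ","),
    cis_effects = if (is.null(truth$cis_effects) || nrow(truth$cis_effects) == 0L) ""
      else paste(sprintf("%s:%s:%.10g", truth$cis_effects$variant,
                         truth$cis_effects$gene, truth$cis_effects$beta),
                 collapse = ","))
  writeLines(c(.header_lines("truth"),
               paste(names(kv), unname(kv), sep = "\t")), path)
  invisible(path)
}

#' Read a planted-truth key-value file written by [write_truth()]
#'
#' @param path file path.
#' @return list with `rng_seed`, `planted_drivers`, `seed_module`,
#'   `cis_effects` (data.frame).
#' @export
read_truth <- function(path) {
  lines <- .read_lines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1L) x[2] else "", character(1))
  names(vals) <- keys
  split_csv <- function(x) if (nzchar(x)) strsplit(x, ",", fixed = TRUE)[[1]] else character()
  ce <- split_csv(vals[["cis_effects"]])
  ced <- if (length(ce)) {
    parts <- strsplit(ce, ":", fixed = TRUE)
    data.frame(variant = vapply(parts, `[`, character(1), 1),
               gene = vapply(parts, `[`, character(1), 2),
               beta = as.numeric(vapply(parts, `[`, character(1), 3)),
               stringsAsFactors = FALSE)
  } else data.frame(variant = character(), gene = character(), beta = numeric())
  list(rng_seed = as.integer(vals[["rng_seed"]]),
       planted_drivers = split_csv(vals[["planted_drivers"]]),
       seed_module = split_csv(vals[["seed_module"]]),
       cis_effects = ced)
}
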