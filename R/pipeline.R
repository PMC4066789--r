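# End-to-end pipeline over TSV inputs: stats -> classify -> enrichment ->
# plasmid scores -> class-restricted distances, with a manifest that makes a
# run reproducible and lets an unchanged rerun skip recomputation.

#' Read a family-by-genome TSV table
#'
#' Expects a header row of genome ids and a first column of family ids;
#' remaining cells must be non-negative integers. Malformed cells are
#' reported with their row and column.
#'
#' @param path TSV file path.
#' @return Integer matrix with family ids as rownames.
#' @export
read_abundance_matrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(path, ": expected a family_id column plus counts")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (is.character(m)) {
    suppress <- matrix(suppressWarnings(as.numeric(m) ), nrow(m),
                       dimnames = dimnames(m))
    bad <- which(is.na(suppress) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(path, ": non-numeric cell at row ", bad[1, 1] + 1L,
           " (family ", ids[bad[1, 1]], "), column ",
           colnames(m)[bad[1, 2]])
    m <- matrix(suppress, nrow = nrow(m), dimnames = dimnames(m))
  }
  bad <- which(is.na(m) | m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(path, ": cell at row ", bad[1, 1] + 1L, " (family ",
         ids[bad[1, 1]], "), column ", colnames(m)[bad[1, 2]],
         " is not a non-negative integer")
  rownames(m) <- ids
  as_abundance_matrix(m)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "family_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a flat key-value pipeline configuration file
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` starts a
#' comment. Values that parse as numbers become numeric; `true`/`false`
#' become logical.
#'
#' @param path configuration file path.
#' @return Named list of settings for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
                  else if (tolower(val) %in% c("true", "false"))
                    as.logical(toupper(val))
                  else val
  }
  out
}

default_pipeline_config <- function() {
  list(matrix = NULL, transfers = NULL, annotations = NULL, plasmid = NULL,
       reference_distance = NULL, out_dir = "famfluct_run",
       bin_width = 390, bin_step = 100, v_max = 450, min_bin = 10,
       include_zeros = TRUE, q_cap = 5, q_low = -0.43, q_high = 1,
       w_min = 0.38, alpha = 0.01, metric = "jaccard", pseudocount = 0.5,
       trend_bins = 10)
}

manifest_lines <- function(config, inputs) {
  params <- config[setdiff(names(config), c("matrix", "transfers",
                                            "annotations", "plasmid",
                                            "reference_distance",
                                            "out_dir"))]
  p <- vapply(names(params), function(k) paste0("param\t", k, "\t",
                                                params[[k]]), character(1))
  i <- vapply(names(inputs), function(k) paste0("input\t", k, "\t",
                                                inputs[[k]], "\t",
                                                unname(tools::md5sum(inputs[[k]]))),
              character(1))
  c(sort(unname(p)), sort(unname(i)))
}

#' Run the full abundance-fluctuation pipeline
#'
#' Reads the abundance matrix (and any optional transfer / annotation /
#' plasmid / reference-distance inputs), computes the per-family statistics,
#' classifies families, runs category enrichment, plasmid scores and
#' class-restricted distances, and writes every stage as TSV under
#' `out_dir`, together with `manifest.txt` (effective parameters plus input
#' checksums) and a run log. If the manifest of a previous run matches and
#' all outputs exist, the computation is skipped.
#'
#' @param config named list (see [read_pipeline_config()] for the file
#'   form). Required: `matrix`. Optional inputs: `transfers`, `annotations`
#'   (TSV with family_id, category), `plasmid` (TSV with family_id, plasmid,
#'   background), `reference_distance` (square TSV). All stage parameters of
#'   [family_stats()], [classify_families()], [category_enrichment()] can be
#'   overridden.
#' @return Invisibly, a list with the computed objects and the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  config <- modifyList(default_pipeline_config(), config)
  if (is.null(config$matrix)) stop("config$matrix (abundance TSV) is required")

  inputs <- list(matrix = config$matrix)
  for (k in c("transfers", "annotations", "plasmid", "reference_distance"))
    if (!is.null(config[[k]])) inputs[[k]] <- config[[k]]
  for (k in names(inputs))
    if (!file.exists(inputs[[k]])) stop("missing input: ", inputs[[k]])

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.txt")
  manifest <- manifest_lines(config, inputs)

  paths <- list(stats = file.path(out_dir, "stats.tsv"),
                labels = file.path(out_dir, "labels.tsv"))
  if (!is.null(config$annotations))
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
  if (!is.null(config$plasmid))
    paths$plasmid <- file.path(out_dir, "plasmid_scores.tsv")
  if (!is.null(config$reference_distance))
    paths$distances <- file.path(out_dir, "distance_summary.tsv")
  if (!is.null(config$transfers))
    paths$trend <- file.path(out_dir, "h_trend.tsv")

  if (file.exists(manifest_path) &&
      identical(readLines(manifest_path, warn = FALSE), manifest) &&
      all(file.exists(unlist(paths)))) {
    message("pipeline outputs up to date in ", out_dir, "; skipping")
    return(invisible(list(paths = paths, skipped = TRUE)))
  }

  log_lines <- c(paste0("famfluct pipeline, ",
                        format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 manifest)
  t0 <- Sys.time()

  counts <- read_abundance_matrix(config$matrix)
  transfers <- if (!is.null(config$transfers))
    read_abundance_matrix(config$transfers) else NULL
  if (!is.null(transfers) && !identical(dimnames(transfers), dimnames(counts)))
    stop("transfer table ids do not match the abundance matrix")

  fs <- family_stats(counts, transfers = transfers,
                     bin_width = config$bin_width, bin_step = config$bin_step,
                     v_max = config$v_max,
                     include_zeros = isTRUE(config$include_zeros),
                     min_bin = config$min_bin, q_cap = config$q_cap)
  write_tsv(fs$stats, paths$stats)

  labels <- classify_families(fs, q_low = config$q_low,
                              q_high = config$q_high, w_min = config$w_min)
  write_tsv(labels, paths$labels)
  log_lines <- c(log_lines, paste0("classified: ",
                                   paste(names(table(labels$class)),
                                         table(labels$class),
                                         sep = "=", collapse = " ")))

  result <- list(stats = fs, labels = labels, paths = paths, skipped = FALSE)

  if (!is.null(config$transfers)) {
    tr <- binned_trend(fs$stats$Q, fs$stats$H, n_bins = config$trend_bins)
    write_tsv(tr, paths$trend)
    result$trend <- tr
  }

  if (!is.null(config$annotations)) {
    ann <- read.delim(config$annotations, stringsAsFactors = FALSE)
    enr <- category_enrichment(labels, ann, alpha = config$alpha)
    write_tsv(enr, paths$enrichment)
    result$enrichment <- enr
    log_lines <- c(log_lines, paste0("enrichment: ", sum(enr$significant),
                                     " significant at alpha = ",
                                     config$alpha))
  }

  if (!is.null(config$plasmid)) {
    pl <- read.delim(config$plasmid, stringsAsFactors = FALSE)
    if (!all(c("family_id", "plasmid", "background") %in% names(pl)))
      stop("plasmid TSV needs columns family_id, plasmid, background")
    sc <- plasmid_enrichment_score(pl$plasmid, pl$background,
                                   pseudocount = config$pseudocount)
    write_tsv(data.frame(family_id = pl$family_id, score = sc), paths$plasmid)
    result$plasmid_scores <- sc
  }

  if (!is.null(config$reference_distance)) {
    ref <- as.matrix(read.delim(config$reference_distance, row.names = 1,
                                check.names = FALSE))
    rows <- list()
    for (cls in c("overdispersed", "poisson_like", "peaked")) {
      n_cls <- sum(labels$class == cls)
      if (n_cls < 2) next
      D <- class_restricted_distance(counts, labels, cls,
                                     metric = config$metric)
      write_matrix_tsv(D, file.path(out_dir, paste0("distance_", cls, ".tsv")),
                       id_col = "genome_id")
      rho <- suppressWarnings(spearman_distance_correlation(D, ref))
      rows[[cls]] <- data.frame(class = cls, n_families = n_cls,
                                spearman_rho = rho)
    }
    dsum <- do.call(rbind, rows)
    write_tsv(dsum, paths$distances)
    result$distance_summary <- dsum
  }

  log_lines <- c(log_lines, sprintf("elapsed: %.2f s",
                                    as.numeric(difftime(Sys.time(), t0,
                                                        units = "secs"))))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  writeLines(manifest, manifest_path)
  invisible(result)
}
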