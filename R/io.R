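# Readers/writers for the external tabular formats and the end-to-end
# pipeline orchestration. One TSV dialect throughout: tab-separated, '.'
# decimal, NA for missing, UTF-8, header rows everywhere except hit tables,
# which follow the headerless tabular-BLAST convention.

OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a tabular alignment hit table
#'
#' Standard 12-column tabular BLAST layout (headerless), with an optional
#' 13th column \code{qlen}; when \code{qlen} is absent a read-length table
#' must be supplied instead, since the aligned-fraction filter needs the
#' full read length as denominator. Gzip-compressed files are read
#' transparently. Malformed rows (identity outside [0, 100], non-positive
#' lengths, alignment stretching more than 10% beyond the read) are
#' skipped, counted, and reported with one warning.
#'
#' @param path file path (optionally .gz)
#' @param read_lengths optional data.frame (read_id, length)
#' @return data.frame with columns \code{read_id, genome_id, pident,
#'   length, evalue, bitscore, qlen} (plus the remaining tabular columns);
#'   attribute \code{"skipped"} counts dropped rows.
#' @export
read_hit_table <- function(path, read_lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) == 12L) {
    names(df) <- OUTFMT6_COLS
    if (is.null(read_lengths))
      stop("hit table has no qlen column; supply 'read_lengths'")
    df$qlen <- read_lengths$length[match(df$qseqid, read_lengths$read_id)]
    if (anyNA(df$qlen))
      stop("read length missing for read(s): ",
           paste(utils::head(unique(df$qseqid[is.na(df$qlen)]), 5),
                 collapse = ", "))
  } else if (ncol(df) == 13L) {
    names(df) <- c(OUTFMT6_COLS, "qlen")
  } else {
    stop("expected 12 or 13 tab-separated columns, found ", ncol(df))
  }
  bad <- !is.finite(df$pident) | df$pident < 0 | df$pident > 100 |
    !is.finite(df$length) | df$length <= 0 |
    !is.finite(df$qlen) | df$qlen <= 0 |
    df$length > 1.1 * df$qlen | !is.finite(df$evalue) | df$evalue < 0 |
    !is.finite(df$bitscore) | df$bitscore <= 0
  if (any(bad))
    warning(sum(bad), " malformed hit row(s) skipped")
  df <- df[!bad, , drop = FALSE]
  df$read_id <- df$qseqid
  df$genome_id <- df$sseqid
  attr(df, "skipped") <- sum(bad)
  df
}

#' Write a hit table in the headerless tabular layout
#' @param hits data.frame as produced by the simulator or reader
#' @param path output path
#' @export
write_hit_table <- function(hits, path) {
  cols <- c(OUTFMT6_COLS, "qlen")
  utils::write.table(format(hits[, cols], trim = TRUE, scientific = 12,
                            digits = 12),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read station metadata
#'
#' Columns \code{station_id temperature_C salinity_psu lat lon
#' dist_coast_nm}, header row, NA for missing.
#' @param path file path
#' @export
read_station_meta <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = "NA")
  if (!"station_id" %in% names(df)) stop("metadata needs a station_id column")
  if (any(df$salinity_psu < 0, na.rm = TRUE)) stop("negative salinity")
  if (any(abs(df$lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  df$station_id <- as.character(df$station_id)
  df
}

#' Write a generic headered TSV
#' @param df data.frame
#' @param path output path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write/read a station x category table (stations as rows)
#' @param table data.frame with stations as rownames
#' @param path file path
#' @export
write_count_table <- function(table, path) {
  out <- data.frame(station_id = rownames(table), table,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  rownames(df) <- df$station_id
  df$station_id <- NULL
  df
}

#' Write simulated station hit tables to a directory
#'
#' Lays out \code{<station>_pass1.tsv} / \code{<station>_pass2.tsv} files,
#' the taxonomy, metadata and truth tables — the on-disk layout
#' \code{\link{run_pipeline}} consumes.
#'
#' @param sim output of \code{\link{simulate_stations}}
#' @param dir output directory (created if needed)
#' @export
write_station_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_taxonomy(sim$tree, file.path(dir, "taxonomy.tsv"))
  write_tsv(sim$meta, file.path(dir, "metadata.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth_stations.tsv"))
  for (s in names(sim$stations)) {
    write_hit_table(sim$stations[[s]]$pass1,
                    file.path(dir, paste0(s, "_pass1.tsv")))
    write_hit_table(sim$stations[[s]]$pass2,
                    file.path(dir, paste0(s, "_pass2.tsv")))
    write_tsv(sim$stations[[s]]$truth,
              file.path(dir, paste0(s, "_truth.tsv")))
  }
  invisible(dir)
}

#' Run the full community-profiling pipeline
#'
#' Orchestrates assign -> profile -> filter -> cluster -> envtest over a
#' directory of per-station hit tables (and, independently, growth fitting
#' when a curves file is given). Every output is written under
#' \code{outdir} together with a manifest recording inputs, thresholds and
#' seed, so a rerun with the same configuration reproduces the files.
#'
#' @param taxonomy path to the taxonomy TSV
#' @param stations_dir directory of \code{<station>_pass1.tsv} /
#'   \code{<station>_pass2.tsv} files
#' @param metadata path to the station metadata TSV (optional; required
#'   for the environmental tests)
#' @param curves path to a growth-curve TSV (optional)
#' @param outdir output directory
#' @param max_evalue,min_identity,min_qcov,score_window recruitment
#'   thresholds (defaults 1e-3, 80, 0.90, 0.05)
#' @param min_density station filter, reads/Mbp (default 600)
#' @param k clusters to cut (default 9, capped at the station count)
#' @param adjust p-adjustment for the Dunn test (default "holm")
#' @param alpha significance level (default 0.05)
#' @param bootstrap_B bootstrap replicates for growth CIs (default 200)
#' @param seed seed recorded in the manifest and used for bootstrap
#' @return invisible list with the in-memory results (assignment log,
#'   tables, dendrogram, cluster labels, env tests, growth report).
#' @export
run_pipeline <- function(taxonomy, stations_dir, metadata = NULL,
                         curves = NULL, outdir,
                         max_evalue = 1e-3, min_identity = 80,
                         min_qcov = 0.90, score_window = 0.05,
                         min_density = 600, k = 9, adjust = "holm",
                         alpha = 0.05, bootstrap_B = 200L, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tree <- read_taxonomy(taxonomy)

  p1_files <- sort(list.files(stations_dir, pattern = "_pass1\\.tsv$",
                              full.names = TRUE))
  if (length(p1_files) == 0L)
    stop("stage assign: no *_pass1.tsv files found in ", stations_dir)
  station_ids <- sub("_pass1\\.tsv$", "", basename(p1_files))

  all_cats <- character()
  rows <- list()
  log <- list()
  for (s in station_ids) {
    p1 <- read_hit_table(file.path(stations_dir, paste0(s, "_pass1.tsv")))
    p2 <- read_hit_table(file.path(stations_dir, paste0(s, "_pass2.tsv")))
    retained <- pass1_retained_reads(p1, tree, max_evalue = max_evalue,
                                     min_qcov = min_qcov)
    asg <- assign_all(retained, p2, tree, min_identity = min_identity,
                      min_qcov = min_qcov, score_window = score_window)
    write_tsv(asg, file.path(outdir, paste0(s, "_assignments.tsv")))
    log[[s]] <- c(n_reads = nrow(p1), n_pass1 = length(retained),
                  n_assigned = nrow(asg))
    row <- aggregate_by_clade(asg, tree, s)
    all_cats <- union(all_cats, colnames(row))
    rows[[s]] <- row
  }
  all_cats <- sort(all_cats)
  raw <- do.call(rbind, lapply(names(rows), function(s)
    aggregate_by_clade_pad(rows[[s]], all_cats)))
  rownames(raw) <- names(rows)
  write_count_table(raw, file.path(outdir, "raw_counts.tsv"))

  normalized <- length_normalize(raw, tree)
  write_count_table(normalized, file.path(outdir, "normalized_counts.tsv"))
  kept <- filter_stations(normalized, min_density = min_density)
  removed <- attr(kept, "removed")
  profiles <- relative_abundance(kept)
  write_count_table(profiles, file.path(outdir, "profiles.tsv"))

  res <- list(tree = tree, log = log, raw = raw, normalized = normalized,
              removed_stations = removed, profiles = profiles)

  if (nrow(profiles) >= 2L) {
    d <- bray_curtis(profiles)
    dend <- upgma(d)
    write_newick(dend, file.path(outdir, "dendrogram.nwk"))
    kk <- min(k, nrow(profiles))
    labels <- cut_clusters(dend, k = kk)
    write_tsv(data.frame(station_id = names(labels), cluster = labels),
              file.path(outdir, "clusters.tsv"))
    res$dendrogram <- dend
    res$clusters <- labels

    if (!is.null(metadata)) {
      meta <- read_station_meta(metadata)
      env <- list()
      for (v in intersect(c("temperature_C", "salinity_psu",
                            "dist_coast_nm"), names(meta))) {
        env[[v]] <- compare_clusters_env(labels, meta, v, adjust = adjust,
                                         alpha = alpha)
        if (env[[v]]$testable) {
          tab <- env[[v]]$summary
          tab$variable <- v
          write_tsv(tab, file.path(outdir, paste0("envtest_", v, ".tsv")))
        }
      }
      res$env_tests <- env
    }
  }

  if (!is.null(curves)) {
    cv <- utils::read.delim(curves, header = TRUE, sep = "\t")
    rates <- fit_rates(cv)
    write_tsv(rates, file.path(outdir, "rates.tsv"))
    report <- growth_fit_report(
      data.frame(strain = rates$strain, temperature_C = rates$temperature_C,
                 mu_per_day = rates$mu_per_day),
      B = bootstrap_B, seed = seed)
    write_tsv(report, file.path(outdir, "ctmi_report.tsv"))
    res$growth_report <- report
  }

  manifest <- list(
    inputs = list(taxonomy = taxonomy, stations_dir = stations_dir,
                  metadata = metadata, curves = curves),
    thresholds = list(max_evalue = max_evalue, min_identity = min_identity,
                      min_qcov = min_qcov, score_window = score_window,
                      min_density = min_density),
    clustering = list(k = k), stats = list(adjust = adjust, alpha = alpha),
    bootstrap = list(B = bootstrap_B), seed = seed,
    stations = station_ids, removed_stations = removed,
    version = as.character(utils::packageVersion("picoprofiler")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  } else {
    writeLines(utils::capture.output(utils::str(manifest)),
               file.path(outdir, "manifest.txt"))
  }
  invisible(res)
}

# pad/reorder a one-row count table onto a common category set
aggregate_by_clade_pad <- function(row, categories) {
  out <- as.data.frame(as.list(stats::setNames(numeric(length(categories)),
                                               categories)),
                       check.names = FALSE)
  known <- intersect(colnames(row), categories)
  out[known] <- row[known]
  rownames(out) <- rownames(row)
  out
}
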