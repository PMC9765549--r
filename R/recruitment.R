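# Two-pass filtering of whole-genome-recruitment hits and per-read LCA
# assignment.
#
# Pass 1 mirrors the initial screen against the full reference database:
# best hit only, e-value < 1e-3, target not an outgroup genome, and >= 90%
# of the read aligned. Pass 2 re-aligns the retained reads against the
# picocyanobacterial genomes only; hits with >= 80% identity (the ANI
# discontinuity separating clades), >= 90% of the read aligned and a bit
# score within 5% of the read's best are kept, and the read is attributed to
# the lowest common ancestor of the matched strains. All comparative filters
# are inclusive; the e-value bound is strict, as printed.

#' Default recruitment thresholds
#'
#' @return list with \code{max_evalue} (1e-3), \code{min_identity} (80),
#'   \code{min_qcov} (0.90) and \code{score_window} (0.05).
#' @export
recruitment_defaults <- function() {
  list(max_evalue = 1e-3, min_identity = 80, min_qcov = 0.90,
       score_window = 0.05)
}

.validate_hits <- function(hits) {
  need <- c("read_id", "genome_id", "pident", "length", "evalue",
            "bitscore", "qlen")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table is missing columns: ", paste(miss, collapse = ", "))
  if (any(hits$qlen <= 0)) stop("non-positive read length in hit table")
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100]")
  # gap columns may stretch the alignment slightly beyond the read
  if (any(hits$length > 1.1 * hits$qlen))
    stop("alignment length exceeds read length by more than 10%")
  invisible(hits)
}

# Best hit per read: max bit score, ties by min e-value then genome id.
.best_hits <- function(hits) {
  o <- order(hits$read_id, -hits$bitscore, hits$evalue, hits$genome_id)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$read_id), , drop = FALSE]
}

#' Pass-1 read retention
#'
#' Reduces the first-pass hit table to one best hit per read (max bit score,
#' ties broken by min e-value then genome id) and keeps reads whose best hit
#' has e-value below \code{max_evalue}, targets a non-outgroup
#' (picocyanobacterial) genome, and covers at least \code{min_qcov} of the
#' read length.
#'
#' @param hits data.frame of pass-1 hits (see \code{\link{read_hit_table}})
#' @param tree a \code{taxonomy_tree} resolving every \code{genome_id}
#' @param max_evalue strict upper bound on e-value (default 1e-3)
#' @param min_qcov minimum aligned fraction of the read (default 0.90)
#' @return character vector of retained read ids.
#' @export
pass1_retained_reads <- function(hits, tree, max_evalue = 1e-3,
                                 min_qcov = 0.90) {
  if (nrow(hits) == 0L) return(character())
  .validate_hits(hits)
  best <- .best_hits(hits)
  strain <- genome_strain(tree, best$genome_id)
  og <- tree$strains$outgroup[match(strain, tree$strains$strain_id)]
  keep <- best$evalue < max_evalue & !og & best$length / best$qlen >= min_qcov
  sort(best$read_id[keep])
}

#' Pass-2 candidate hits of one read
#'
#' Keeps the hits of a single read that pass the identity, aligned-fraction
#' and best-score-window filters. The score window is relative to the read's
#' best bit score among all its hits (before the other filters), so the
#' best-scoring hit always survives the window itself.
#'
#' @param read_hits data.frame of hits sharing one \code{read_id}
#' @param min_identity minimum percent identity, inclusive (default 80)
#' @param min_qcov minimum aligned fraction of the read, inclusive (0.90)
#' @param score_window fractional bit-score window below the best (0.05)
#' @return the retained rows (possibly none).
#' @export
candidate_hits <- function(read_hits, min_identity = 80, min_qcov = 0.90,
                           score_window = 0.05) {
  if (nrow(read_hits) == 0L) stop("'read_hits' must be non-empty")
  if (length(unique(read_hits$read_id)) != 1L)
    stop("'read_hits' mixes several read ids")
  .validate_hits(read_hits)
  keep <- read_hits$pident >= min_identity &
    read_hits$length / read_hits$qlen >= min_qcov &
    read_hits$bitscore >= (1 - score_window) * max(read_hits$bitscore)
  read_hits[keep, , drop = FALSE]
}

#' Assign one read by the LCA of its candidate hits
#'
#' @inheritParams candidate_hits
#' @param tree a \code{taxonomy_tree}
#' @return data.frame row (read_id, taxon_id, rank, n_candidates), or
#'   \code{NULL} when the read is unassigned (empty candidate set, or the
#'   candidate set involves an outgroup strain so the LCA falls above the
#'   genus).
#' @export
assign_read <- function(read_hits, tree, min_identity = 80, min_qcov = 0.90,
                        score_window = 0.05) {
  cand <- candidate_hits(read_hits, min_identity, min_qcov, score_window)
  if (nrow(cand) == 0L) return(NULL)
  strains <- unique(genome_strain(tree, cand$genome_id))
  og <- tree$strains$outgroup[match(strains, tree$strains$strain_id)]
  if (any(og)) return(NULL)
  taxon <- lowest_common_ancestor(tree, strains)
  rk <- taxon_rank(tree, taxon)
  if (rk %in% c("root", "outgroup")) return(NULL)
  data.frame(read_id = read_hits$read_id[1L], taxon_id = taxon, rank = rk,
             n_candidates = nrow(cand), stringsAsFactors = FALSE)
}

#' Assign all pass-1-retained reads from a pass-2 hit table
#'
#' Applies \code{\link{assign_read}} to every read in \code{pass1_reads}
#' that has pass-2 hits. Reads present in the pass-2 table but not retained
#' by pass 1 are ignored.
#'
#' @param pass1_reads character vector of read ids retained by pass 1
#' @param pass2_hits data.frame of pass-2 hits
#' @param tree a \code{taxonomy_tree}
#' @param min_identity,min_qcov,score_window filter thresholds (defaults 80,
#'   0.90, 0.05)
#' @return data.frame (read_id, taxon_id, rank, n_candidates) with an
#'   attribute \code{"log"}: counts of input reads, unassigned reads and
#'   assignments per rank.
#' @export
assign_all <- function(pass1_reads, pass2_hits, tree, min_identity = 80,
                       min_qcov = 0.90, score_window = 0.05) {
  empty <- data.frame(read_id = character(), taxon_id = character(),
                      rank = character(), n_candidates = integer(),
                      stringsAsFactors = FALSE)
  log <- list(input_reads = length(pass1_reads), unassigned = 0L,
              assigned_by_rank = integer())
  if (length(pass1_reads) == 0L || nrow(pass2_hits) == 0L) {
    log$unassigned <- length(pass1_reads)
    attr(empty, "log") <- log
    return(empty)
  }
  .validate_hits(pass2_hits)
  pass2_hits <- pass2_hits[pass2_hits$read_id %in% pass1_reads, , drop = FALSE]

  # vectorised filters, then per-read LCA
  best <- stats::ave(pass2_hits$bitscore, pass2_hits$read_id, FUN = max)
  keep <- pass2_hits$pident >= min_identity &
    pass2_hits$length / pass2_hits$qlen >= min_qcov &
    pass2_hits$bitscore >= (1 - score_window) * best
  cand <- pass2_hits[keep, , drop = FALSE]
  cand$strain <- genome_strain(tree, cand$genome_id)
  og_strains <- tree$strains$strain_id[tree$strains$outgroup]

  by_read <- split(cand$strain, cand$read_id)
  n_cand <- lengths(by_read)
  # reads with the same candidate strain set share their LCA; resolve each
  # distinct set once
  sets <- lapply(by_read, function(s) sort(unique(s)))
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  uniq <- !duplicated(keys)
  taxon_of <- vapply(sets[uniq], function(strains) {
    if (any(strains %in% og_strains)) return(NA_character_)
    taxon <- lowest_common_ancestor(tree, strains)
    if (taxon_rank(tree, taxon) %in% c("root", "outgroup"))
      NA_character_ else taxon
  }, character(1))
  names(taxon_of) <- keys[uniq]
  taxon <- unname(taxon_of[keys])
  ok <- !is.na(taxon)
  out <- if (any(ok)) {
    data.frame(read_id = names(by_read)[ok], taxon_id = taxon[ok],
               rank = vapply(taxon[ok], function(id) taxon_rank(tree, id),
                             character(1), USE.NAMES = FALSE),
               n_candidates = unname(n_cand[ok]), stringsAsFactors = FALSE)
  } else empty
  rownames(out) <- NULL
  log$unassigned <- length(pass1_reads) - nrow(out)
  log$assigned_by_rank <- table(out$rank)
  attr(out, "log") <- log
  out
}
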