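# Reference taxonomy of marine picocyanobacteria: a five-rank hierarchy
# (genus > subcluster > clade > subclade > strain) plus an outgroup subtree
# used to discard non-target reads. Node table + parent pointers; all LCA
# queries work on precomputed root paths.

RANK_LEVELS <- c(root = 0L, outgroup = 1L, genus = 1L, subcluster = 2L,
                 clade = 3L, subclade = 4L, strain = 5L)

ROOT_ID <- "__root__"
OUTGROUP_ID <- "__outgroup__"

#' Build a picocyanobacterial reference taxonomy
#'
#' Constructs the rank hierarchy used for lowest-common-ancestor read
#' assignment from a strain-level table. Each in-group strain is attached
#' along the path genus > subcluster > clade > subclade > strain; missing
#' intermediate ranks (\code{NA}) are skipped so the strain attaches to its
#' nearest known ancestor. Outgroup strains are attached under a distinguished
#' sibling of the genus so that any candidate set containing an outgroup
#' strain resolves above the genus and the read is discarded downstream.
#'
#' @param records data.frame with columns \code{strain_id}, \code{subclade},
#'   \code{clade}, \code{subcluster}, \code{genus}, \code{genome_length_bp}
#'   and \code{outgroup} (logical or 0/1). \code{NA} is allowed for
#'   intermediate ranks.
#' @param genome_map optional data.frame (\code{genome_id}, \code{strain_id})
#'   mapping sequence records to strains; defaults to the identity map (one
#'   genome per strain, named after it).
#'
#' @return an object of class \code{taxonomy_tree}: a list with \code{nodes}
#'   (id, rank, parent), \code{strains} (strain_id, genome_length_bp,
#'   outgroup), \code{genome_map} (named character vector genome_id ->
#'   strain_id) and \code{paths} (per-strain root paths, precomputed).
#' @examples
#' tax <- build_taxonomy(data.frame(
#'   strain_id = "CC9311", subclade = "Ia", clade = "I",
#'   subcluster = "5.1", genus = "Synechococcus",
#'   genome_length_bp = 2606748, outgroup = FALSE))
#' taxon_path(tax, "CC9311")
#' @export
build_taxonomy <- function(records, genome_map = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame of strain records")
  need <- c("strain_id", "subclade", "clade", "subcluster", "genus",
            "genome_length_bp", "outgroup")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("taxonomy records are missing columns: ", paste(miss, collapse = ", "))
  records$strain_id <- as.character(records$strain_id)
  dup <- records$strain_id[duplicated(records$strain_id)]
  if (length(dup))
    stop("duplicate strain id(s): ", paste(unique(dup), collapse = ", "))
  bad_len <- !is.finite(records$genome_length_bp) | records$genome_length_bp <= 0
  if (any(bad_len))
    stop("non-positive genome length for strain(s): ",
         paste(records$strain_id[bad_len], collapse = ", "))
  records$outgroup <- as.logical(records$outgroup)

  ids <- ROOT_ID
  rank <- "root"
  parent <- NA_character_
  add_node <- function(id, rk, par) {
    if (!id %in% ids) {
      ids <<- c(ids, id); rank <<- c(rank, rk); parent <<- c(parent, par)
    } else {
      i <- match(id, ids)
      if (rank[i] != rk)
        stop("taxon id '", id, "' used at two ranks ('", rank[i], "' and '",
             rk, "'); ids must be unique within the tree")
      if (!identical(parent[i], par))
        stop("taxon id '", id, "' attached under two parents ('",
             parent[i], "' and '", par, "')")
    }
    id
  }

  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (isTRUE(r$outgroup)) {
      add_node(OUTGROUP_ID, "outgroup", ROOT_ID)
      add_node(r$strain_id, "strain", OUTGROUP_ID)
      next
    }
    if (is.na(r$genus) || !nzchar(r$genus))
      stop("in-group strain '", r$strain_id, "' has no genus")
    par <- add_node(as.character(r$genus), "genus", ROOT_ID)
    for (rk in c("subcluster", "clade", "subclade")) {
      val <- r[[rk]]
      if (!is.na(val) && nzchar(as.character(val)))
        par <- add_node(as.character(val), rk, par)
    }
    add_node(r$strain_id, "strain", par)
  }

  nodes <- data.frame(id = ids, rank = rank, parent = parent,
                      stringsAsFactors = FALSE)
  strains <- data.frame(strain_id = records$strain_id,
                        genome_length_bp = as.numeric(records$genome_length_bp),
                        outgroup = records$outgroup,
                        stringsAsFactors = FALSE)
  if (is.null(genome_map)) {
    gm <- stats::setNames(strains$strain_id, strains$strain_id)
  } else {
    if (anyDuplicated(genome_map$genome_id))
      stop("a genome id maps to more than one strain")
    unknown <- setdiff(genome_map$strain_id, strains$strain_id)
    if (length(unknown))
      stop("genome map references unknown strain(s): ",
           paste(unknown, collapse = ", "))
    gm <- stats::setNames(as.character(genome_map$strain_id),
                          as.character(genome_map$genome_id))
  }

  tree <- structure(list(nodes = nodes, strains = strains, genome_map = gm),
                    class = "taxonomy_tree")
  tree$paths <- lapply(stats::setNames(nm = nodes$id), function(id)
    .root_path(nodes, id))
  # rank order must strictly descend along every root path
  for (p in tree$paths[strains$strain_id[!strains$outgroup]]) {
    lv <- RANK_LEVELS[nodes$rank[match(p, nodes$id)]]
    if (any(diff(lv) <= 0))
      stop("ranks do not strictly descend along path: ",
           paste(p, collapse = " > "))
  }
  tree
}

.root_path <- function(nodes, id) {
  path <- character()
  cur <- id
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- nodes$parent[match(cur, nodes$id)]
  }
  path
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  n_in <- sum(!x$strains$outgroup)
  cat("Picocyanobacterial reference taxonomy\n")
  cat("  in-group strains: ", n_in, " (", sum(x$strains$outgroup),
      " outgroup)\n", sep = "")
  cat("  nodes:", nrow(x$nodes), " genomes:", length(x$genome_map), "\n")
  invisible(x)
}

#' Root path of a taxon
#'
#' @param tree a \code{taxonomy_tree}
#' @param id taxon id
#' @return character vector of node ids from the universal root to \code{id}.
#' @export
taxon_path <- function(tree, id) {
  p <- tree$paths[[id]]
  if (is.null(p)) stop("unknown taxon id: ", id)
  p
}

#' Rank of a taxon
#' @inheritParams taxon_path
#' @return one of "root", "outgroup", "genus", "subcluster", "clade",
#'   "subclade", "strain".
#' @export
taxon_rank <- function(tree, id) {
  i <- match(id, tree$nodes$id)
  if (is.na(i)) stop("unknown taxon id: ", id)
  tree$nodes$rank[i]
}

#' Map a genome id to its strain
#' @inheritParams taxon_path
#' @param genome_id sequence-record id as it appears in hit tables
#' @export
genome_strain <- function(tree, genome_id) {
  s <- tree$genome_map[genome_id]
  if (anyNA(s)) stop("genome id(s) absent from taxonomy: ",
                     paste(genome_id[is.na(s)], collapse = ", "))
  unname(s)
}

#' Lowest common ancestor of a set of strains
#'
#' Returns the deepest taxonomy node lying on the root path of every strain
#' in the set; a singleton set returns the strain itself. Reads whose
#' candidate matches span several clades are thereby assigned conservatively
#' at the subcluster or genus level.
#'
#' @param tree a \code{taxonomy_tree}
#' @param strain_ids non-empty character vector of strain ids
#' @return the id of the LCA node.
#' @export
lowest_common_ancestor <- function(tree, strain_ids) {
  strain_ids <- unique(as.character(strain_ids))
  if (length(strain_ids) == 0L) stop("'strain_ids' must be non-empty")
  unknown <- setdiff(strain_ids, tree$strains$strain_id)
  if (length(unknown))
    stop("unknown strain id(s): ", paste(unknown, collapse = ", "))
  paths <- tree$paths[strain_ids]
  ref <- paths[[1L]]
  k <- length(ref)
  for (p in paths[-1L]) {
    m <- min(k, length(p))
    eq <- ref[seq_len(m)] == p[seq_len(m)]
    k <- if (all(eq)) m else which(!eq)[1L] - 1L
    if (k == 0L) break
  }
  if (k == 0L) stop("strains share no common ancestor (corrupt tree)")
  ref[k]
}

#' Read a taxonomy table
#'
#' Expects tab-separated columns \code{strain_id subclade clade subcluster
#' genus genome_length_bp outgroup} with a header row; \code{NA} marks a
#' missing intermediate rank.
#' @param path file path
#' @return a \code{taxonomy_tree}
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = "NA", colClasses = "character")
  df$genome_length_bp <- as.numeric(df$genome_length_bp)
  df$outgroup <- as.integer(df$outgroup) != 0L
  build_taxonomy(df)
}

#' Write a taxonomy table
#' @param tree a \code{taxonomy_tree}
#' @param path file path
#' @export
write_taxonomy <- function(tree, path) {
  df <- taxonomy_records(tree)
  df$outgroup <- as.integer(df$outgroup)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Recover the strain-level record table from a taxonomy tree
#' @param tree a \code{taxonomy_tree}
#' @return data.frame in the same layout \code{build_taxonomy} accepts.
#' @export
taxonomy_records <- function(tree) {
  recs <- lapply(seq_len(nrow(tree$strains)), function(i) {
    sid <- tree$strains$strain_id[i]
    out <- tree$strains$outgroup[i]
    res <- list(strain_id = sid, subclade = NA_character_,
                clade = NA_character_, subcluster = NA_character_,
                genus = NA_character_,
                genome_length_bp = tree$strains$genome_length_bp[i],
                outgroup = out)
    if (!out) {
      p <- tree$paths[[sid]]
      rk <- tree$nodes$rank[match(p, tree$nodes$id)]
      for (lvl in c("subclade", "clade", "subcluster", "genus")) {
        j <- match(lvl, rk)
        if (!is.na(j)) res[[lvl]] <- p[j]
      }
    }
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

# Ancestor-or-self of `id` at rank `at`; NA when the path has no such rank.
.ancestor_at <- function(tree, id, at) {
  p <- taxon_path(tree, id)
  rk <- tree$nodes$rank[match(p, tree$nodes$id)]
  j <- match(at, rk)
  if (is.na(j)) NA_character_ else p[j]
}

.is_outgroup_node <- function(tree, id) {
  OUTGROUP_ID %in% taxon_path(tree, id)
}
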