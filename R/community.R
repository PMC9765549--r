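# Clade-level community profiling of sampling stations: roll assignments up
# to clades (with "5.1" and "Syn" categories for reads assignable only to
# the subcluster or genus), normalize by mean genome length, drop
# low-coverage stations, total-sum scale, and cluster stations by
# Bray-Curtis/UPGMA. Environmental differences between station clusters are
# tested by Kruskal-Wallis with a Dunn post hoc and a compact letter display.

#' Map an assignment taxon to its clade-level category
#'
#' Strain-, subclade- and clade-level assignments roll up to their clade (or
#' to the subcluster id when the subtree has no clade rank, as for SC 5.2 /
#' SC 5.3). Subcluster-level assignments keep the subcluster id (category
#' "5.1"); genus-level assignments become category "Syn".
#'
#' @param tree a \code{taxonomy_tree}
#' @param taxon_id taxon id(s)
#' @return character vector of category labels.
#' @export
clade_category <- function(tree, taxon_id) {
  vapply(taxon_id, function(id) {
    rk <- taxon_rank(tree, id)
    switch(rk,
      genus = "Syn",
      subcluster = id,
      strain = , subclade = , clade = {
        cl <- .ancestor_at(tree, id, "clade")
        if (!is.na(cl)) cl else .ancestor_at(tree, id, "subcluster")
      },
      stop("taxon '", id, "' (rank ", rk, ") has no clade-level category"))
  }, character(1), USE.NAMES = FALSE)
}

#' Aggregate read assignments of one station by clade
#'
#' @param assignments data.frame from \code{\link{assign_all}}
#' @param tree a \code{taxonomy_tree}
#' @param station_id station label for the resulting row
#' @param categories optional category order for the result (missing
#'   categories padded with 0)
#' @return one-row data.frame of read counts, rownames = station id.
#' @export
aggregate_by_clade <- function(assignments, tree, station_id,
                               categories = NULL) {
  cats <- if (nrow(assignments))
    clade_category(tree, assignments$taxon_id) else character()
  tab <- table(cats)
  if (is.null(categories)) categories <- sort(names(tab))
  counts <- stats::setNames(numeric(length(categories)), categories)
  known <- intersect(names(tab), categories)
  counts[known] <- as.numeric(tab[known])
  out <- as.data.frame(as.list(counts), check.names = FALSE)
  rownames(out) <- station_id
  out
}

#' Mean genome length (bp) of the strains under a category
#' @param tree a \code{taxonomy_tree}
#' @param category category label ("Syn" averages all in-group strains)
#' @export
category_mean_genome_length <- function(tree, category) {
  st <- tree$strains[!tree$strains$outgroup, , drop = FALSE]
  if (category != "Syn") {
    member <- vapply(st$strain_id, function(s)
      category %in% taxon_path(tree, s), logical(1))
    st <- st[member, , drop = FALSE]
  }
  if (nrow(st) == 0L)
    stop("category '", category, "' has no strains with genome lengths")
  mean(st$genome_length_bp)
}

#' Genome-length normalization of a count table
#'
#' Divides each category's read counts by the mean genome length (in Mbp)
#' of the strains it covers, turning raw counts into reads per Mbp. For the
#' coarse categories ("5.1", "Syn") the mean is taken over all strains of
#' the corresponding subtree.
#'
#' @param table station x category data.frame of raw read counts
#' @param tree a \code{taxonomy_tree}
#' @return data.frame of the same shape in reads/Mbp.
#' @export
length_normalize <- function(table, tree) {
  mbp <- vapply(colnames(table), function(cat)
    category_mean_genome_length(tree, cat) / 1e6, numeric(1))
  out <- sweep(as.matrix(table), 2L, mbp, "/")
  as.data.frame(out, check.names = FALSE)
}

#' Remove low-coverage stations
#'
#' Stations whose summed normalized recruitment falls below
#' \code{min_density} reads/Mbp are removed to limit noise in the
#' composition profiles (the boundary is inclusive: a station at exactly the
#' threshold is kept).
#'
#' @param table normalized station x category table (reads/Mbp)
#' @param min_density threshold in reads per Mbp (default 600)
#' @return the retained table, with attribute \code{"removed"} listing the
#'   dropped station ids.
#' @export
filter_stations <- function(table, min_density = 600) {
  totals <- rowSums(table)
  keep <- totals >= min_density
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- rownames(table)[!keep]
  out
}

#' Relative abundance profiles (total-sum scaling)
#'
#' Row-normalizes each station's counts by its total so profiles sum to 1
#' (vegan's \code{decostand(method = "total")}). Zero-total stations are
#' dropped with a warning.
#'
#' @param table station x category table (any consistent units)
#' @return data.frame of relative abundances.
#' @export
relative_abundance <- function(table) {
  totals <- rowSums(table)
  if (any(totals == 0)) {
    warning("dropping zero-total station(s): ",
            paste(rownames(table)[totals == 0], collapse = ", "))
    table <- table[totals > 0, , drop = FALSE]
  }
  as.data.frame(vegan::decostand(as.matrix(table), method = "total"),
                check.names = FALSE)
}

#' Bray-Curtis dissimilarity between station profiles
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed with
#' \code{vegan::vegdist}.
#'
#' @param profiles station x category matrix/data.frame of non-negative
#'   abundances
#' @return a \code{dist} object.
#' @export
bray_curtis <- function(profiles) {
  m <- as.matrix(profiles)
  if (any(m < 0)) stop("negative abundances")
  if (any(rowSums(m) == 0))
    stop("Bray-Curtis is undefined for all-zero profiles: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' UPGMA clustering of stations
#'
#' Average-linkage agglomerative clustering (unweighted pair-group method
#' with arithmetic mean): the closest pair of clusters is merged at its
#' current distance, and the merged cluster's distance to any other is the
#' size-weighted mean of its members' distances.
#'
#' @param dist a \code{dist} object (n >= 2, no missing values)
#' @return an \code{hclust} object (merge heights in Bray-Curtis units when
#'   fed \code{\link{bray_curtis}} output).
#' @export
upgma <- function(dist) {
  if (!inherits(dist, "dist")) dist <- stats::as.dist(dist)
  if (attr(dist, "Size") < 2L) stop("need at least 2 stations to cluster")
  if (any(!is.finite(dist))) stop("distance matrix contains missing values")
  stats::hclust(dist, method = "average")
}

#' Cut a dendrogram into station clusters
#'
#' @param dendrogram an \code{hclust} object
#' @param k number of clusters, or
#' @param h cut height (clusters = connected components below h)
#' @return named integer vector station -> cluster.
#' @export
cut_clusters <- function(dendrogram, k = NULL, h = NULL) {
  n <- length(dendrogram$order)
  if (!is.null(k) && (k < 1L || k > n))
    stop("'k' must be between 1 and the number of stations (", n, ")")
  stats::cutree(dendrogram, k = k, h = h)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths encode merge-height differences so leaf-to-root path
#' length equals half the cophenetic distance, the usual ultrametric layout.
#'
#' @param dendrogram an \code{hclust} object
#' @param path output file
#' @export
write_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram), file = path)
  invisible(path)
}

# ---- environmental comparison ----------------------------------------------

#' Dunn's post hoc test of multiple comparisons after Kruskal-Wallis
#'
#' Pairwise z statistics on the joint ranks with the tie correction, with
#' multiplicity-adjusted two-sided p-values.
#'
#' @param values numeric vector
#' @param groups grouping factor/vector, same length
#' @param adjust p-adjustment method passed to \code{stats::p.adjust}
#'   (default "holm")
#' @return data.frame (group1, group2, z, p, p_adj).
#' @export
dunn_test <- function(values, groups, adjust = "holm") {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  g <- levels(groups)
  pairs <- utils::combn(g, 2L)
  z <- apply(pairs, 2L, function(p) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / n_g[[p[1]]] + 1 / n_g[[p[2]]]))
    if (se == 0) return(0)
    (mean_rank[[p[1]]] - mean_rank[[p[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

# Compact letter display: groups sharing a letter are not significantly
# different. Letters are assigned to the maximal cliques of the
# not-significantly-different graph.
.letter_display <- function(groups, pairs, signif) {
  g <- igraph::make_empty_graph(n = length(groups), directed = FALSE)
  igraph::V(g)$name <- groups
  nsd <- pairs[!signif, , drop = FALSE]
  if (nrow(nsd))
    g <- igraph::add_edges(g, t(as.matrix(nsd[, c("group1", "group2")])))
  cliques <- igraph::max_cliques(g)
  # order cliques by their first member so letters read naturally
  first <- vapply(cliques, function(cl) min(match(names(cl), groups)),
                  numeric(1))
  cliques <- cliques[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cliques)) {
    lab <- if (i <= 26) letters[i] else paste0(letters[(i - 1) %/% 26],
                                               letters[(i - 1) %% 26 + 1])
    members <- names(cliques[[i]])
    letters_out[members] <- paste0(letters_out[members], lab)
  }
  letters_out
}

#' Compare an environmental variable across station clusters
#'
#' Kruskal-Wallis test over clusters, Dunn post hoc with adjusted p-values,
#' and a compact letter display in which clusters sharing a letter are not
#' significantly different at adjusted p < \code{alpha}.
#'
#' @param labels named vector station -> cluster (from
#'   \code{\link{cut_clusters}})
#' @param meta data.frame with a \code{station_id} column and the variable
#' @param variable column name in \code{meta} (e.g. "temperature_C")
#' @param adjust p-adjustment method ("holm", "bh", "bonferroni", ...)
#' @param alpha significance level for the letter display (default 0.05)
#' @return object of class \code{env_test}: list with \code{kruskal}
#'   (statistic, df, p), \code{dunn} (pairwise table), \code{letters},
#'   \code{summary} (per-cluster n/mean/median), or a "not testable" marker
#'   when the variable is entirely missing.
#' @export
compare_clusters_env <- function(labels, meta, variable, adjust = "holm",
                                 alpha = 0.05) {
  if (!variable %in% names(meta))
    stop("variable '", variable, "' not in metadata")
  vals <- meta[[variable]][match(names(labels), meta$station_id)]
  ok <- !is.na(vals)
  res <- list(variable = variable, alpha = alpha, adjust = adjust)
  if (!any(ok)) {
    res$testable <- FALSE
    class(res) <- "env_test"
    return(res)
  }
  vals <- vals[ok]
  cl <- factor(labels[ok])
  res$testable <- TRUE
  res$summary <- data.frame(
    cluster = levels(cl),
    n = as.vector(table(cl)),
    mean = as.vector(tapply(vals, cl, mean)),
    median = as.vector(tapply(vals, cl, median)),
    stringsAsFactors = FALSE)
  kw <- stats::kruskal.test(vals, cl)
  h <- unname(kw$statistic)
  # all-tied data: the tie correction empties the denominator; H is 0
  if (!is.finite(h)) h <- 0
  res$kruskal <- list(statistic = h, df = unname(kw$parameter),
                      p = if (is.finite(kw$p.value)) kw$p.value else 1)
  res$dunn <- dunn_test(vals, cl, adjust = adjust)
  signif <- res$dunn$p_adj < alpha & is.finite(res$dunn$p_adj)
  res$letters <- .letter_display(levels(cl), res$dunn, signif)
  res$summary$letters <- res$letters[res$summary$cluster]
  class(res) <- "env_test"
  res
}

#' @export
print.env_test <- function(x, ...) {
  cat("Environmental comparison across station clusters:", x$variable, "\n")
  if (!x$testable) {
    cat("  not testable (variable entirely missing)\n")
    return(invisible(x))
  }
  cat(sprintf("  Kruskal-Wallis H = %.3f, df = %d, p = %.3g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p))
  print(x$summary, row.names = FALSE)
  cat("  (clusters sharing a letter: not significantly different, Dunn,",
      x$adjust, "adjusted p <", x$alpha, ")\n")
  invisible(x)
}
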