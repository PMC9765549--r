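# Independent brute-force oracles, kept deliberately naive so they share no
# code with the implementation they check.

# LCA by explicit root-path intersection: list every ancestor chain, walk
# positions until the chains disagree.
oracle_lca <- function(tree, strain_ids) {
  paths <- lapply(unique(strain_ids), function(s) taxon_path(tree, s))
  depth <- min(lengths(paths))
  last <- NULL
  for (i in seq_len(depth)) {
    ids <- vapply(paths, `[`, character(1), i)
    if (length(unique(ids)) > 1L) break
    last <- ids[[1L]]
  }
  last
}

# UPGMA with explicit all-pairs averaging over the original matrix:
# inter-cluster distance is recomputed from scratch each round as the mean
# of all member-pair distances.
oracle_upgma_heights <- function(d) {
  m <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(m[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# small random taxonomy: a few clades under SC 5.1, a clade-free SC 5.2
# strain and optional outgroups
random_taxonomy <- function(n_clades = 3L, strains_per_clade = 2L,
                            with_52 = TRUE, n_outgroup = 1L) {
  clades <- as.character(utils::as.roman(seq_len(n_clades)))
  recs <- do.call(rbind, lapply(clades, function(cl) data.frame(
    strain_id = paste0("S", cl, "_", seq_len(strains_per_clade)),
    subclade = paste0(cl, letters[seq_len(strains_per_clade)]),
    clade = cl, subcluster = "5.1", genus = "Synechococcus",
    genome_length_bp = round(runif(strains_per_clade, 2.1e6, 2.9e6)),
    outgroup = FALSE, stringsAsFactors = FALSE)))
  if (with_52)
    recs <- rbind(recs, data.frame(
      strain_id = "S52_1", subclade = NA, clade = NA, subcluster = "5.2",
      genus = "Synechococcus", genome_length_bp = 2.4e6, outgroup = FALSE))
  if (n_outgroup > 0L)
    recs <- rbind(recs, data.frame(
      strain_id = paste0("OG_", seq_len(n_outgroup)), subclade = NA,
      clade = NA, subcluster = NA, genus = NA,
      genome_length_bp = round(runif(n_outgroup, 2e6, 6e6)),
      outgroup = TRUE))
  build_taxonomy(recs)
}

# one synthetic hit row in the in-memory layout
make_hit <- function(read_id, genome_id, pident = 99, qlen = 242,
                     length = 240, evalue = 1e-20, bitscore = NULL) {
  if (is.null(bitscore)) bitscore <- 2 * length * (pident / 100 - 0.5)
  data.frame(qseqid = read_id, sseqid = genome_id, pident = pident,
             length = length, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = length, sstart = 1L, send = length, evalue = evalue,
             bitscore = bitscore, qlen = qlen, read_id = read_id,
             genome_id = genome_id, stringsAsFactors = FALSE)
}

random_cardinal <- function() {
  tmin <- runif(1, -5, 8)
  topt <- tmin + runif(1, 10, 25)
  tmax <- topt + runif(1, 2, 8)
  list(Tmin = tmin, Topt = topt, Tmax = tmax, mu_opt = runif(1, 0.2, 1.5))
}
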