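tax_c <- local({
  set.seed(2)
  random_taxonomy(n_clades = 4, strains_per_clade = 2, with_52 = TRUE)
})

test_that("assignments roll up to clade with 5.1/Syn categories", {
  asg <- data.frame(
    read_id = sprintf("r%d", 1:7),
    taxon_id = c("SI_1", "SI_1", "SI_1", "Ia", "Ib", "5.1", "Synechococcus"),
    rank = c(rep("strain", 3), "subclade", "subclade", "subcluster",
             "genus"),
    n_candidates = 1L, stringsAsFactors = FALSE)
  row <- aggregate_by_clade(asg, tax_c, "st1",
                            categories = c("I", "II", "5.1", "Syn"))
  expect_equal(unlist(row),
               c(I = 5, II = 0, `5.1` = 1, Syn = 1))
  # SC 5.2 strain (no clade rank) rolls up to its subcluster
  expect_equal(clade_category(tax_c, "S52_1"), "5.2")
})

test_that("clade aggregation equals a brute-force root-path tally", {
  set.seed(3)
  strains <- tax_c$strains$strain_id[!tax_c$strains$outgroup]
  asg <- data.frame(read_id = sprintf("r%d", 1:200),
                    taxon_id = sample(strains, 200, replace = TRUE),
                    rank = "strain", n_candidates = 1L,
                    stringsAsFactors = FALSE)
  row <- aggregate_by_clade(asg, tax_c, "st")
  oracle <- table(vapply(asg$taxon_id, function(s) {
    p <- taxon_path(tax_c, s)
    rk <- vapply(p, function(id) taxon_rank(tax_c, id), character(1))
    if ("clade" %in% rk) p[match("clade", rk)] else p[match("subcluster", rk)]
  }, character(1)))
  expect_equal(unlist(row)[names(oracle)], c(oracle)[names(oracle)],
               ignore_attr = TRUE)
})

test_that("genome-length normalization divides by mean clade genome in Mbp", {
  recs <- data.frame(
    strain_id = c("A1", "A2", "B1"), subclade = NA,
    clade = c("I", "I", "II"), subcluster = "5.1",
    genus = "Synechococcus", genome_length_bp = c(2.4e6, 2.6e6, 2.2e6),
    outgroup = FALSE)
  tax <- build_taxonomy(recs)
  tab <- data.frame(I = 250, II = 250, row.names = "st1")
  norm <- length_normalize(tab, tax)
  expect_equal(norm$I, 250 / 2.5)   # mean(2.4, 2.6) Mbp
  expect_equal(norm$II, 250 / 2.2)
  expect_gt(norm$II, norm$I)        # smaller genomes, higher density

  set.seed(4)
  tab2 <- as.data.frame(matrix(rpois(10, 100), 5, 2,
                               dimnames = list(paste0("s", 1:5),
                                               c("I", "II"))))
  norm2 <- length_normalize(tab2, tax)
  expect_equal(as.matrix(norm2),
               sweep(as.matrix(tab2), 2, c(2.5, 2.2), "/"),
               ignore_attr = TRUE)
})

test_that("station filter keeps totals at or above 600 reads/Mbp", {
  tab <- data.frame(I = c(650, 600, 599), II = 0,
                    row.names = c("a", "b", "c"))
  kept <- filter_stations(tab)
  expect_equal(rownames(kept), c("a", "b"))
  expect_equal(attr(kept, "removed"), "c")
  empty <- filter_stations(tab[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("relative abundance is total-sum scaling", {
  tab <- data.frame(I = 30, II = 70, row.names = "st")
  expect_equal(unlist(relative_abundance(tab)), c(I = 0.3, II = 0.7))
  set.seed(5)
  tab2 <- as.data.frame(matrix(runif(40, 1, 100), 8, 5))
  rownames(tab2) <- paste0("s", 1:8)
  prof <- relative_abundance(tab2)
  expect_equal(unname(rowSums(prof)), rep(1, 8), tolerance = 1e-9)
  expect_equal(relative_abundance(tab2 * 10), prof)
  tab3 <- rbind(tab2, s9 = 0)
  expect_warning(p3 <- relative_abundance(tab3), "zero-total")
  expect_equal(nrow(p3), 8L)
})

test_that("Bray-Curtis matches the formula and its degenerate cases", {
  x <- c(0.5, 0.5, 0); y <- c(1, 0, 0)
  expect_equal(as.numeric(bray_curtis(rbind(x, y))), 0.5)
  expect_equal(as.numeric(bray_curtis(rbind(x, x))), 0)
  expect_equal(as.numeric(bray_curtis(rbind(c(1, 0), c(0, 1)))), 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("UPGMA reproduces hand and oracle dendrograms", {
  d2 <- stats::as.dist(matrix(c(0, .3, .3, 0), 2,
                              dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(upgma(d2)$height, 0.3)

  m3 <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- upgma(stats::as.dist(m3))
  expect_equal(hc3$height, c(0.1, 0.4))

  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
    d <- stats::as.dist(m + t(m))
    hc <- upgma(d)
    expect_equal(hc$height, oracle_upgma_heights(d), tolerance = 1e-12)
    expect_true(all(diff(hc$height) >= -1e-12))
    # cophenetic distance of two leaves = height of their lowest merge
    expect_true(all(abs(stats::cophenetic(hc) - stats::cophenetic(hc)) == 0))
  }
  expect_error(upgma(stats::as.dist(matrix(c(0, NA, NA, 0), 2))), "missing")
})

test_that("cutting the dendrogram yields components below the cut", {
  m3 <- matrix(c(0, .1, .4, .1, 0, .4, .4, .4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma(stats::as.dist(m3))
  expect_equal(unname(cut_clusters(hc, h = 0.2)), c(1, 1, 2))
  expect_equal(length(unique(cut_clusters(hc, k = 3))), 3L)
  expect_equal(length(unique(cut_clusters(hc, k = 1))), 1L)
  expect_error(cut_clusters(hc, k = 5), "between 1 and")
})

test_that("Newick export round-trips through ape with matching topology", {
  set.seed(8)
  m <- matrix(runif(36, .1, 1), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("st", 1:6)
  hc <- upgma(stats::as.dist(m))
  f <- tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, paste0("st", 1:6))
})

test_that("cluster environmental comparison: letters separate disjoint groups", {
  labels <- stats::setNames(rep(1:2, each = 10), paste0("s", 1:20))
  meta <- data.frame(station_id = paste0("s", 1:20),
                     temperature_C = c(seq(10, 12, length.out = 10),
                                       seq(25, 27, length.out = 10)))
  et <- compare_clusters_env(labels, meta, "temperature_C")
  expect_true(et$testable)
  expect_lt(et$kruskal$p, 0.05)
  expect_false(et$letters[["1"]] == et$letters[["2"]])
  expect_equal(et$summary$median, c(11, 26))
})

test_that("constant values give H = 0 and one shared letter", {
  labels <- stats::setNames(rep(1:3, each = 4), paste0("s", 1:12))
  meta <- data.frame(station_id = paste0("s", 1:12), temperature_C = 17.5)
  et <- compare_clusters_env(labels, meta, "temperature_C")
  expect_equal(et$kruskal$statistic, 0)
  expect_equal(length(unique(et$letters)), 1L)
})

test_that("a variable with no data is reported not testable", {
  labels <- stats::setNames(rep(1:2, each = 3), paste0("s", 1:6))
  meta <- data.frame(station_id = paste0("s", 1:6),
                     salinity_psu = NA_real_)
  et <- compare_clusters_env(labels, meta, "salinity_psu")
  expect_false(et$testable)
})

test_that("type-I error of the letter display is near nominal", {
  set.seed(9)
  shared <- vapply(1:100, function(i) {
    labels <- stats::setNames(rep(1:2, each = 10), paste0("s", 1:20))
    meta <- data.frame(station_id = paste0("s", 1:20),
                       temperature_C = rnorm(20, 18, 2))
    et <- compare_clusters_env(labels, meta, "temperature_C")
    et$letters[["1"]] == et$letters[["2"]]
  }, logical(1))
  expect_gte(mean(shared), 0.9)
})

test_that("Dunn z for two groups squares to the Kruskal-Wallis statistic", {
  set.seed(10)
  vals <- rnorm(24)
  grp <- rep(c("a", "b"), each = 12)
  dn <- dunn_test(vals, grp)
  kw <- stats::kruskal.test(vals, factor(grp))
  expect_equal(dn$z^2, unname(kw$statistic), tolerance = 1e-10)
})
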