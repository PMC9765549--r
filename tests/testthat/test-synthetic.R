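test_that("the reference-set generator is deterministic and rank-valid", {
  cfg <- simulation_config()
  a <- simulate_reference_set(cfg, seed = 3)
  b <- simulate_reference_set(cfg, seed = 3)
  expect_identical(a$records, b$records)
  expect_equal(sum(!a$tree$strains$outgroup), 8L)   # 4 clades x 2 strains

  f1 <- tempfile(); f2 <- tempfile()
  write_taxonomy(a$tree, f1); write_taxonomy(b$tree, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(simulate_reference_set(simulation_config(n_clades = 0)),
               "at least one clade")
})

test_that("identity bands must be ordered within-strain >= within-clade > cross-clade", {
  expect_error(simulation_config(id_within_clade = c(75, 95)),
               "identity bands")
})

test_that("hit tables honour composition, bands and planted fractions", {
  cfg <- simulation_config(outgroup_fraction = 0.1)
  ref <- simulate_reference_set(cfg, seed = 5)
  ht <- simulate_hit_tables(ref$tree, c(I = 1.0, II = 0, III = 0, IV = 0),
                            1500, cfg, seed = 6)
  # ~10% outgroup contamination, binomial tolerance
  expect_lt(abs(ht$planted$outgroup / 1500 - 0.1), 3 * sqrt(0.1 * 0.9 / 1500))

  p1 <- pass1_retained_reads(ht$pass1, ref$tree)
  asg <- assign_all(p1, ht$pass2, ref$tree)
  cat_of <- clade_category(ref$tree, asg$taxon_id)
  ok <- cat_of == "I" | cat_of %in% c("5.1", "Syn")
  expect_gte(mean(ok), 0.99)

  expect_error(simulate_hit_tables(ref$tree, c(I = 0.5), 10, cfg),
               "sum to 1")
  expect_error(simulate_hit_tables(ref$tree, c(XX = 1), 10, cfg),
               "not in taxonomy")
})

test_that("hit tables round-trip through the reader byte-for-value", {
  cfg <- simulation_config()
  ref <- simulate_reference_set(cfg, seed = 7)
  ht <- simulate_hit_tables(ref$tree, c(I = .25, II = .25, III = .25,
                                        IV = .25), 300, cfg, seed = 8)
  f <- tempfile(fileext = ".tsv")
  write_hit_table(ht$pass2, f)
  back <- read_hit_table(f)
  expect_equal(nrow(back), nrow(ht$pass2))
  expect_equal(back$pident, ht$pass2$pident)
  expect_equal(back$bitscore, ht$pass2$bitscore)
  expect_equal(back$qlen, ht$pass2$qlen)
  expect_identical(back$read_id, ht$pass2$read_id)
})

test_that("same seed gives byte-identical hit tables", {
  cfg <- simulation_config()
  ref <- simulate_reference_set(cfg, seed = 7)
  comp <- c(I = .25, II = .25, III = .25, IV = .25)
  f1 <- tempfile(); f2 <- tempfile()
  write_hit_table(simulate_hit_tables(ref$tree, comp, 200, cfg,
                                      seed = 9)$pass2, f1)
  write_hit_table(simulate_hit_tables(ref$tree, comp, 200, cfg,
                                      seed = 9)$pass2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("wider identity separation never lowers clade recovery", {
  recovery <- function(cross_band) {
    cfg <- simulation_config(id_cross_clade = cross_band,
                             outgroup_fraction = 0)
    ref <- simulate_reference_set(cfg, seed = 10)
    ht <- simulate_hit_tables(ref$tree, c(I = .25, II = .25, III = .25,
                                          IV = .25), 600, cfg, seed = 11)
    p1 <- pass1_retained_reads(ht$pass1, ref$tree)
    asg <- assign_all(p1, ht$pass2, ref$tree)
    m <- merge(asg, ht$truth, by = "read_id")
    cat_of <- clade_category(ref$tree, m$taxon_id)
    mean(cat_of == m$true_clade | cat_of %in% c("5.1", "Syn"))
  }
  expect_gte(recovery(c(60, 68)), recovery(c(70, 78)) - 1e-9)
})

test_that("station simulation plants regimes, metadata and low-coverage depth", {
  cfg <- simulation_config(n_stations = 6, reads_per_station = 400,
                           low_coverage_stations = 2)
  sim <- simulate_stations(cfg, seed = 12)
  expect_equal(length(sim$stations), 6L)
  expect_equal(sum(sim$truth$planted_low_coverage), 2L)
  depths <- vapply(sim$stations, function(s) nrow(s$pass1), integer(1))
  expect_true(all(depths[sim$truth$planted_low_coverage] == 200))
  expect_true(all(depths[!sim$truth$planted_low_coverage] == 400))
  cold <- sim$meta$temperature_C[sim$truth$regime == "cold"]
  warm <- sim$meta$temperature_C[sim$truth$regime == "warm"]
  expect_lt(mean(cold), mean(warm))
})

test_that("growth curves follow the thermal model exactly at zero noise", {
  cfg <- simulation_config(growth_cv = 0, growth_reps = 1)
  panel <- default_growth_panel()[c(1, 5), ]
  sim <- simulate_growth_curves(panel, cfg, seed = 13)
  rates <- suppressWarnings(fit_rates(sim$curves))
  truth <- merge(rates, panel, by = "strain")
  expected <- mapply(ctmi_mu, truth$temperature_C, truth$Tmin, truth$Topt,
                     truth$Tmax, truth$mu_opt)
  expect_equal(truth$mu_per_day, expected, tolerance = 1e-6)
  # beyond Tmax the culture never grows
  hot <- sim$curves[sim$curves$strain == "SynI_1" &
                      sim$curves$temperature_C > 26, ]
  expect_true(all(hot$cells_per_ml == hot$cells_per_ml[1]))
})

test_that("growth-curve generation is seed-deterministic", {
  a <- simulate_growth_curves(seed = 14)
  b <- simulate_growth_curves(seed = 14)
  expect_identical(a$curves, b$curves)
})
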