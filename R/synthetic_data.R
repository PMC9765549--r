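# Ground-truth-labelled synthetic data for benchmarking every pipeline
# stage. Hits are simulated directly as alignment statistics (identity,
# aligned length, bit score) rather than by mutating sequences and
# realigning: the assignment logic only ever sees hit statistics, so this
# is exact and fast. The identity bands encode the ANI structure of the
# picocyanobacterial radiation: near-identical within a strain, high within
# a clade, and a discontinuity below 80% between clades; outgroup taxa sit
# in their own band to exercise the first-pass discard.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator with defaults chosen
#' to mirror the study design: a small SC 5.1 reference set of 4 clades x 2
#' strains plus outgroups; 242 bp mean reads whose identity bands are
#' ordered within-strain >= within-clade > cross-clade (< 80%); two
#' temperature-keyed composition regimes (a cold clade I/IV community and a
#' warm clade II/III community); and CTMI-shaped growth responses sampled
#' in triplicate on an acclimation grid from 10 to 33 degrees C.
#'
#' @param n_clades clades in subcluster 5.1 (roman numerals I, II, ...)
#' @param strains_per_clade strains per clade
#' @param genome_length_range genome length range, bp
#' @param n_outgroup outgroup genomes
#' @param read_len_mean,read_len_sd read length model, bp
#' @param id_within_strain,id_within_clade,id_cross_clade,id_outgroup
#'   percent-identity bands c(lo, hi)
#' @param qcov_range aligned fraction of the read for genuine hits
#' @param outgroup_fraction fraction of reads whose best pass-1 hit is an
#'   outgroup genome (contamination)
#' @param low_qcov_fraction fraction of reads planted with < 90% coverage
#' @param high_evalue_fraction fraction planted with e-value >= 1e-3
#' @param sibling_hit_prob probability a same-clade strain also hits a read
#' @param cross_hit_prob probability a cross-clade strain hits a read
#' @param n_stations,reads_per_station station model size
#' @param regimes list of regimes, each list(name, composition = named
#'   clade fractions, temperature = c(mean, sd), salinity = c(mean, sd))
#' @param dirichlet_conc concentration of per-station composition noise
#' @param low_coverage_stations how many stations get sub-threshold depth
#' @param low_coverage_depth read depth for those stations
#' @param growth_temps acclimation temperatures, degrees C
#' @param growth_reps biological replicates per temperature
#' @param growth_sigma rate noise (per day) for rate-level simulation
#' @param growth_cv multiplicative lognormal CV of cell counts
#' @param growth_times sampling times, days
#' @param n0,capacity inoculum and stationary-phase density, cells/mL
#' @return list of class \code{sim_config}.
#' @export
simulation_config <- function(
    n_clades = 4L, strains_per_clade = 2L,
    genome_length_range = c(2.2e6, 2.86e6), n_outgroup = 3L,
    read_len_mean = 242, read_len_sd = 30,
    id_within_strain = c(98, 100), id_within_clade = c(95, 98),
    id_cross_clade = c(70, 78), id_outgroup = c(85, 95),
    qcov_range = c(0.92, 1), outgroup_fraction = 0.02,
    low_qcov_fraction = 0.02, high_evalue_fraction = 0.01,
    sibling_hit_prob = 0.9, cross_hit_prob = 0.3,
    n_stations = 20L, reads_per_station = 2000L,
    regimes = list(
      cold = list(composition = c(I = 0.50, II = 0.05, III = 0.05, IV = 0.40),
                  temperature = c(12, 1.5), salinity = c(34.5, 0.8)),
      warm = list(composition = c(I = 0.05, II = 0.45, III = 0.45, IV = 0.05),
                  temperature = c(25, 1.5), salinity = c(37.5, 0.8))),
    dirichlet_conc = 200, low_coverage_stations = 0L,
    low_coverage_depth = 200L,
    growth_temps = seq(10, 33, by = 3), growth_reps = 3L,
    growth_sigma = 0.05, growth_cv = 0.05,
    growth_times = seq(0, 8, by = 1), n0 = 1e4, capacity = 5e7) {
  if (id_within_strain[1] < id_within_clade[1] ||
      id_within_clade[1] <= id_cross_clade[2])
    stop("identity bands must be ordered within-strain >= within-clade > cross-clade")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

.roman <- function(i) as.character(utils::as.roman(i))

#' Simulate a reference taxonomy
#'
#' Builds a strain table of \code{n_clades} x \code{strains_per_clade}
#' SC 5.1 strains (each strain its own subclade, e.g. Ia, Ib) plus
#' \code{n_outgroup} outgroup genomes, with genome lengths drawn uniformly
#' in the configured range.
#'
#' @param cfg a \code{\link{simulation_config}}
#' @param seed RNG seed
#' @return list with \code{tree} (a \code{taxonomy_tree}) and
#'   \code{records} (the strain table).
#' @export
simulate_reference_set <- function(cfg = simulation_config(), seed = 1L) {
  if (cfg$n_clades < 1L) stop("need at least one clade")
  .with_seed(seed, {
    clades <- .roman(seq_len(cfg$n_clades))
    recs <- do.call(rbind, lapply(clades, function(cl) {
      data.frame(
        strain_id = paste0("Syn", cl, "_", seq_len(cfg$strains_per_clade)),
        subclade = paste0(cl, letters[seq_len(cfg$strains_per_clade)]),
        clade = cl, subcluster = "5.1", genus = "Synechococcus",
        genome_length_bp = round(stats::runif(cfg$strains_per_clade,
                                              cfg$genome_length_range[1],
                                              cfg$genome_length_range[2])),
        outgroup = FALSE, stringsAsFactors = FALSE)
    }))
    if (cfg$n_outgroup > 0L) {
      recs <- rbind(recs, data.frame(
        strain_id = paste0("OUT_", seq_len(cfg$n_outgroup)),
        subclade = NA_character_, clade = NA_character_,
        subcluster = NA_character_, genus = NA_character_,
        genome_length_bp = round(stats::runif(cfg$n_outgroup, 2e6, 6e6)),
        outgroup = TRUE, stringsAsFactors = FALSE))
    }
    list(tree = build_taxonomy(recs), records = recs)
  })
}

.sim_bitscore <- function(alen, pident) {
  pmax(30, 2 * alen * (pident / 100 - 0.5))
}

.hit_row <- function(read_id, genome_id, qlen, qcov, pident,
                     evalue = NULL) {
  alen <- pmax(30L, as.integer(round(qcov * qlen)))
  bs <- .sim_bitscore(alen, pident)
  if (is.null(evalue)) evalue <- 10^(-pmin(bs / 10, 180))
  data.frame(
    qseqid = read_id, sseqid = genome_id, pident = round(pident, 2),
    length = alen, mismatch = as.integer(round(alen * (1 - pident / 100))),
    gapopen = 0L, qstart = 1L, qend = alen,
    sstart = 1000L, send = 1000L + alen - 1L,
    evalue = evalue, bitscore = round(bs, 1), qlen = qlen,
    read_id = read_id, genome_id = genome_id,
    stringsAsFactors = FALSE)
}

#' Simulate two-pass hit tables with known read origins
#'
#' Each read draws a true source clade from \code{composition} and a source
#' strain uniformly within it. The pass-1 table holds one best hit per read
#' (outgroup contamination, low-coverage and high-e-value reads planted at
#' the configured fractions exercise every pass-1 filter); the pass-2 table
#' holds the multi-genome hits: the source strain in the within-strain
#' identity band, same-clade strains in the within-clade band, and
#' cross-clade strains strictly below the 80% discontinuity. Bit scores are
#' monotone in aligned length x identity.
#'
#' @param tree a \code{taxonomy_tree} from \code{\link{simulate_reference_set}}
#' @param composition named vector of clade fractions summing to 1
#' @param n_reads number of reads
#' @param cfg a \code{\link{simulation_config}}
#' @param seed RNG seed
#' @param read_prefix prefix for read ids
#' @return list with \code{pass1}, \code{pass2} (hit data.frames in
#'   tabular-BLAST + qlen layout), \code{truth} (read_id, true_strain,
#'   true_clade; outgroup reads labelled "outgroup") and \code{planted}
#'   (counts of reads planted to fail each pass-1 filter).
#' @export
simulate_hit_tables <- function(tree, composition, n_reads,
                                cfg = simulation_config(), seed = 1L,
                                read_prefix = "read") {
  if (abs(sum(composition) - 1) > 1e-6)
    stop("'composition' must sum to 1")
  st <- tree$strains[!tree$strains$outgroup, , drop = FALSE]
  recs <- taxonomy_records(tree)
  recs_in <- recs[!recs$outgroup, , drop = FALSE]
  unknown <- setdiff(names(composition), recs_in$clade)
  if (length(unknown))
    stop("composition names not in taxonomy: ", paste(unknown, collapse = ", "))
  og <- tree$strains$strain_id[tree$strains$outgroup]
  if (cfg$outgroup_fraction > 0 && length(og) == 0L)
    stop("outgroup fraction > 0 but the taxonomy has no outgroup strains")

  .with_seed(seed, {
    read_id <- sprintf("%s_%06d", read_prefix, seq_len(n_reads))
    qlen <- pmax(100L, as.integer(round(stats::rnorm(
      n_reads, cfg$read_len_mean, cfg$read_len_sd))))
    true_clade <- sample(names(composition), n_reads, replace = TRUE,
                         prob = composition)
    true_strain <- vapply(true_clade, function(cl)
      sample(recs_in$strain_id[recs_in$clade == cl], 1L), character(1))

    n_og <- stats::rbinom(1L, n_reads, cfg$outgroup_fraction)
    is_og <- seq_len(n_reads) %in% sample.int(n_reads, n_og)
    rest <- which(!is_og)
    n_lq <- stats::rbinom(1L, length(rest), cfg$low_qcov_fraction)
    lq <- rest[sample.int(length(rest), n_lq)]
    rest2 <- setdiff(rest, lq)
    n_he <- stats::rbinom(1L, length(rest2), cfg$high_evalue_fraction)
    he <- rest2[sample.int(length(rest2), n_he)]

    true_strain[is_og] <- NA_character_
    true_clade[is_og] <- "outgroup"

    # pass 1: one best hit per read
    p1_genome <- ifelse(is_og, sample(og, n_reads, replace = TRUE),
                        true_strain)
    p1_id <- ifelse(is_og,
                    stats::runif(n_reads, cfg$id_outgroup[1],
                                 cfg$id_outgroup[2]),
                    stats::runif(n_reads, cfg$id_within_strain[1],
                                 cfg$id_within_strain[2]))
    p1_qcov <- stats::runif(n_reads, cfg$qcov_range[1], cfg$qcov_range[2])
    p1_qcov[lq] <- stats::runif(length(lq), 0.5, 0.85)
    pass1 <- .hit_row(read_id, p1_genome, qlen, p1_qcov, p1_id)
    pass1$evalue[he] <- stats::runif(length(he), 1e-3, 1e-1)

    # pass 2: multi-genome hits for non-outgroup reads
    p2 <- vector("list", n_reads)
    clade_of <- stats::setNames(recs_in$clade, recs_in$strain_id)
    for (i in which(!is_og)) {
      strains <- true_strain[i]
      idents <- stats::runif(1, cfg$id_within_strain[1],
                             cfg$id_within_strain[2])
      sibs <- recs_in$strain_id[recs_in$clade == true_clade[i] &
                                  recs_in$strain_id != true_strain[i]]
      sibs <- sibs[stats::runif(length(sibs)) < cfg$sibling_hit_prob]
      others <- recs_in$strain_id[recs_in$clade != true_clade[i]]
      others <- others[stats::runif(length(others)) < cfg$cross_hit_prob]
      strains <- c(strains, sibs, others)
      idents <- c(idents,
                  stats::runif(length(sibs), cfg$id_within_clade[1],
                               cfg$id_within_clade[2]),
                  stats::runif(length(others), cfg$id_cross_clade[1],
                               cfg$id_cross_clade[2]))
      qc <- c(p1_qcov[i],
              stats::runif(length(strains) - 1L, cfg$qcov_range[1],
                           cfg$qcov_range[2]))
      p2[[i]] <- .hit_row(rep(read_id[i], length(strains)), strains,
                          qlen[i], qc, idents)
    }
    pass2 <- do.call(rbind, p2[!vapply(p2, is.null, logical(1))])
    rownames(pass2) <- NULL

    list(pass1 = pass1, pass2 = pass2,
         truth = data.frame(read_id = read_id, true_strain = true_strain,
                            true_clade = true_clade,
                            stringsAsFactors = FALSE),
         planted = list(outgroup = sum(is_og), low_qcov = length(lq),
                        high_evalue = length(he)))
  })
}

#' Simulate a station survey with temperature-keyed composition regimes
#'
#' Stations are split round-robin across the configured regimes; each
#' station's clade composition is a Dirichlet perturbation of its regime's
#' composition, its temperature and salinity are drawn from the regime's
#' distributions, and its reads are generated by
#' \code{\link{simulate_hit_tables}}. The first
#' \code{low_coverage_stations} stations are planted with sub-threshold
#' read depth to exercise the reads/Mbp station filter.
#'
#' @param cfg a \code{\link{simulation_config}}
#' @param seed RNG seed
#' @return list with \code{tree}, \code{stations} (named list of hit-table
#'   bundles), \code{meta} (station metadata data.frame) and \code{truth}
#'   (station_id, regime, planted_low_coverage).
#' @export
simulate_stations <- function(cfg = simulation_config(), seed = 1L) {
  if (length(cfg$regimes) < 1L) stop("need at least one regime")
  ref <- simulate_reference_set(cfg, seed = seed)
  .with_seed(seed + 1L, {
    n <- cfg$n_stations
    regime_names <- names(cfg$regimes)
    regime <- rep(regime_names, length.out = n)
    station_id <- sprintf("OSD%03d", seq_len(n))
    low <- seq_len(n) <= cfg$low_coverage_stations

    meta <- data.frame(station_id = station_id,
                       temperature_C = NA_real_, salinity_psu = NA_real_,
                       lat = round(stats::runif(n, -60, 60), 3),
                       lon = round(stats::runif(n, -180, 180), 3),
                       dist_coast_nm = round(stats::rexp(n, 1 / 5), 1),
                       stringsAsFactors = FALSE)
    stations <- vector("list", n)
    seeds <- sample.int(1e6, n)
    for (i in seq_len(n)) {
      rg <- cfg$regimes[[regime[i]]]
      comp <- .rdirichlet(cfg$dirichlet_conc * rg$composition)
      names(comp) <- names(rg$composition)
      meta$temperature_C[i] <- round(stats::rnorm(1, rg$temperature[1],
                                                  rg$temperature[2]), 2)
      meta$salinity_psu[i] <- round(stats::rnorm(1, rg$salinity[1],
                                                 rg$salinity[2]), 2)
      depth <- if (low[i]) cfg$low_coverage_depth else cfg$reads_per_station
      stations[[i]] <- simulate_hit_tables(
        ref$tree, comp, depth, cfg, seed = seeds[i],
        read_prefix = station_id[i])
    }
    names(stations) <- station_id
    list(tree = ref$tree, stations = stations, meta = meta,
         truth = data.frame(station_id = station_id, regime = regime,
                            planted_low_coverage = low,
                            stringsAsFactors = FALSE))
  })
}

#' Default cardinal parameters for the simulated strain panel
#'
#' Two strains per clade I-IV: cold-adapted thermotypes (clades I and IV)
#' with low cardinal temperatures, warm thermotypes (clades II and III)
#' with high ones.
#'
#' @return data.frame \code{strain, Tmin, Topt, Tmax, mu_opt}.
#' @export
default_growth_panel <- function() {
  data.frame(
    strain = c("SynI_1", "SynI_2", "SynIV_1", "SynIV_2",
               "SynII_1", "SynII_2", "SynIII_1", "SynIII_2"),
    Tmin = c(-3, -2, -2.5, -1.5, 6, 7, 5, 6.5),
    Topt = c(22, 21, 23, 22.5, 28, 29, 27, 28.5),
    Tmax = c(26, 25.5, 27, 26.5, 32.5, 33.5, 31.5, 33),
    mu_opt = c(0.55, 0.6, 0.5, 0.65, 0.9, 0.85, 0.95, 0.8),
    stringsAsFactors = FALSE)
}

#' Simulate growth curves from CTMI-shaped thermal responses
#'
#' For every strain x temperature x replicate, cell densities follow
#' N(t) = N0 exp(mu(T) t) capped at the carrying capacity (stationary
#' phase), with multiplicative lognormal measurement noise of coefficient
#' of variation \code{growth_cv}; mu(T) comes from \code{\link{ctmi_mu}}.
#' Temperatures beyond the strain's viable range give flat curves.
#'
#' @param panel data.frame \code{strain, Tmin, Topt, Tmax, mu_opt}
#'   (default \code{\link{default_growth_panel}})
#' @param cfg a \code{\link{simulation_config}}
#' @param seed RNG seed
#' @return list with \code{curves} (strain, temperature_C, replicate,
#'   time_days, cells_per_ml) and \code{truth} (the panel).
#' @export
simulate_growth_curves <- function(panel = default_growth_panel(),
                                   cfg = simulation_config(), seed = 1L) {
  for (i in seq_len(nrow(panel)))
    .check_cardinal(panel$Tmin[i], panel$Topt[i], panel$Tmax[i],
                    panel$mu_opt[i])
  .with_seed(seed, {
    grid <- expand.grid(strain = panel$strain,
                        temperature_C = cfg$growth_temps,
                        replicate = seq_len(cfg$growth_reps),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      p <- panel[panel$strain == grid$strain[i], ]
      mu <- ctmi_mu(grid$temperature_C[i], p$Tmin, p$Topt, p$Tmax, p$mu_opt)
      n <- pmin(cfg$n0 * exp(mu * cfg$growth_times), cfg$capacity)
      if (cfg$growth_cv > 0) {
        sdlog <- sqrt(log(1 + cfg$growth_cv^2))
        n <- n * stats::rlnorm(length(n), -sdlog^2 / 2, sdlog)
      }
      data.frame(strain = grid$strain[i],
                 temperature_C = grid$temperature_C[i],
                 replicate = grid$replicate[i],
                 time_days = cfg$growth_times, cells_per_ml = n,
                 stringsAsFactors = FALSE)
    })
    list(curves = do.call(rbind, rows), truth = panel)
  })
}

#' Simulate replicate growth rates directly from the thermal response
#'
#' Rate-level shortcut used for recovery and coverage studies: mu
#' observations are the CTMI value plus Gaussian noise of sd \code{sigma},
#' clamped at zero (non-growing cultures are recorded as zero growth).
#'
#' @param params one-row data.frame or list with Tmin, Topt, Tmax, mu_opt
#' @param temps temperatures
#' @param n_reps replicates per temperature
#' @param sigma rate noise sd (per day)
#' @param seed RNG seed
#' @return data.frame \code{temperature_C, mu_per_day}.
#' @export
simulate_rates <- function(params, temps = seq(10, 33, by = 3), n_reps = 3L,
                           sigma = 0.05, seed = 1L) {
  .with_seed(seed, {
    temp <- rep(temps, each = n_reps)
    mu <- ctmi_mu(temp, params$Tmin, params$Topt, params$Tmax,
                  params$mu_opt)
    mu <- pmax(0, mu + stats::rnorm(length(mu), 0, sigma))
    data.frame(temperature_C = temp, mu_per_day = mu)
  })
}
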