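#' Configuration for the synthetic aerobiome generator
#'
#' Encodes the study conditions the generator emulates: multi-city,
#' multi-year air sampling with ~20 pooled negative controls; a common
#' contaminant source (kitome/handler profile) shared across negatives and
#' mixed into air samples at a Beta-distributed read fraction around a mean
#' of 0.627; lognormal species abundances sampled multinomially at a
#' lognormal per-sample depth; city-specific species pools on top of a
#' shared pool; and planted per-city core species guaranteed high relative
#' abundance so the prevalence-based core definition holds by construction.
#'
#' @param n_cities number of cities (default 6).
#' @param years sampling years (default 2017:2019).
#' @param samples_per_city_year air samples per city per year (default 14).
#' @param n_negatives pooled negative controls (default 22; split field/lab).
#' @param n_species_shared species in the shared air pool (default 120).
#' @param n_species_city_specific extra species private to each city
#'   (default 40).
#' @param n_contaminants contaminant taxa (default 60).
#' @param n_contaminants_in_air contaminants also genuinely present in the
#'   air pool (the hard case for the prevalence gate; default 5).
#' @param contaminant_read_fraction_mean mean fraction of an air sample's
#'   classified reads that are contaminant-derived (default 0.627).
#' @param contaminant_fraction_conc Beta concentration for the per-sample
#'   contaminant fraction (default 20; larger = less dispersion).
#' @param depth_meanlog,depth_sdlog lognormal parameters of per-sample
#'   classified read depth (defaults log(1e6) and 0.5).
#' @param abundance_shape lognormal sigma of species abundances (default 1.5).
#' @param city_effect_size multiplicative fold on city-specific species
#'   (default 8).
#' @param core_species_per_city planted core species per city (default 10).
#' @param core_min_rel_abundance minimum expected within-city relative
#'   abundance of each planted core species (default 0.01).
#' @param negative_background_fraction fraction of each negative control's
#'   reads drawn from a sparse air-species background rather than the
#'   contaminant profile (default 0.03, the residue real blanks retain).
#' @param species_occupancy probability that a non-core pool species is
#'   present in any given air sample (default 0.6); models the transient,
#'   low-prevalence character of most aerobiome taxa. Planted core species
#'   always have occupancy 1.
#' @param humidity_effect_size multiplicative fold applied to a subset of
#'   shared species in high-humidity samples (default 0 = no effect).
#' @param seed integer seed driving the single RNG stream.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cities = 6,
                             years = 2017:2019,
                             samples_per_city_year = 14,
                             n_negatives = 22,
                             n_species_shared = 120,
                             n_species_city_specific = 40,
                             n_contaminants = 60,
                             n_contaminants_in_air = 5,
                             contaminant_read_fraction_mean = 0.627,
                             contaminant_fraction_conc = 20,
                             depth_meanlog = log(1e6),
                             depth_sdlog = 0.5,
                             abundance_shape = 1.5,
                             city_effect_size = 8,
                             core_species_per_city = 10,
                             core_min_rel_abundance = 0.01,
                             negative_background_fraction = 0.03,
                             species_occupancy = 0.6,
                             humidity_effect_size = 0,
                             seed = 1L) {
  cfg <- list(n_cities = n_cities, years = years,
              samples_per_city_year = samples_per_city_year,
              n_negatives = n_negatives,
              n_species_shared = n_species_shared,
              n_species_city_specific = n_species_city_specific,
              n_contaminants = n_contaminants,
              n_contaminants_in_air = n_contaminants_in_air,
              contaminant_read_fraction_mean = contaminant_read_fraction_mean,
              contaminant_fraction_conc = contaminant_fraction_conc,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              abundance_shape = abundance_shape,
              city_effect_size = city_effect_size,
              core_species_per_city = core_species_per_city,
              core_min_rel_abundance = core_min_rel_abundance,
              negative_background_fraction = negative_background_fraction,
              species_occupancy = species_occupancy,
              humidity_effect_size = humidity_effect_size,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cities >= 1, samples_per_city_year >= 1, n_negatives >= 2,
              n_species_shared >= 1, n_contaminants >= 1,
              depth_sdlog >= 0, abundance_shape > 0)
    if (contaminant_read_fraction_mean < 0 ||
        contaminant_read_fraction_mean >= 1) {
      stop("contaminant_read_fraction_mean must lie in [0,1)")
    }
    if (core_species_per_city > n_species_city_specific) {
      stop("core_species_per_city exceeds the city-specific pool size")
    }
    if (n_contaminants_in_air > n_contaminants) {
      stop("n_contaminants_in_air exceeds n_contaminants")
    }
    if (species_occupancy <= 0 || species_occupancy > 1) {
      stop("species_occupancy must lie in (0,1]")
    }
    if (negative_background_fraction < 0 || negative_background_fraction >= 1) {
      stop("negative_background_fraction must lie in [0,1)")
    }
  })
  class(cfg) <- "synthetic_config"
  cfg
}

city_names <- c("Avalon", "Brightwater", "Calder", "Dunmore", "Eastvale",
                "Farrow", "Gatley", "Harwick")

#' Generate a synthetic aerobiome dataset with planted ground truth
#'
#' Deterministic given `config$seed`. Returns the merged raw taxon count
#' table (air samples, field/lab negatives and one positive control per
#' year), the sample metadata, and a `truth` list holding the planted
#' contaminant taxid set, per-city core taxid sets, per-sample planted
#' contaminant read fractions and the config echo.
#'
#' Negatives carry the shared contaminant profile (with per-sample
#' Dirichlet jitter) plus a sparse low-level background of air species;
#' air samples mix the contaminant profile at a Beta-distributed fraction
#' with the city pool. Temperature and humidity are drawn per city,
#' ground level per locality, so covariate-recovery analyses have signal
#' to find.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `table` ([taxon_table]), `metadata`
#'   (data frame) and `truth` (list).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)

  n_city_sp <- cfg$n_cities * cfg$n_species_city_specific
  n_taxa <- cfg$n_contaminants + cfg$n_species_shared + n_city_sp
  taxid <- seq_len(n_taxa) + 100000L
  role <- c(rep("contaminant", cfg$n_contaminants),
            rep("shared", cfg$n_species_shared),
            rep(paste0("city", seq_len(cfg$n_cities)),
                each = cfg$n_species_city_specific))
  kingdom <- sample(c("Bacteria", "Fungi", "Virus", "Archaea"), n_taxa,
                    replace = TRUE, prob = c(0.72, 0.24, 0.02, 0.02))
  # the study's contaminant inventory is bacterial/fungal only
  kingdom[role == "contaminant"] <-
    sample(c("Bacteria", "Fungi"), cfg$n_contaminants, replace = TRUE,
           prob = c(0.91, 0.09))
  taxa <- data.frame(taxid = taxid,
                     name = paste0(tolower(kingdom), " sp. SYN", taxid),
                     rank = "species", kingdom = kingdom,
                     stringsAsFactors = FALSE)

  cities <- city_names[seq_len(cfg$n_cities)]

  # base lognormal abundance profiles
  contam_idx <- which(role == "contaminant")
  shared_idx <- which(role == "shared")
  contam_profile <- numeric(n_taxa)
  contam_profile[contam_idx] <-
    stats::rlnorm(length(contam_idx), 0, cfg$abundance_shape)
  contam_profile <- contam_profile / sum(contam_profile)

  shared_ab <- stats::rlnorm(length(shared_idx), 0, cfg$abundance_shape)

  # contaminants that are also genuine members of the air pool
  contam_in_air <- integer(0)
  if (cfg$n_contaminants_in_air > 0) {
    contam_in_air <- sample(contam_idx, cfg$n_contaminants_in_air)
  }

  city_profiles <- matrix(0, nrow = cfg$n_cities, ncol = n_taxa)
  city_core <- vector("list", cfg$n_cities)
  names(city_core) <- cities
  city_core_idx <- vector("list", cfg$n_cities)
  humidity_species <- sample(shared_idx, max(1, length(shared_idx) %/% 6))
  for (ci in seq_len(cfg$n_cities)) {
    prof <- numeric(n_taxa)
    prof[shared_idx] <- shared_ab
    own_idx <- which(role == paste0("city", ci))
    prof[own_idx] <- stats::rlnorm(length(own_idx), 0, cfg$abundance_shape) *
      cfg$city_effect_size
    if (length(contam_in_air) > 0) {
      prof[contam_in_air] <- stats::rlnorm(length(contam_in_air), 0,
                                           cfg$abundance_shape)
    }
    core_idx <- own_idx[seq_len(cfg$core_species_per_city)]
    city_core[[ci]] <- taxid[core_idx]
    city_core_idx[[ci]] <- core_idx
    prof <- prof / sum(prof)
    # lift planted core species to a floor well above the detection level
    prof[core_idx] <- pmax(prof[core_idx], cfg$core_min_rel_abundance)
    prof <- prof / sum(prof)
    city_profiles[ci, ] <- prof
  }

  n_air <- cfg$n_cities * length(cfg$years) * cfg$samples_per_city_year
  air_city <- rep(rep(seq_len(cfg$n_cities), each = cfg$samples_per_city_year),
                  times = length(cfg$years))
  air_year <- rep(cfg$years, each = cfg$n_cities * cfg$samples_per_city_year)

  fr_mean <- cfg$contaminant_read_fraction_mean
  if (fr_mean > 0) {
    a <- fr_mean * cfg$contaminant_fraction_conc
    b <- (1 - fr_mean) * cfg$contaminant_fraction_conc
    contam_frac <- stats::rbeta(n_air, a, b)
  } else {
    contam_frac <- rep(0, n_air)
  }
  depth <- pmax(1000, round(stats::rlnorm(n_air, cfg$depth_meanlog,
                                          cfg$depth_sdlog)))

  # per-city environmental covariates
  city_temp <- stats::runif(cfg$n_cities, 15, 32)
  city_hum <- stats::runif(cfg$n_cities, 40, 85)

  counts <- matrix(0L, nrow = n_air + cfg$n_negatives +
                     length(cfg$years), ncol = n_taxa)
  sample_id <- character(nrow(counts))
  temperature <- humidity <- numeric(n_air)

  jitter_profile <- function(p, conc = 200) {
    nz <- p > 0
    g <- stats::rgamma(sum(nz), shape = p[nz] * conc, rate = 1)
    if (sum(g) == 0) g[] <- 1
    out <- numeric(length(p))
    out[nz] <- g / sum(g)
    out
  }

  for (i in seq_len(n_air)) {
    ci <- air_city[i]
    temperature[i] <- stats::rnorm(1, city_temp[ci], 2.5)
    humidity[i] <- min(99, max(10, stats::rnorm(1, city_hum[ci], 6)))
    prof <- city_profiles[ci, ]
    # transient occupancy of non-core pool species (cores always present)
    if (cfg$species_occupancy < 1) {
      occ_idx <- setdiff(which(prof > 0), city_core_idx[[ci]])
      off <- occ_idx[stats::runif(length(occ_idx)) > cfg$species_occupancy]
      prof[off] <- 0
      prof <- prof / sum(prof)
    }
    if (cfg$humidity_effect_size > 0 && humidity[i] > 65) {
      prof[humidity_species] <- prof[humidity_species] *
        (1 + cfg$humidity_effect_size)
      prof <- prof / sum(prof)
    }
    mix <- contam_frac[i] * jitter_profile(contam_profile) +
      (1 - contam_frac[i]) * prof
    counts[i, ] <- stats::rmultinom(1, depth[i], mix)[, 1]
    sample_id[i] <- sprintf("AIR%04d", i)
  }

  # negatives: shared contaminant profile + sparse background of air species
  neg_depth <- pmax(500, round(stats::rlnorm(cfg$n_negatives,
                                             cfg$depth_meanlog - log(10),
                                             cfg$depth_sdlog)))
  for (j in seq_len(cfg$n_negatives)) {
    i <- n_air + j
    bg <- numeric(n_taxa)
    bg_idx <- sample(shared_idx, min(10, length(shared_idx)))
    bg[bg_idx] <- stats::rlnorm(length(bg_idx), 0, 1)
    bg <- bg / sum(bg)
    bgf <- cfg$negative_background_fraction
    mix <- (1 - bgf) * jitter_profile(contam_profile) + bgf * bg
    counts[i, ] <- stats::rmultinom(1, neg_depth[j], mix)[, 1]
    sample_id[i] <- sprintf("NEG%03d", j)
  }

  # one even positive control per year (mock community on shared species)
  mock_idx <- shared_idx[seq_len(min(8, length(shared_idx)))]
  for (k in seq_along(cfg$years)) {
    i <- n_air + cfg$n_negatives + k
    p <- numeric(n_taxa)
    p[mock_idx] <- 1 / length(mock_idx)
    counts[i, ] <- stats::rmultinom(1, 1e5, p)[, 1]
    sample_id[i] <- sprintf("POS%03d", k)
  }

  rownames(counts) <- sample_id
  storage.mode(counts) <- "integer"

  n_loc <- 3
  air_loc <- paste0(cities[air_city], "_L",
                    1 + (seq_len(n_air) %% n_loc))
  loc_levels <- unique(air_loc)
  loc_ground <- sample(c("above", "below"), length(loc_levels), replace = TRUE)
  names(loc_ground) <- loc_levels

  neg_type <- rep(c("field_negative", "lab_negative"),
                  length.out = cfg$n_negatives)
  plate <- sprintf("P%d:%s%02d",
                   1 + (seq_len(nrow(counts)) - 1) %/% 96,
                   LETTERS[1 + ((seq_len(nrow(counts)) - 1) %% 96) %/% 12],
                   1 + (seq_len(nrow(counts)) - 1) %% 12)
  coverage_air <- pmin(1, pmax(0, stats::plogis((log(depth) -
    cfg$depth_meanlog) / cfg$depth_sdlog) + stats::rnorm(n_air, 0, 0.05)))

  metadata <- data.frame(
    sample_id = sample_id,
    city = c(cities[air_city], rep("Control", cfg$n_negatives),
             rep("Control", length(cfg$years))),
    year = c(air_year,
             rep(cfg$years, length.out = cfg$n_negatives),
             cfg$years),
    sample_type = c(rep("air", n_air), neg_type,
                    rep("positive", length(cfg$years))),
    locality = c(air_loc, rep(NA_character_,
                              cfg$n_negatives + length(cfg$years))),
    temperature = c(temperature, rep(NA_real_,
                                     cfg$n_negatives + length(cfg$years))),
    humidity = c(humidity, rep(NA_real_,
                               cfg$n_negatives + length(cfg$years))),
    travellers = c(round(stats::rlnorm(n_air, log(80), 0.9)),
                   rep(NA_real_, cfg$n_negatives + length(cfg$years))),
    ground_level = c(loc_ground[air_loc],
                     rep(NA_character_, cfg$n_negatives + length(cfg$years))),
    enclosure = NA_character_,
    dna_conc = c(round(stats::rlnorm(n_air, log(0.5), 0.8), 3),
                 rep(NA_real_, cfg$n_negatives + length(cfg$years))),
    dna_below_detection = c(rep(FALSE, n_air),
                            rep(TRUE, cfg$n_negatives),
                            rep(FALSE, length(cfg$years))),
    plate_position = plate,
    nonpareil_coverage = c(coverage_air,
                           rep(NA_real_, cfg$n_negatives + length(cfg$years))),
    stringsAsFactors = FALSE)
  rownames(metadata) <- NULL

  truth <- list(
    contaminant_taxids = taxid[contam_idx],
    contaminants_in_air_taxids = taxid[contam_in_air],
    city_core_taxids = city_core,
    contaminant_fraction = stats::setNames(contam_frac, sample_id[seq_len(n_air)]),
    config = cfg)

  list(table = taxon_table(counts, taxa, transform = "raw"),
       metadata = metadata, truth = truth)
}

#' Generate an even mock positive-control sample
#'
#' A single-sample table mimicking an even mock community standard
#' (equal nominal proportions), multinomially sampled at the given depth.
#' Used to sanity-check the abundance threshold: every mock member sits
#' far above a 0.005% cut-off.
#'
#' @param n_species number of mock members (default 8).
#' @param depth total classified reads (must be positive).
#' @param even if FALSE, a lognormal staggered composition is used instead.
#' @param seed RNG seed.
#' @return a single-sample raw [taxon_table].
#' @export
generate_positive_control <- function(n_species = 8, depth = 1e6,
                                      even = TRUE, seed = 1L) {
  if (depth <= 0) stop("depth must be positive")
  stopifnot(n_species >= 1)
  set.seed(seed)
  p <- if (even) rep(1 / n_species, n_species) else {
    w <- stats::rlnorm(n_species, 0, 1.5)
    w / sum(w)
  }
  counts <- matrix(stats::rmultinom(1, depth, p)[, 1], nrow = 1,
                   dimnames = list("MOCK001", NULL))
  taxa <- data.frame(taxid = seq_len(n_species) + 900000L,
                     name = paste0("mock sp. M", seq_len(n_species)),
                     rank = "species", kingdom = "Bacteria",
                     stringsAsFactors = FALSE)
  taxon_table(counts, taxa, transform = "raw")
}
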