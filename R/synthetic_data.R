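# Synthetic inputs with known ground truth, emulating a two-site tableting
# study: two production sites (A and B) share an excipient-derived ASV pool
# but differ in site-specific dust- and water-derived pools; tablets are
# manufactured by direct compression (dry) or wet granulation (water added),
# under closed or open laboratory atmospheres; a foreign-water control group
# mixes site-A dust with site-B water. Sequencing counts follow a
# Dirichlet-multinomial, DART-MS spectra carry site-shifted peak
# intensities, and biogeography combines narrow-range site species with
# cosmopolitan ones.

#' Default configuration for the count-table generator
#'
#' The eight tablet groups mirror the study design: per site, direct
#' compression under closed (`*-1`) and open (`*-2`) atmospheres and wet
#' granulation with local water (`*-3`); site A additionally produces a
#' wet-granulation group without water (`E-4`) and one with site-B water
#' (`E-5`, the prediction-only foreign-water control). Three tablets per
#' group, two excipient samples, one dust and one water sample per site and
#' two negative controls. Per-sample read depths are drawn uniformly from
#' 5264-329354 reads, a realistic 16S range for such tablets; the
#' foreign-water group's dust:water admixture is 3:1 so its environmental
#' signature dominates its water signature.
#'
#' @param n_excipient,n_dust,n_water,n_contam ASVs per source pool (dust and
#'   water pools are per site).
#' @param frac_dust_closed,frac_dust_open,frac_dust_wg,frac_water_wg
#'   Admixture fractions of the tablet community contributed by dust/water
#'   under each scenario (the remainder is excipient-derived).
#' @param frac_contam Trace contamination fraction present in every sample.
#' @param depth_range,control_depth_range Read-depth ranges (uniform).
#' @param theta Dirichlet concentration (lower = more overdispersion).
#' @param planted Optional `list(n = , lfc = )`: plant a country effect of
#'   `|lfc|` log2 units on `n` ASVs of the shared pool (half overabundant in
#'   each country) instead of relying on presence/absence pool structure.
#' @return A config list for [simulate_counts()].
#' @export
default_counts_config <- function(n_excipient = 120, n_dust = 60,
                                  n_water = 30, n_contam = 10,
                                  frac_dust_closed = 0.03,
                                  frac_dust_open = 0.10,
                                  frac_dust_wg = 0.18,
                                  frac_water_wg = 0.06,
                                  frac_contam = 0.005,
                                  depth_range = c(5264, 329354),
                                  control_depth_range = c(200, 1000),
                                  theta = 1000,
                                  planted = NULL) {
  groups <- data.frame(
    group_label  = c("T-1", "T-2", "T-3", "E-1", "E-2", "E-3", "E-4", "E-5"),
    country      = c("B", "B", "B", "A", "A", "A", "A", "A"),
    manufacturing = c("direct_compression", "direct_compression",
                      "wet_granulation", "direct_compression",
                      "direct_compression", "wet_granulation",
                      "wet_granulation", "wet_granulation"),
    water_source = c("none", "none", "local", "none", "none", "local",
                     "none", "foreign"),
    atmosphere   = c("closed", "open", "open", "closed", "open", "open",
                     "open", "open"),
    n_tablets    = 3,
    stringsAsFactors = FALSE
  )
  list(groups = groups, prediction_only = "E-5",
       n_excipient = n_excipient, n_dust = n_dust, n_water = n_water,
       n_contam = n_contam,
       frac_dust_closed = frac_dust_closed, frac_dust_open = frac_dust_open,
       frac_dust_wg = frac_dust_wg, frac_water_wg = frac_water_wg,
       frac_contam = frac_contam,
       depth_range = depth_range, control_depth_range = control_depth_range,
       theta = theta, planted = planted,
       n_excipient_samples = 2, n_env_samples = 1, n_controls = 2)
}

#' Benchmark configuration for differential-abundance recovery
#'
#' All tablets share one pool of `n_asvs` ASVs; `n_planted` of them carry a
#' true country effect of `lfc` log2 units (half overabundant in each
#' country), the rest are null. Site-specific dust/water pools are disabled
#' so the only systematic country signal is the planted one.
#'
#' @param n_asvs Total shared-pool ASVs (default 500).
#' @param n_planted ASVs with a planted effect (default 50).
#' @param lfc Planted |log2-fold change| (default 3).
#' @param ... Passed to [default_counts_config()].
#' @return A config list for [simulate_counts()].
#' @export
da_benchmark_config <- function(n_asvs = 500, n_planted = 50, lfc = 3, ...) {
  default_counts_config(n_excipient = n_asvs, n_dust = 0, n_water = 0,
                        n_contam = 0,
                        frac_dust_closed = 0, frac_dust_open = 0,
                        frac_dust_wg = 0, frac_water_wg = 0,
                        frac_contam = 0,
                        planted = list(n = n_planted, lfc = lfc), ...)
}

#' Simulate an ASV count table with known ground truth
#'
#' Tablet communities are mixtures of the excipient pool with
#' scenario-dependent dust and water admixtures (closed atmosphere: small
#' dust fraction; open: larger; wet granulation: dust plus water, dust
#' dominating); the foreign-water group mixes site-A dust with site-B
#' water. Counts are drawn from a Dirichlet-multinomial at a per-sample
#' depth drawn uniformly from the configured range. Negative controls carry
#' sparse contamination ASVs, which also seep into every other sample at a
#' trace fraction.
#'
#' @param config From [default_counts_config()] or [da_benchmark_config()].
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A list: `counts` (a [count_table()]), `sheet` (a
#'   [sample_sheet()]), `truth` (data frame: `asv_id`, `source_pool`,
#'   `planted_lfc`, `base_abundance`).
#' @export
simulate_counts <- function(config = default_counts_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cfg <- config
  fr_named <- c(cfg$frac_dust_closed, cfg$frac_dust_open,
                cfg$frac_dust_wg + cfg$frac_water_wg, cfg$frac_contam)
  if (any(fr_named < 0) || any(fr_named > 1) || max(fr_named) + cfg$frac_contam > 1)
    stop("admixture fractions must leave a positive excipient remainder")

  pools <- c(rep("excipient", cfg$n_excipient),
             rep("dust_A", cfg$n_dust), rep("dust_B", cfg$n_dust),
             rep("water_A", cfg$n_water), rep("water_B", cfg$n_water),
             rep("control_contam", cfg$n_contam))
  n_asv <- length(pools)
  asv_ids <- sprintf("ASV_%04d", seq_len(n_asv))
  base <- rlnorm(n_asv, meanlog = 0, sdlog = 1)

  planted_lfc <- rep(0, n_asv)
  if (!is.null(cfg$planted)) {
    shared <- which(pools == "excipient")
    if (cfg$planted$n > length(shared))
      stop("cannot plant more effects than shared-pool ASVs")
    idx <- sample(shared, cfg$planted$n)
    half <- length(idx) %/% 2
    planted_lfc[idx[seq_len(half)]] <- cfg$planted$lfc
    planted_lfc[idx[seq(half + 1, length(idx))]] <- -cfg$planted$lfc
  }

  g <- cfg$groups
  samples <- data.frame(sample_id = character(0), sample_type = character(0),
                        country = character(0), manufacturing = character(0),
                        water_source = character(0), group_label = character(0),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(g))) {
    for (t in seq_len(g$n_tablets[k])) {
      samples <- rbind(samples, data.frame(
        sample_id = sprintf("%s_t%d", g$group_label[k], t),
        sample_type = "tablet", country = g$country[k],
        manufacturing = g$manufacturing[k],
        water_source = g$water_source[k], group_label = g$group_label[k],
        stringsAsFactors = FALSE))
    }
  }
  env <- function(id, type, ctry) data.frame(
    sample_id = id, sample_type = type, country = ctry,
    manufacturing = "direct_compression", water_source = "none",
    group_label = type, stringsAsFactors = FALSE)
  for (e in seq_len(cfg$n_excipient_samples))
    samples <- rbind(samples, env(sprintf("EXC_%d", e), "excipient", "unknown"))
  for (e in seq_len(cfg$n_env_samples)) {
    samples <- rbind(samples, env(sprintf("DUST_A_%d", e), "dust", "A"))
    samples <- rbind(samples, env(sprintf("DUST_B_%d", e), "dust", "B"))
    samples <- rbind(samples, env(sprintf("WATER_A_%d", e), "water", "A"))
    samples <- rbind(samples, env(sprintf("WATER_B_%d", e), "water", "B"))
  }
  for (e in seq_len(cfg$n_controls))
    samples <- rbind(samples, env(sprintf("NEG_%d", e), "neg_control",
                                  "unknown"))

  pool_frac_for <- function(row) {
    # returns named fractions over source pools for one sample
    fr <- c(excipient = 0, dust_A = 0, dust_B = 0, water_A = 0, water_B = 0,
            control_contam = cfg$frac_contam)
    if (row$sample_type == "tablet") {
      grp <- g[g$group_label == row$group_label, ]
      dust_pool <- paste0("dust_", row$country)
      f_dust <- if (grp$manufacturing == "wet_granulation") cfg$frac_dust_wg
        else if (grp$atmosphere == "open") cfg$frac_dust_open
        else cfg$frac_dust_closed
      fr[dust_pool] <- f_dust
      if (row$water_source == "local")
        fr[paste0("water_", row$country)] <- cfg$frac_water_wg
      if (row$water_source == "foreign")
        fr[paste0("water_", setdiff(c("A", "B"), row$country))] <-
          cfg$frac_water_wg
      fr["excipient"] <- 1 - sum(fr)
    } else if (row$sample_type == "excipient") {
      fr["excipient"] <- 1 - sum(fr)
    } else if (row$sample_type == "dust") {
      fr[paste0("dust_", row$country)] <- 1 - sum(fr)
    } else if (row$sample_type == "water") {
      fr[paste0("water_", row$country)] <- 1 - sum(fr)
    } else {                                   # negative control
      fr["control_contam"] <- 1
    }
    if (abs(sum(fr) - 1) > 1e-9) stop("admixture fractions do not sum to 1")
    fr
  }

  # environmental/control samples whose source pool is disabled (zero ASVs)
  # cannot be generated; drop them rather than emit empty columns
  pool_sizes <- table(factor(pools, levels = c("excipient", "dust_A",
                                               "dust_B", "water_A", "water_B",
                                               "control_contam")))
  droppable <- vapply(seq_len(nrow(samples)), function(j) {
    row <- samples[j, ]
    pool <- switch(row$sample_type,
                   dust = paste0("dust_", row$country),
                   water = paste0("water_", row$country),
                   neg_control = "control_contam",
                   excipient = "excipient",
                   NA_character_)
    !is.na(pool) && pool_sizes[[pool]] == 0
  }, logical(1))
  if (any(droppable)) {
    warning("dropping ", sum(droppable),
            " environmental/control sample(s) whose source pool is empty")
    samples <- samples[!droppable, , drop = FALSE]
  }

  counts <- matrix(0L, n_asv, nrow(samples),
                   dimnames = list(asv_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    row <- samples[j, ]
    fr <- pool_frac_for(row)
    w <- base
    for (p in names(fr)) {
      sel <- pools == p
      tot <- sum(base[sel])
      w[sel] <- if (tot > 0 && fr[[p]] > 0) base[sel] / tot * fr[[p]] else 0
    }
    if (row$sample_type == "tablet" && any(planted_lfc != 0)) {
      sgn <- if (row$country == "A") 1 else -1
      w <- w * 2^(sgn * planted_lfc / 2)
    }
    if (sum(w) == 0) stop("sample with empty expected community: ",
                          row$sample_id)
    w <- w / sum(w)
    depth_rng <- if (row$sample_type == "neg_control")
      cfg$control_depth_range else cfg$depth_range
    depth <- sample(seq(depth_rng[1], depth_rng[2]), 1)
    active <- w > 0
    p_dir <- numeric(n_asv)
    p_dir[active] <- stats::rgamma(sum(active), shape = cfg$theta * w[active])
    if (sum(p_dir) == 0) p_dir[active] <- w[active]
    counts[, j] <- as.integer(rmultinom(1, depth, p_dir / sum(p_dir)))
  }

  list(counts = count_table(counts, marker = "16S"),
       sheet = sample_sheet(samples, prediction_only = cfg$prediction_only),
       truth = data.frame(asv_id = asv_ids, source_pool = pools,
                          planted_lfc = planted_lfc, base_abundance = base,
                          stringsAsFactors = FALSE))
}

#' Default configuration for the DART-MS spectrum generator
#'
#' Forty shared peaks across all tablets, ten site-specific peaks per site
#' with a planted intensity shift, Gaussian intensity noise, three technical
#' replicates of four tablets per group (96 measurements over the eight
#' groups) and three blank background strips whose peaks also contaminate
#' every tablet spectrum.
#'
#' @param n_shared,n_site Shared and per-site peak counts.
#' @param site_shift Planted intensity difference for site peaks (arbitrary
#'   units, default 50).
#' @param sigma Intensity noise standard deviation (default 5).
#' @param replicates,tablets_per_group Technical replicates and tablets.
#' @param n_blank_peaks,n_blanks Background peaks and blank strips.
#' @return A config list for [simulate_spectra()].
#' @export
default_spectra_config <- function(n_shared = 40, n_site = 10,
                                   site_shift = 50, sigma = 5,
                                   replicates = 3, tablets_per_group = 4,
                                   n_blank_peaks = 8, n_blanks = 3) {
  groups <- data.frame(
    group_label = c("T-1", "T-2", "T-3", "E-1", "E-2", "E-3", "E-4", "E-5"),
    country = c("B", "B", "B", "A", "A", "A", "A", "A"),
    stringsAsFactors = FALSE
  )
  list(groups = groups, prediction_only = "E-5",
       n_shared = n_shared, n_site = n_site, site_shift = site_shift,
       sigma = sigma, replicates = replicates,
       tablets_per_group = tablets_per_group,
       n_blank_peaks = n_blank_peaks, n_blanks = n_blanks,
       mz_range = c(50, 800))
}

#' Simulate DART-MS centroided peak lists with known ground truth
#'
#' @param config From [default_spectra_config()].
#' @param seed Integer seed.
#' @return A list: `spectra` (tablet [spectrum_set()]), `blanks` (blank
#'   [spectrum_set()]), `truth` (per peak: `mz`, `kind` in shared /
#'   site_A / site_B / background, `planted_shift`).
#' @export
simulate_spectra <- function(config = default_spectra_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cfg <- config
  n_pk <- cfg$n_shared + 2 * cfg$n_site + cfg$n_blank_peaks
  mz <- sort(runif(n_pk, cfg$mz_range[1] + 1, cfg$mz_range[2] - 1))
  # keep peaks well separated relative to the 15-mmu alignment tolerance
  while (any(diff(mz) < 0.5))
    mz <- sort(runif(n_pk, cfg$mz_range[1] + 1, cfg$mz_range[2] - 1))
  kind <- sample(c(rep("shared", cfg$n_shared),
                   rep("site_A", cfg$n_site), rep("site_B", cfg$n_site),
                   rep("background", cfg$n_blank_peaks)))
  base_int <- runif(n_pk, 40, 100)
  base_int[kind == "background"] <- runif(sum(kind == "background"), 20, 60)
  truth <- data.frame(mz = mz, kind = kind, base_intensity = base_int,
                      planted_shift = ifelse(kind %in% c("site_A", "site_B"),
                                             cfg$site_shift, 0),
                      stringsAsFactors = FALSE)

  peak_rows <- function(meas_id, tab_id, grp, country, is_blank) {
    keep <- if (is_blank) kind == "background" else kind != "none"
    ints <- numeric(n_pk)
    ints[kind == "background"] <- base_int[kind == "background"]
    if (!is_blank) {
      ints[kind == "shared"] <- base_int[kind == "shared"]
      own <- paste0("site_", country)
      ints[kind == own] <- cfg$site_shift
      # other site's peaks stay at zero expected intensity
    }
    ints <- ints + rnorm(n_pk, 0, cfg$sigma)
    sel <- keep & ints > 0.5
    data.frame(measurement_id = meas_id, tablet_id = tab_id,
               group_label = grp, mz = mz[sel], intensity = ints[sel],
               stringsAsFactors = FALSE)
  }

  rows <- list()
  for (k in seq_len(nrow(cfg$groups))) {
    grp <- cfg$groups$group_label[k]; ctry <- cfg$groups$country[k]
    for (t in seq_len(cfg$tablets_per_group)) {
      tab_id <- sprintf("%s_tab%d", grp, t)
      for (r in seq_len(cfg$replicates)) {
        rows[[length(rows) + 1]] <-
          peak_rows(sprintf("%s_r%d", tab_id, r), tab_id, grp, ctry, FALSE)
      }
    }
  }
  blanks <- list()
  for (b in seq_len(cfg$n_blanks)) {
    blanks[[b]] <- peak_rows(sprintf("BLANK_%d", b), sprintf("BLANK_%d", b),
                             "blank", NA, TRUE)
  }
  list(spectra = spectrum_set(do.call(rbind, rows)),
       blanks = spectrum_set(do.call(rbind, blanks), blank_groups = "blank"),
       truth = truth)
}

#' Default configuration for the biogeography generator
#'
#' Six narrow-range species per production site, drawn from truncated
#' Gaussian ranges around each site's coordinates (defaults: a northern
#' English site and a Bangkok site), four cosmopolitan species with uniform
#' global records, fifty records per species, a 30-degree synthetic
#' botanical-region grid, and a 15% rate of tied top BLAST hits.
#'
#' @param asvs_a,asvs_b ASV ids to tie to each site's species (defaults
#'   generate ids).
#' @param species_per_site,n_cosmopolitan,records_per_species,range_radius
#'   Range structure parameters (radius in degrees).
#' @param ambiguity_rate Fraction of ASVs given two tied top hits.
#' @param species_level_rate Fraction of ASVs with species-rank hits (the
#'   rest only resolve at genus rank, exercising the genus fallback).
#' @param site_a,site_b Site coordinates `c(lon, lat)`.
#' @param region_grid Region cell size in degrees.
#' @return A config list for [simulate_biogeography()].
#' @export
default_biogeo_config <- function(asvs_a = sprintf("ASVA_%02d", 1:6),
                                  asvs_b = sprintf("ASVB_%02d", 1:6),
                                  species_per_site = 6,
                                  n_cosmopolitan = 4,
                                  records_per_species = 50,
                                  range_radius = 10,
                                  ambiguity_rate = 0.15,
                                  species_level_rate = 1,
                                  site_a = c(-1.78, 53.64),
                                  site_b = c(100.53, 13.77),
                                  region_grid = 30) {
  list(asvs_a = asvs_a, asvs_b = asvs_b,
       species_per_site = species_per_site,
       n_cosmopolitan = n_cosmopolitan,
       records_per_species = records_per_species,
       range_radius = range_radius, ambiguity_rate = ambiguity_rate,
       species_level_rate = species_level_rate,
       site_a = site_a, site_b = site_b, region_grid = region_grid)
}

trunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate BLAST hits, occurrences and region presences with ground truth
#'
#' @param config From [default_biogeo_config()].
#' @param seed Integer seed.
#' @return A list: `hits` (a [blast_hits()] table), `occurrences` (an
#'   [occurrence_set()]), `regions` (a [region_presence()] matrix), `truth`
#'   (`species` data frame with range centers/radii and `asv_map` from ASV
#'   to true species).
#' @export
simulate_biogeography <- function(config = default_biogeo_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cfg <- config
  if (cfg$range_radius <= 0) stop("range_radius must be > 0")

  mk_species <- function(prefix, n)
    sprintf("%s_genus%02d %s_sp", prefix, seq_len(n), tolower(prefix))
  sp_a <- mk_species("SiteA", cfg$species_per_site)
  sp_b <- mk_species("SiteB", cfg$species_per_site)
  sp_c <- mk_species("Cosmo", cfg$n_cosmopolitan)
  species <- data.frame(
    species_name = c(sp_a, sp_b, sp_c),
    pool = c(rep("site_A", length(sp_a)), rep("site_B", length(sp_b)),
             rep("cosmopolitan", length(sp_c))),
    center_lon = c(rep(cfg$site_a[1], length(sp_a)),
                   rep(cfg$site_b[1], length(sp_b)),
                   rep(NA, length(sp_c))),
    center_lat = c(rep(cfg$site_a[2], length(sp_a)),
                   rep(cfg$site_b[2], length(sp_b)),
                   rep(NA, length(sp_c))),
    radius = c(rep(cfg$range_radius, length(sp_a) + length(sp_b)),
               rep(NA, length(sp_c))),
    stringsAsFactors = FALSE
  )

  occ <- list()
  for (i in seq_len(nrow(species))) {
    n <- cfg$records_per_species
    if (species$pool[i] == "cosmopolitan") {
      lon <- runif(n, -180, 180); lat <- runif(n, -60, 75)
    } else {
      sd <- cfg$range_radius / 2   # ~95% of records within the radius
      lon <- trunc_norm(n, species$center_lon[i], sd, -180, 180)
      lat <- trunc_norm(n, species$center_lat[i], sd, -90, 90)
    }
    occ[[i]] <- data.frame(species_name = species$species_name[i],
                           longitude = lon, latitude = lat,
                           stringsAsFactors = FALSE)
  }
  occ <- occurrence_set(do.call(rbind, occ))

  w <- cfg$region_grid
  lon_cells <- seq(-180, 180 - w, by = w)
  lat_cells <- seq(-90, 90 - w, by = w)
  codes <- as.vector(outer(seq_along(lon_cells), seq_along(lat_cells),
                           function(i, j) sprintf("REG_%02d_%02d", i, j)))
  pres <- matrix(0L, nrow(species), length(codes),
                 dimnames = list(species$species_name, codes))
  for (i in seq_len(nrow(species))) {
    rec <- occ[occ$species_name == species$species_name[i], ]
    ci <- pmin(floor((rec$longitude + 180) / w), length(lon_cells) - 1)
    cj <- pmin(floor((rec$latitude + 90) / w), length(lat_cells) - 1)
    pres[i, sprintf("REG_%02d_%02d", ci + 1, cj + 1)] <- 1L
  }

  empty_hits <- data.frame(query_asv = character(0),
                           subject_taxon_name = character(0),
                           taxon_rank = character(0),
                           percent_identity = numeric(0),
                           query_coverage = numeric(0),
                           stringsAsFactors = FALSE)
  mk_hits <- function(asvs, pool_species) {
    if (length(asvs) == 0) return(empty_hits)
    out <- list()
    for (k in seq_along(asvs)) {
      sp <- pool_species[((k - 1) %% length(pool_species)) + 1]
      genus <- strsplit(sp, " ")[[1]][1]
      pid <- round(runif(1, 97.5, 99.9), 1)
      has_species <- runif(1) < cfg$species_level_rate
      rows <- list()
      if (has_species) {
        rows[[1]] <- data.frame(query_asv = asvs[k], subject_taxon_name = sp,
                                taxon_rank = "species", percent_identity = pid,
                                query_coverage = 1, stringsAsFactors = FALSE)
        if (runif(1) < cfg$ambiguity_rate && length(pool_species) > 1) {
          alt <- setdiff(pool_species, sp)[1]
          rows[[2]] <- data.frame(query_asv = asvs[k],
                                  subject_taxon_name = alt,
                                  taxon_rank = "species",
                                  percent_identity = pid,
                                  query_coverage = 1, stringsAsFactors = FALSE)
        }
        # a weaker species hit below the LPI, never selected
        rows[[length(rows) + 1]] <- data.frame(
          query_asv = asvs[k],
          subject_taxon_name = pool_species[(k %% length(pool_species)) + 1],
          taxon_rank = "species", percent_identity = max(pid - 1.5, 97),
          query_coverage = 1, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        query_asv = asvs[k], subject_taxon_name = genus,
        taxon_rank = "genus", percent_identity = pid,
        query_coverage = 1, stringsAsFactors = FALSE)
      out[[k]] <- do.call(rbind, rows)
    }
    do.call(rbind, out)
  }
  hits <- blast_hits(rbind(mk_hits(cfg$asvs_a, sp_a),
                           mk_hits(cfg$asvs_b, sp_b)))
  asv_map <- data.frame(
    asv_id = c(cfg$asvs_a, cfg$asvs_b),
    species_name = c(sp_a[((seq_along(cfg$asvs_a) - 1) %% length(sp_a)) + 1],
                     sp_b[((seq_along(cfg$asvs_b) - 1) %% length(sp_b)) + 1]),
    site = c(rep("A", length(cfg$asvs_a)), rep("B", length(cfg$asvs_b))),
    stringsAsFactors = FALSE
  )
  list(hits = hits, occurrences = occ,
       regions = region_presence(pres),
       truth = list(species = species, asv_map = asv_map))
}
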