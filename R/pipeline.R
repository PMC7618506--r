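# Orchestration of the two headline analyses: reference-based origin
# prediction (filters -> differential abundance -> DAPC -> held-out
# prediction) and reference-free geomapping (differential abundance ->
# selection -> LPI taxon resolution -> unified maps). Each run produces a
# provenance manifest with per-stage record counts and content checksums so
# that reruns are verifiably identical.

md5_of <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  saveRDS(obj, con, version = 2)  # content-only stream, no file metadata
  close(con)
  unname(tools::md5sum(f))
}

new_manifest <- function(analysis, config_digest, seed) {
  list(analysis = analysis, config = config_digest, seed = seed,
       stages = list(), warnings = character(0))
}

manifest_stage <- function(manifest, name, n_in, n_out, checksum,
                           notes = NULL) {
  manifest$stages[[name]] <- list(n_in = n_in, n_out = n_out,
                                  checksum = checksum, notes = notes)
  manifest
}

collect_warnings <- function(expr) {
  warns <- character(0)
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

#' Configuration for the origin-prediction analysis
#'
#' @param seed Master seed driving simulation, rarefaction and permutations.
#' @param counts_config Generator config ([default_counts_config()]); ignored
#'   when `counts`/`sheet` are supplied.
#' @param counts,sheet Optional real inputs (a [count_table()] and
#'   [sample_sheet()]); when `NULL`, inputs are simulated.
#' @param control_threshold,min_total,q Filtering/testing parameters.
#' @param depth,n_iter Rarefaction depth and iterations.
#' @param var_target DAPC retained-variance target.
#' @return A config list for [run_origin_analysis()].
#' @export
origin_config <- function(seed = 1, counts_config = default_counts_config(),
                          counts = NULL, sheet = NULL,
                          control_threshold = 10, min_total = 1000,
                          q = 0.05, depth = 5000, n_iter = 25,
                          var_target = 0.90) {
  list(seed = seed, counts_config = counts_config, counts = counts,
       sheet = sheet, control_threshold = control_threshold,
       min_total = min_total, q = q, depth = depth, n_iter = n_iter,
       var_target = var_target)
}

#' Run the reference-based origin-prediction analysis
#'
#' Stages: decontamination (negative-control and excipient exclusion),
#' abundance filtering, poscounts/Wald differential-abundance testing with
#' the prediction-only group excluded, iterative rarefaction, DAPC on the
#' rarefied counts of the differentially abundant ASVs, leave-one-out
#' cross-validation, and class prediction for the held-out group. Fully
#' deterministic given the config seed.
#'
#' @param config From [origin_config()].
#' @return A list with `da` (the `da_result`), `da_asvs`, `model`, `loocv`
#'   (accuracy and per-sample predictions), `heldout` (posteriors for the
#'   prediction-only group, or `NULL`), and `manifest`.
#' @export
run_origin_analysis <- function(config = origin_config()) {
  manifest <- new_manifest("origin", md5_of(config[setdiff(names(config),
                                                           c("counts", "sheet"))]),
                           config$seed)
  if (is.null(config$counts)) {
    sim <- simulate_counts(config$counts_config, seed = config$seed)
    counts <- sim$counts; sheet <- sim$sheet
  } else {
    counts <- config$counts; sheet <- config$sheet
    if (is.null(sheet)) stop("counts supplied without a sample sheet")
  }
  manifest <- manifest_stage(manifest, "input", NA, nrow(counts),
                             md5_of(unclass(counts)))

  # control filtering applies to everything; the excipient exclusion only to
  # the differential-abundance testing (the rarefied classifier input keeps
  # full per-sample depth and is restricted to discriminant ASVs later)
  in_table <- sheet$sample_id %in% colnames(counts)
  ctl <- sheet$sample_id[in_table & sheet$sample_type == "neg_control"]
  exc <- sheet$sample_id[in_table & sheet$sample_type == "excipient"]
  step_ctl <- collect_warnings(remove_control_asvs(counts, ctl,
                                                   threshold = config$control_threshold))
  manifest$warnings <- c(manifest$warnings, step_ctl$warnings)
  ctl_filtered <- step_ctl$value$counts
  step_exc <- collect_warnings(remove_excipient_asvs(ctl_filtered, exc))
  manifest$warnings <- c(manifest$warnings, step_exc$warnings)
  filtered <- step_exc$value$counts
  manifest <- manifest_stage(manifest, "decontaminate", nrow(counts),
                             nrow(filtered), md5_of(unclass(filtered)),
                             notes = list(control = step_ctl$value$report$n_removed,
                                          excipient = step_exc$value$report$n_removed))

  abund <- abundance_filter(filtered, min_total = config$min_total)
  manifest <- manifest_stage(manifest, "abundance_filter", nrow(filtered),
                             nrow(abund), md5_of(unclass(abund)))

  meta <- sheet[match(colnames(abund), sheet$sample_id), ]
  tablets <- colnames(abund)[meta$sample_type == "tablet"]
  tab_counts <- subset_counts(abund, cols = tablets)
  da <- collect_warnings(wald_da_test(tab_counts, sheet, q = config$q))
  manifest$warnings <- c(manifest$warnings, da$warnings)
  da <- da$value
  da_asvs <- da$asv_id[da$overabundant_in != "none"]
  manifest <- manifest_stage(manifest, "differential_abundance",
                             nrow(tab_counts), length(da_asvs),
                             md5_of(da))
  if (length(da_asvs) < 2)
    stop("origin analysis aborted at stage differential_abundance: ",
         "fewer than 2 discriminant ASVs at q = ", config$q)

  # rarefy the control-filtered tablet table (full depth), then restrict to
  # the discriminant ASVs; excipient-derived ASVs are already excluded from
  # that set by construction
  meta_c <- sheet[match(colnames(ctl_filtered), sheet$sample_id), ]
  rar_in <- subset_counts(ctl_filtered,
                          cols = colnames(ctl_filtered)[meta_c$sample_type == "tablet"])
  rar <- collect_warnings(rarefy_iterative(rar_in, depth = config$depth,
                                           n_iter = config$n_iter,
                                           seed = config$seed + 1L))
  manifest$warnings <- c(manifest$warnings, rar$warnings)
  rar <- rar$value
  da_in_rar <- intersect(da_asvs, rownames(rar))
  x <- t(unclass(subset_counts(rar, rows = da_in_rar)))
  manifest <- manifest_stage(manifest, "rarefy", ncol(tab_counts), nrow(x),
                             md5_of(x))

  meta_r <- sheet[match(rownames(x), sheet$sample_id), ]
  pred_only <- attr(sheet, "prediction_only") %||% character()
  is_train <- !(meta_r$group_label %in% pred_only)
  model <- fit_dapc(x[is_train, , drop = FALSE], meta_r$country[is_train],
                    var_target = config$var_target)
  cv <- collect_warnings(loocv(x[is_train, , drop = FALSE],
                               meta_r$country[is_train],
                               function(f, l) fit_dapc(f, l,
                                 var_target = config$var_target)))
  manifest$warnings <- c(manifest$warnings, cv$warnings)
  cv <- cv$value
  heldout <- NULL
  if (any(!is_train))
    heldout <- predict_membership(model, x[!is_train, , drop = FALSE])
  manifest <- manifest_stage(manifest, "classify", sum(is_train),
                             length(model$classes),
                             md5_of(list(cv$predictions, heldout)),
                             notes = list(loocv_accuracy = cv$accuracy,
                                          n_pcs = model$n_pcs))
  list(da = da, da_asvs = da_asvs, model = model, loocv = cv,
       heldout = heldout, manifest = manifest)
}

#' Configuration for the reference-free geomapping analysis
#'
#' @param seed Master seed.
#' @param counts_config,biogeo_config Generator configs; the biogeography
#'   generator is re-targeted at the ASVs selected from the count data.
#' @param counts,sheet,hits,occurrences,regions Optional real inputs; any
#'   `NULL` entry is simulated.
#' @param control_threshold,min_total,q,min_samples Stage parameters.
#' @param bin_width Point-map bin width in degrees.
#' @param exclude_taxon Optional `list(taxon =, min_identity =)` exclusion
#'   (e.g. corn in starch-based tablets) applied before selection.
#' @return A config list for [run_geomap_analysis()].
#' @export
geomap_config <- function(seed = 1, counts_config = default_counts_config(),
                          biogeo_config = default_biogeo_config(),
                          counts = NULL, sheet = NULL, hits = NULL,
                          occurrences = NULL, regions = NULL,
                          control_threshold = 10, min_total = 1000,
                          q = 0.05, min_samples = 2, bin_width = 5,
                          exclude_taxon = NULL) {
  list(seed = seed, counts_config = counts_config,
       biogeo_config = biogeo_config, counts = counts, sheet = sheet,
       hits = hits, occurrences = occurrences, regions = regions,
       control_threshold = control_threshold, min_total = min_total,
       q = q, min_samples = min_samples, bin_width = bin_width,
       exclude_taxon = exclude_taxon)
}

#' Run the reference-free geomapping analysis
#'
#' Stages: decontamination, abundance filtering, differential-abundance
#' testing, selection of per-country overabundant ASVs (present in at least
#' `min_samples` samples of one country and absent from the other), optional
#' taxon exclusion, LPI taxon resolution with genus fallback, and unified
#' point and region maps per country. When no ASV survives selection for a
#' country, its maps are empty and the result carries a `no_signal` flag.
#'
#' @param config From [geomap_config()].
#' @return A list with `da`, `selected` (per-country ASV sets),
#'   `assignments` (per-country [genus_fallback()] results), `point_maps`,
#'   `region_maps`, `no_signal` (named logical), and `manifest`.
#' @export
run_geomap_analysis <- function(config = geomap_config()) {
  manifest <- new_manifest("geomap",
                           md5_of(config[setdiff(names(config),
                                                 c("counts", "sheet", "hits",
                                                   "occurrences", "regions"))]),
                           config$seed)
  if (is.null(config$counts)) {
    sim <- simulate_counts(config$counts_config, seed = config$seed)
    counts <- sim$counts; sheet <- sim$sheet
  } else {
    counts <- config$counts; sheet <- config$sheet
  }
  manifest <- manifest_stage(manifest, "input", NA, nrow(counts),
                             md5_of(unclass(counts)))

  dec <- collect_warnings(decontaminate(counts, sheet,
                                        control_threshold = config$control_threshold))
  manifest$warnings <- c(manifest$warnings, dec$warnings)
  filtered <- dec$value$counts
  abund <- abundance_filter(filtered, min_total = config$min_total)
  manifest <- manifest_stage(manifest, "filter", nrow(counts), nrow(abund),
                             md5_of(unclass(abund)))

  meta <- sheet[match(colnames(abund), sheet$sample_id), ]
  tab_counts <- subset_counts(abund,
                              cols = colnames(abund)[meta$sample_type == "tablet"])
  da <- collect_warnings(wald_da_test(tab_counts, sheet, q = config$q))
  manifest$warnings <- c(manifest$warnings, da$warnings)
  da <- da$value
  sel <- collect_warnings(select_overabundant_asvs(da, tab_counts, sheet,
                                                   min_samples = config$min_samples))
  manifest$warnings <- c(manifest$warnings, sel$warnings)
  sel <- sel$value
  manifest <- manifest_stage(manifest, "select", nrow(da),
                             length(sel$A) + length(sel$B),
                             md5_of(sel),
                             notes = list(A = length(sel$A), B = length(sel$B)))

  if (is.null(config$hits)) {
    bcfg <- config$biogeo_config
    bcfg$asvs_a <- sel$A; bcfg$asvs_b <- sel$B
    bio <- simulate_biogeography(bcfg, seed = config$seed + 1L)
    hits <- bio$hits; occurrences <- bio$occurrences; regions <- bio$regions
  } else {
    hits <- config$hits
    occurrences <- config$occurrences
    regions <- config$regions
  }

  excluded_asvs <- character(0)
  if (!is.null(config$exclude_taxon)) {
    ex <- config$exclude_taxon
    flag <- grepl(paste0("^", ex$taxon, "( |$)"), hits$subject_taxon_name) &
      hits$percent_identity >= (ex$min_identity %||% 90)
    excluded_asvs <- intersect(unique(hits$query_asv[flag]),
                               c(sel$A, sel$B))
    sel$A <- setdiff(sel$A, excluded_asvs)
    sel$B <- setdiff(sel$B, excluded_asvs)
    manifest <- manifest_stage(manifest, "exclude_taxon",
                               length(excluded_asvs) + length(sel$A) +
                                 length(sel$B),
                               length(sel$A) + length(sel$B),
                               md5_of(sel),
                               notes = list(excluded = excluded_asvs))
  }

  assignments <- point_maps <- region_maps <- list()
  no_signal <- c(A = length(sel$A) == 0, B = length(sel$B) == 0)
  for (ctry in c("A", "B")) {
    asvs <- sel[[ctry]]
    res <- genus_fallback(hits, asvs)
    assignments[[ctry]] <- res
    if (length(res$taxa) == 0) {
      no_signal[[ctry]] <- TRUE
      point_maps[[ctry]] <- unified_point_map(
        occurrence_set(data.frame(species_name = character(0),
                                  longitude = numeric(0),
                                  latitude = numeric(0))),
        character(0), bin_width = config$bin_width)
      region_maps[[ctry]] <- if (!is.null(regions))
        unified_region_map(regions, character(0)) else NULL
    } else {
      pm <- collect_warnings(unified_point_map(occurrences, res$taxa,
                                               bin_width = config$bin_width))
      manifest$warnings <- c(manifest$warnings, pm$warnings)
      point_maps[[ctry]] <- pm$value
      rm_ <- collect_warnings(unified_region_map(regions, res$taxa))
      manifest$warnings <- c(manifest$warnings, rm_$warnings)
      region_maps[[ctry]] <- rm_$value
    }
  }
  manifest <- manifest_stage(manifest, "maps",
                             length(sel$A) + length(sel$B),
                             sum(vapply(point_maps, nrow, integer(1))),
                             md5_of(list(point_maps, region_maps)),
                             notes = list(no_signal = no_signal,
                                          fallback = lapply(assignments,
                                                            `[[`, "fallback")))
  list(da = da, selected = sel, excluded_asvs = excluded_asvs,
       assignments = assignments, point_maps = point_maps,
       region_maps = region_maps, no_signal = no_signal,
       manifest = manifest)
}

#' Write a run manifest as canonical JSON
#'
#' @param manifest A manifest from one of the `run_*` functions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(path)
}
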