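# Reference-free geolocation: selection of origin-informative ASVs, taxon
# resolution under the largest-percent-identity (LPI) rule, and unified
# species-distribution maps (pooled point occurrences or superimposed
# botanical regions).

#' Select per-country overabundant ASVs for geographic mapping
#'
#' An ASV enters a country's set when (i) it is flagged overabundant in that
#' country by the differential-abundance test, (ii) it has nonzero counts in
#' at least `min_samples` of that country's tablet samples, and (iii) it is
#' entirely absent from the other country's tablet samples ("only occurred"
#' - the strictest reading, so mapped taxa exclusively mark one production
#' country).
#'
#' @param da A `da_result` from [wald_da_test()].
#' @param counts The [count_table()] the test was run on.
#' @param sheet A [sample_sheet()].
#' @param min_samples Minimum number of supporting samples (default 2).
#' @return Named list `A`, `B` of ASV-id character vectors.
#' @export
select_overabundant_asvs <- function(da, counts, sheet, min_samples = 2) {
  if (min_samples < 1) stop("min_samples must be >= 1")
  if (nrow(da) == 0) {
    warning("empty differential-abundance result; no ASVs selected")
    return(list(A = character(0), B = character(0)))
  }
  meta <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  tab <- meta$sample_type == "tablet"
  pick <- function(ctry, other) {
    flagged <- da$asv_id[da$overabundant_in == ctry]
    flagged <- intersect(flagged, rownames(counts))
    if (!length(flagged)) return(character(0))
    own <- colnames(counts)[tab & meta$country == ctry]
    opp <- colnames(counts)[tab & meta$country == other]
    m <- unclass(counts)
    n_own <- rowSums(m[flagged, own, drop = FALSE] > 0)
    any_opp <- rowSums(m[flagged, opp, drop = FALSE] > 0) > 0
    flagged[n_own >= min_samples & !any_opp]
  }
  list(A = pick("A", "B"), B = pick("B", "A"))
}

#' Resolve an ASV to taxa by the largest-percent-identity rule
#'
#' Among the ASV's species-rank hits, only those at the maximum percent
#' identity (LPI) are kept. One distinct species (even via several tied
#' hits) yields a `single_species` assignment; several distinct species
#' yield a `species_set` of equally possible species; no species-rank hits
#' yield `unassigned` (genus handling is a group-level decision, see
#' [genus_fallback()]).
#'
#' @param hits A [blast_hits()] table, already threshold-filtered.
#' @param asv ASV id to resolve.
#' @param rank Taxon rank to resolve at (`"species"`, default, or
#'   `"genus"`).
#' @return A `taxon_assignment` list: `asv_id`, `resolution`, `taxa`
#'   (sorted), `lpi`.
#' @export
resolve_lpi <- function(hits, asv, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  rows <- hits[hits$query_asv == asv & hits$taxon_rank == rank, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(structure(list(asv_id = asv, resolution = "unassigned",
                          taxa = character(0), lpi = NA_real_),
                     class = "taxon_assignment"))
  }
  lpi <- max(rows$percent_identity)
  taxa <- sort(unique(trimws(gsub("\\s+", " ",
    rows$subject_taxon_name[rows$percent_identity == lpi]))))
  res <- if (length(taxa) == 1) {
    if (rank == "species") "single_species" else "genus"
  } else {
    if (rank == "species") "species_set" else "genus"
  }
  structure(list(asv_id = asv, resolution = res, taxa = taxa, lpi = lpi),
            class = "taxon_assignment")
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("taxon_assignment %s [%s]: %s (LPI %.1f)\n", x$asv_id,
              x$resolution,
              if (length(x$taxa)) paste(x$taxa, collapse = " | ") else "-",
              if (is.na(x$lpi)) NA else x$lpi))
  invisible(x)
}

#' Genus fallback for a country's assignment set
#'
#' Species-level assignments take precedence: if at least one ASV in the
#' country's set resolves to the species level, the species-level
#' assignments are returned unchanged (unassigned ASVs dropped). Only when
#' no ASV resolves to species is every ASV re-resolved at the genus rank.
#' A country set with neither species- nor genus-level information comes
#' back empty with `fallback = "none"`.
#'
#' @param hits A [blast_hits()] table.
#' @param country_asvs Character vector of the country's selected ASV ids.
#' @return A list with `assignments` (list of `taxon_assignment`),
#'   `fallback` (`"species"`, `"genus"` or `"none"`), and `taxa` (unique
#'   taxon names across the set).
#' @export
genus_fallback <- function(hits, country_asvs) {
  sp <- lapply(country_asvs, function(a) resolve_lpi(hits, a, "species"))
  has_sp <- vapply(sp, function(x) x$resolution != "unassigned", logical(1))
  if (any(has_sp)) {
    keep <- sp[has_sp]
    return(list(assignments = keep, fallback = "species",
                taxa = sort(unique(unlist(lapply(keep, `[[`, "taxa"))))))
  }
  ge <- lapply(country_asvs, function(a) resolve_lpi(hits, a, "genus"))
  has_ge <- vapply(ge, function(x) x$resolution != "unassigned", logical(1))
  if (any(has_ge)) {
    keep <- ge[has_ge]
    return(list(assignments = keep, fallback = "genus",
                taxa = sort(unique(unlist(lapply(keep, `[[`, "taxa"))))))
  }
  list(assignments = list(), fallback = "none", taxa = character(0))
}

# --- binning ---------------------------------------------------------------

# Square lattice anchored at (-180, -90): cell (i, j) covers
# [-180 + i*w, -180 + (i+1)*w) x [-90 + j*w, ...).
square_bin_index <- function(lon, lat, w) {
  i <- pmin(floor((lon + 180) / w), ceiling(360 / w) - 1)
  j <- pmin(floor((lat + 90) / w), ceiling(180 / w) - 1)
  cbind(i = i, j = j)
}

# Pointy-top hexagonal lattice anchored at (-180, -90); `w` is the
# horizontal center spacing in degrees of longitude. Assignment by cube
# rounding of fractional axial coordinates.
hex_bin_index <- function(lon, lat, w) {
  size <- w / sqrt(3)                       # circumradius
  x <- lon + 180; y <- lat + 90
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
  rf <- (2 / 3 * y) / size
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = rx, r = rz)
}

hex_center <- function(q, r, w) {
  size <- w / sqrt(3)
  x <- size * (sqrt(3) * q + sqrt(3) / 2 * r)
  y <- size * (3 / 2 * r)
  cbind(lon = x - 180, lat = y - 90)
}

#' Unified point-occurrence map for a species group
#'
#' Pools the occurrence records of every species in the group onto one map
#' and counts observations per bin of a fixed global lattice anchored at
#' (-180, -90). The larger a bin's count, the more often the group's species
#' have been reported there. Records are not deduplicated: repeated
#' coordinates each count as an observation.
#'
#' @param occ An [occurrence_set()].
#' @param species_group Character vector of species names forming the group.
#' @param bin_width Bin width in degrees of longitude (default 5).
#' @param shape `"hex"` (default) or `"square"` lattice.
#' @return A `unified_point_map` data frame: one row per nonempty bin with
#'   bin indices, `center_lon`, `center_lat`, `count`; attributes
#'   `bin_width`, `shape`, `n_records`, `missing_species`.
#' @export
unified_point_map <- function(occ, species_group, bin_width = 5,
                              shape = c("hex", "square")) {
  shape <- match.arg(shape)
  if (bin_width <= 0) stop("bin_width must be > 0")
  missing_sp <- setdiff(species_group, unique(occ$species_name))
  if (length(missing_sp))
    warning("species with zero occurrence records: ",
            paste(missing_sp, collapse = ", "))
  sub <- occ[occ$species_name %in% species_group, , drop = FALSE]
  if (nrow(sub) == 0) {
    out <- data.frame(center_lon = numeric(0), center_lat = numeric(0),
                      count = integer(0))
  } else if (shape == "square") {
    idx <- square_bin_index(sub$longitude, sub$latitude, bin_width)
    key <- paste(idx[, 1], idx[, 2])
    tab <- table(key)
    ij <- do.call(rbind, strsplit(names(tab), " "))
    i <- as.numeric(ij[, 1]); j <- as.numeric(ij[, 2])
    out <- data.frame(i = i, j = j,
                      center_lon = -180 + (i + 0.5) * bin_width,
                      center_lat = -90 + (j + 0.5) * bin_width,
                      count = as.integer(tab))
  } else {
    idx <- hex_bin_index(sub$longitude, sub$latitude, bin_width)
    key <- paste(idx[, 1], idx[, 2])
    tab <- table(key)
    qr <- do.call(rbind, strsplit(names(tab), " "))
    q <- as.numeric(qr[, 1]); r <- as.numeric(qr[, 2])
    ctr <- hex_center(q, r, bin_width)
    out <- data.frame(q = q, r = r,
                      center_lon = ctr[, "lon"], center_lat = ctr[, "lat"],
                      count = as.integer(tab))
  }
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bin_width = bin_width, shape = shape,
            n_records = nrow(sub), missing_species = missing_sp,
            class = c("unified_point_map", "data.frame"))
}

#' Unified botanical-region map for a species group
#'
#' Superimposes the region-presence rows of the group's species: each
#' region's value is the number of group species recorded present there
#' (1 if a single species occurs, > 1 where several co-occur).
#'
#' @param regions A [region_presence()] matrix.
#' @param species_group Character vector of species names; species absent
#'   from the table are warned about and counted as all-zero rows.
#' @return Named integer vector of per-region co-occurring species counts.
#' @export
unified_region_map <- function(regions, species_group) {
  missing_sp <- setdiff(species_group, rownames(regions))
  if (length(missing_sp))
    warning("species absent from the region table (counted as absent ",
            "everywhere): ", paste(missing_sp, collapse = ", "))
  present <- intersect(species_group, rownames(regions))
  if (length(present) == 0)
    return(setNames(rep(0L, ncol(regions)), colnames(regions)))
  counts <- colSums(unclass(regions)[present, , drop = FALSE])
  storage.mode(counts) <- "integer"
  counts
}
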