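#' @importFrom stats aov anova aggregate cmdscale cov dist kruskal.test
#'   median p.adjust pnorm prcomp quantile rbinom rlnorm rmultinom rnorm
#'   runif sd setNames var
#' @importFrom utils read.delim write.table read.csv head
NULL

# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Construct an ASV-by-sample count table
#'
#' The central container of the pipeline: a non-negative integer matrix of
#' amplicon sequence variant (ASV) read counts with ASVs as rows and samples
#' as columns, tagged with the marker gene it was profiled with.
#'
#' @param counts Numeric matrix of non-negative integers; rows are ASVs,
#'   columns are samples. Dimnames are required and must be unique.
#' @param marker One of `"16S"`, `"18S"`, `"trnL"`.
#' @return An object of class `count_table`: the integer matrix with a
#'   `marker` attribute.
#' @export
count_table <- function(counts, marker = c("16S", "18S", "trnL")) {
  marker <- match.arg(marker)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("count table requires ASV row names and sample column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate asv_ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample_ids in count table")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(counts, marker = marker, class = c("count_table", "matrix", "array"))
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table [%s]: %d ASVs x %d samples, %s total reads\n",
              attr(x, "marker"), nrow(x), ncol(x),
              format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' Marker gene of a count table
#' @param x A `count_table`.
#' @return Character scalar, one of `"16S"`, `"18S"`, `"trnL"`.
#' @export
marker <- function(x) attr(x, "marker")

# Rebuild a count_table after subsetting, preserving the marker tag.
subset_counts <- function(x, rows = NULL, cols = NULL) {
  m <- attr(x, "marker")
  y <- unclass(x)
  if (!is.null(rows)) y <- y[rows, , drop = FALSE]
  if (!is.null(cols)) y <- y[, cols, drop = FALSE]
  count_table(y, marker = m)
}

SAMPLE_TYPES   <- c("tablet", "excipient", "dust", "water", "neg_control")
COUNTRIES      <- c("A", "B", "unknown")
MANUFACTURING  <- c("direct_compression", "wet_granulation")
WATER_SOURCES  <- c("none", "local", "foreign")

#' Construct and validate a sample metadata sheet
#'
#' @param df Data frame with columns `sample_id`, `sample_type`, `country`,
#'   `manufacturing`, `water_source`, `group_label`.
#' @param prediction_only Character vector of group labels that are held out
#'   of supervised analyses; tablets in these groups may carry
#'   `country = "unknown"`.
#' @return A validated `sample_sheet` data frame.
#' @export
sample_sheet <- function(df, prediction_only = character()) {
  req <- c("sample_id", "sample_type", "country", "manufacturing",
           "water_source", "group_label")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("metadata sheet is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) stop("metadata sheet has no rows")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop(sprintf("invalid %s value(s): %s (allowed: %s)", col,
                   paste(bad, collapse = ", "), paste(allowed, collapse = ", ")))
  }
  check_enum("sample_type", SAMPLE_TYPES)
  check_enum("country", COUNTRIES)
  check_enum("manufacturing", MANUFACTURING)
  check_enum("water_source", WATER_SOURCES)
  tab <- df$sample_type == "tablet" & !(df$group_label %in% prediction_only)
  if (any(tab & df$country == "unknown"))
    stop("tablet samples must have a known country unless prediction-only: ",
         paste(df$sample_id[tab & df$country == "unknown"], collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  attr(df, "prediction_only") <- prediction_only
  class(df) <- c("sample_sheet", "data.frame")
  df
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read an ASV count table from TSV
#'
#' Expects a tab-separated file whose first column is `asv_id` and whose
#' remaining columns are sample ids, one ASV per row.
#'
#' @param path File path.
#' @param marker Marker gene label to attach (`"16S"`, `"18S"` or `"trnL"`).
#' @return A [count_table()].
#' @export
read_count_table <- function(path, marker = c("16S", "18S", "trnL")) {
  marker <- match.arg(marker)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("count table needs an asv_id column plus >= 1 sample")
  smp <- names(df)[-1]
  if (anyDuplicated(smp)) stop("duplicate sample_ids in count table header")
  asv <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  colnames(mat) <- smp   # as.matrix mangles duplicate data-frame names
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer cell at ASV '%s', sample '%s': '%s'",
                 asv[bad[1, 1]], colnames(mat)[bad[1, 2]],
                 mat[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- list(asv, colnames(mat))
  count_table(num, marker = marker)
}

#' Write a count table to TSV
#' @param x A `count_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(asv_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample metadata sheet from TSV
#'
#' @param path File path to a tab-separated sheet with columns `sample_id`,
#'   `sample_type`, `country`, `manufacturing`, `water_source`, `group_label`.
#' @param prediction_only Group labels held out of supervised analyses.
#' @return A [sample_sheet()].
#' @export
read_metadata <- function(path, prediction_only = character()) {
  if (file.size(path) == 0) stop("metadata file is empty: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  sample_sheet(df, prediction_only = prediction_only)
}

#' Write a sample sheet to TSV
#' @param x A `sample_sheet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tabular BLAST hit file
#'
#' Parses an outfmt-6-like tab-separated file with columns
#' `qseqid  staxon  srank  pident  qcov` and drops rows failing the coverage
#' or identity thresholds. Both thresholds are inclusive (`>=`), matching the
#' semantics of the corresponding QIIME parameters.
#'
#' @param path File path.
#' @param min_coverage Minimum query coverage in \[0, 1\] (default 0.9).
#' @param min_identity Minimum percent identity in \[0, 100\] (default 97).
#' @return A `blast_hits` data frame with columns `query_asv`,
#'   `subject_taxon_name`, `taxon_rank`, `percent_identity`, `query_coverage`.
#' @export
read_blast_hits <- function(path, min_coverage = 0.9, min_identity = 97) {
  cols <- c("qseqid", "staxon", "srank", "pident", "qcov")
  if (file.size(path) == 0) {
    df <- data.frame(qseqid = character(), staxon = character(),
                     srank = character(), pident = numeric(),
                     qcov = numeric())
  } else {
    df <- read.delim(path, header = TRUE, check.names = FALSE,
                     fileEncoding = "UTF-8")
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("BLAST hit file missing column(s): ",
           paste(missing_cols, collapse = ", "))
  }
  blast_hits(data.frame(
    query_asv          = as.character(df$qseqid),
    subject_taxon_name = as.character(df$staxon),
    taxon_rank         = as.character(df$srank),
    percent_identity   = as.numeric(df$pident),
    query_coverage     = as.numeric(df$qcov),
    stringsAsFactors = FALSE
  ), min_coverage = min_coverage, min_identity = min_identity)
}

#' Construct a validated BLAST hit table
#' @param df Data frame with columns `query_asv`, `subject_taxon_name`,
#'   `taxon_rank`, `percent_identity`, `query_coverage`.
#' @param min_coverage,min_identity Inclusive retention thresholds applied on
#'   construction; set to 0 to keep everything.
#' @return A `blast_hits` data frame.
#' @export
blast_hits <- function(df, min_coverage = 0, min_identity = 0) {
  req <- c("query_asv", "subject_taxon_name", "taxon_rank",
           "percent_identity", "query_coverage")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("blast_hits missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    if (any(df$percent_identity < 0 | df$percent_identity > 100))
      stop("percent_identity outside [0, 100]")
    if (any(df$query_coverage < 0 | df$query_coverage > 1))
      stop("query_coverage outside [0, 1]")
    bad_rank <- setdiff(unique(df$taxon_rank), c("species", "genus", "higher"))
    if (length(bad_rank))
      stop("unknown taxon_rank value(s): ", paste(bad_rank, collapse = ", "))
    keep <- df$query_coverage >= min_coverage &
      df$percent_identity >= min_identity
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Write a BLAST hit table in the outfmt-6-like layout
#' @param x A `blast_hits` table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(x, path) {
  df <- data.frame(qseqid = x$query_asv, staxon = x$subject_taxon_name,
                   srank = x$taxon_rank, pident = x$percent_identity,
                   qcov = x$query_coverage)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read species point-occurrence records
#'
#' Expects CSV with header `species,lon,lat`; longitudes in \[-180, 180\]
#' degrees and latitudes in \[-90, 90\].
#'
#' @param path File path.
#' @return An `occurrence_set` data frame with columns `species_name`,
#'   `longitude`, `latitude`.
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  occurrence_set(data.frame(species_name = as.character(df$species),
                            longitude = as.numeric(df$lon),
                            latitude = as.numeric(df$lat),
                            stringsAsFactors = FALSE))
}

#' Construct a validated occurrence set
#' @param df Data frame with columns `species_name`, `longitude`, `latitude`.
#' @return An `occurrence_set` data frame.
#' @export
occurrence_set <- function(df) {
  req <- c("species_name", "longitude", "latitude")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("occurrence_set missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    if (any(!nzchar(df$species_name) | is.na(df$species_name)))
      stop("species_name must be non-empty")
    if (any(is.na(df$longitude)) || any(df$longitude < -180 | df$longitude > 180))
      stop("longitude outside [-180, 180]")
    if (any(is.na(df$latitude)) || any(df$latitude < -90 | df$latitude > 90))
      stop("latitude outside [-90, 90]")
  }
  class(df) <- c("occurrence_set", "data.frame")
  df
}

#' Write occurrence records as CSV
#' @param x An `occurrence_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(x, path) {
  df <- data.frame(species = x$species_name, lon = x$longitude,
                   lat = x$latitude)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a botanical-region presence/absence table
#'
#' Wide CSV matrix: header `species,<region code>,...`, entries 0/1. Region
#' codes follow the WGSRPD level-3 convention but are treated as opaque.
#'
#' @param path File path.
#' @return A `region_presence` 0/1 matrix, species as rows, regions as columns.
#' @export
read_regions <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  region_presence(m)
}

#' Construct a validated region-presence matrix
#' @param m Numeric 0/1 matrix, species as rows, region codes as columns.
#' @return A `region_presence` matrix.
#' @export
region_presence <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (any(is.na(m)) || !all(m %in% c(0, 1)))
    stop("region presence entries must be 0 or 1")
  storage.mode(m) <- "integer"
  structure(m, class = c("region_presence", "matrix", "array"))
}

#' Write a region-presence matrix as wide CSV
#' @param x A `region_presence` matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a spectrum set as a one-peak-per-row CSV
#' @param x A `spectrum_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path) {
  df <- data.frame(measurement_id = x$measurement_id,
                   tablet_id = x$tablet_id, group = x$group_label,
                   mz = x$mz, intensity = x$intensity)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read centroided mass-spectral peak lists
#'
#' One peak per row: `measurement_id,tablet_id,group,mz,intensity`. Peaks
#' outside the 50-800 m/z acquisition window are retained but flagged (column
#' `in_range`) with a warning, so no raw signal is silently discarded.
#'
#' @param path File path.
#' @param blank_groups Group labels identifying background (blank) strips.
#' @return A `spectrum_set` data frame with columns `measurement_id`,
#'   `tablet_id`, `group_label`, `mz`, `intensity`, `blank`, `in_range`.
#' @export
read_peaks <- function(path, blank_groups = "blank") {
  df <- read.csv(path, fileEncoding = "UTF-8")
  spectrum_set(data.frame(
    measurement_id = as.character(df$measurement_id),
    tablet_id = as.character(df$tablet_id),
    group_label = as.character(df$group),
    mz = as.numeric(df$mz),
    intensity = as.numeric(df$intensity),
    stringsAsFactors = FALSE
  ), blank_groups = blank_groups)
}

#' Construct a validated spectrum set
#'
#' @param df Data frame with columns `measurement_id`, `tablet_id`,
#'   `group_label`, `mz`, `intensity` (and optionally `blank`).
#' @param blank_groups Group labels to flag as background strips when no
#'   `blank` column is supplied.
#' @param mz_range Acquisition window in Daltons; peaks outside are flagged,
#'   not dropped.
#' @return A `spectrum_set` data frame sorted by measurement and m/z.
#' @export
spectrum_set <- function(df, blank_groups = "blank", mz_range = c(50, 800)) {
  req <- c("measurement_id", "tablet_id", "group_label", "mz", "intensity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("spectrum_set missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df)) {
    if (any(is.na(df$intensity)) || any(df$intensity < 0))
      stop("peak intensity must be >= 0")
    if (any(is.na(df$mz))) stop("peak mz must be numeric")
    if (is.null(df$blank)) df$blank <- df$group_label %in% blank_groups
    df$in_range <- df$mz >= mz_range[1] & df$mz <= mz_range[2]
    if (any(!df$in_range))
      warning(sum(!df$in_range), " peak(s) outside the ", mz_range[1], "-",
              mz_range[2], " m/z acquisition window (kept, flagged)")
    df <- df[order(df$measurement_id, df$mz), , drop = FALSE]
    dup <- duplicated(df[, c("measurement_id", "mz")])
    if (any(dup))
      stop("mz values must be strictly increasing within a measurement")
    rownames(df) <- NULL
  } else {
    df$blank <- logical(0)
    df$in_range <- logical(0)
  }
  class(df) <- c("spectrum_set", "data.frame")
  df
}
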