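# Contamination and excipient exclusion rules applied to ASV count tables
# before any community or differential-abundance analysis.

new_filter_report <- function(rule, removed, retained, params = list()) {
  stopifnot(length(intersect(removed, retained)) == 0)
  structure(list(rule = rule,
                 n_removed = length(removed),
                 n_retained = length(retained),
                 removed_ids = removed,
                 params = params),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report [%s]: %d ASVs removed, %d retained\n",
              x$rule, x$n_removed, x$n_retained))
  invisible(x)
}

#' Remove ASVs detected in negative controls
#'
#' Any ASV whose read count strictly exceeds `threshold` in any single
#' negative-control sample (DNA extraction or PCR control) is excluded from
#' all samples. The rule is per control sample, not summed across controls:
#' this is the conservative forensic reading. Control columns are dropped
#' from the returned table.
#'
#' @param counts A [count_table()].
#' @param control_samples Non-empty character vector of control sample ids.
#' @param threshold Read-count threshold; removal requires count `> threshold`
#'   (strict), default 10.
#' @return A list with elements `counts` (filtered table without control
#'   columns) and `report` (a `filter_report`).
#' @export
remove_control_asvs <- function(counts, control_samples, threshold = 10) {
  if (length(control_samples) == 0)
    stop("control sample set must be non-empty")
  if (threshold < 0) stop("threshold must be >= 0")
  missing_ctl <- setdiff(control_samples, colnames(counts))
  if (length(missing_ctl))
    stop("control sample(s) not in table: ", paste(missing_ctl, collapse = ", "))
  ctl <- unclass(counts)[, control_samples, drop = FALSE]
  contaminated <- rownames(counts)[apply(ctl > threshold, 1, any)]
  keep_asv <- setdiff(rownames(counts), contaminated)
  keep_smp <- setdiff(colnames(counts), control_samples)
  list(
    counts = subset_counts(counts, rows = keep_asv, cols = keep_smp),
    report = new_filter_report("control", contaminated, keep_asv,
                               params = list(threshold = threshold,
                                             controls = control_samples))
  )
}

#' Remove ASVs present in pure excipient samples
#'
#' Presence is any nonzero count in any excipient sample; there is no read
#' threshold. This strips the biosignature contributed by the raw tablet
#' ingredients so that downstream tests see mainly production-environment
#' signal.
#'
#' @param counts A [count_table()].
#' @param excipient_samples Non-empty character vector of excipient sample ids.
#' @param drop_excipient_columns Drop the excipient columns from the output
#'   (default `TRUE`).
#' @return A list with elements `counts` and `report`.
#' @export
remove_excipient_asvs <- function(counts, excipient_samples,
                                  drop_excipient_columns = TRUE) {
  if (length(excipient_samples) == 0)
    stop("excipient sample set must be non-empty")
  missing_exc <- setdiff(excipient_samples, colnames(counts))
  if (length(missing_exc))
    stop("excipient sample(s) not in table: ",
         paste(missing_exc, collapse = ", "))
  exc <- unclass(counts)[, excipient_samples, drop = FALSE]
  present <- rownames(counts)[apply(exc > 0, 1, any)]
  keep_asv <- setdiff(rownames(counts), present)
  keep_smp <- if (drop_excipient_columns)
    setdiff(colnames(counts), excipient_samples) else colnames(counts)
  list(
    counts = subset_counts(counts, rows = keep_asv, cols = keep_smp),
    report = new_filter_report("excipient", present, keep_asv,
                               params = list(excipients = excipient_samples))
  )
}

#' Remove ASVs assigned to a given taxon
#'
#' Excludes ASVs whose BLAST hits match `taxon_name` at or above
#' `min_identity` percent identity. Used to strip excipient-derived taxa
#' (e.g. corn, from starch) from plant-marker tables so that geographic
#' inference is not driven by ingredients.
#'
#' @param counts A [count_table()].
#' @param hits A [blast_hits()] table.
#' @param taxon_name Non-empty taxon name matched against
#'   `subject_taxon_name` (prefix match at the genus token, so `"Zea"`
#'   matches `"Zea mays"`).
#' @param min_identity Minimum percent identity for a hit to trigger removal
#'   (default 90).
#' @return A list with elements `counts` and `report`.
#' @export
remove_taxon_asvs <- function(counts, hits, taxon_name, min_identity = 90) {
  if (!nzchar(taxon_name)) stop("taxon_name must be non-empty")
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must be in [0, 100]")
  hit_rows <- nrow(hits) > 0 &
    grepl(paste0("^", taxon_name, "( |$)"), hits$subject_taxon_name) &
    hits$percent_identity >= min_identity
  flagged <- unique(hits$query_asv[hit_rows])
  removed <- intersect(rownames(counts), flagged)
  keep_asv <- setdiff(rownames(counts), removed)
  list(
    counts = subset_counts(counts, rows = keep_asv),
    report = new_filter_report("taxon", removed, keep_asv,
                               params = list(taxon = taxon_name,
                                             min_identity = min_identity))
  )
}

#' Apply the standard decontamination chain
#'
#' Runs the three exclusion rules in the fixed order controls, excipients,
#' then (optionally) taxon, recording a `filter_report` per rule.
#'
#' @param counts A [count_table()].
#' @param sheet A [sample_sheet()] used to locate control and excipient
#'   samples by `sample_type`.
#' @param control_threshold Threshold for [remove_control_asvs()].
#' @param exclude_taxon Optional `list(taxon = , min_identity = )` forwarded
#'   to [remove_taxon_asvs()]; requires `hits`.
#' @param hits Optional [blast_hits()] table.
#' @return A list with `counts` (filtered table) and `reports` (list of
#'   `filter_report`s in application order).
#' @export
decontaminate <- function(counts, sheet, control_threshold = 10,
                          exclude_taxon = NULL, hits = NULL) {
  in_table <- sheet$sample_id %in% colnames(counts)
  ctl <- sheet$sample_id[in_table & sheet$sample_type == "neg_control"]
  exc <- sheet$sample_id[in_table & sheet$sample_type == "excipient"]
  reports <- list()
  step1 <- remove_control_asvs(counts, ctl, threshold = control_threshold)
  reports$control <- step1$report
  step2 <- remove_excipient_asvs(step1$counts, exc)
  reports$excipient <- step2$report
  out <- step2$counts
  if (!is.null(exclude_taxon)) {
    if (is.null(hits)) stop("taxon exclusion requires a BLAST hit table")
    step3 <- remove_taxon_asvs(out, hits, exclude_taxon$taxon,
                               min_identity = exclude_taxon$min_identity %||% 90)
    reports$taxon <- step3$report
    out <- step3$counts
  }
  list(counts = out, reports = reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
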