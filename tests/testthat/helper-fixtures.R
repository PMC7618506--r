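# Shared fixture builders: every fixture is generated in code at test time.

make_counts <- function(mat, marker = "16S") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("asv%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  count_table(mat, marker = marker)
}

random_counts <- function(n_asv = 50, n_smp = 10, lambda = 20, seed = 1,
                          marker = "16S") {
  set.seed(seed)
  make_counts(matrix(rpois(n_asv * n_smp, lambda), n_asv, n_smp),
              marker = marker)
}

make_sheet <- function(sample_ids, types, countries = "A",
                       manufacturing = "direct_compression",
                       water = "none", groups = NULL,
                       prediction_only = character()) {
  n <- length(sample_ids)
  sample_sheet(data.frame(
    sample_id = sample_ids,
    sample_type = rep_len(types, n),
    country = rep_len(countries, n),
    manufacturing = rep_len(manufacturing, n),
    water_source = rep_len(water, n),
    group_label = rep_len(groups %||% types, n),
    stringsAsFactors = FALSE
  ), prediction_only = prediction_only)
}

make_hits <- function(asv, taxon, rank = "species", pid = 99, cov = 1) {
  n <- max(length(asv), length(taxon), length(pid))
  blast_hits(data.frame(
    query_asv = rep_len(asv, n),
    subject_taxon_name = rep_len(taxon, n),
    taxon_rank = rep_len(rank, n),
    percent_identity = rep_len(pid, n),
    query_coverage = rep_len(cov, n),
    stringsAsFactors = FALSE
  ))
}

make_spectra <- function(df) spectrum_set(df)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-country tablet design used by diff_abund tests: n_per tablets per
# country x method cell (country B gets one fewer wet-granulation tablet to
# mimic the unbalanced design).
two_country_sheet <- function(ids_a_dc, ids_a_wg, ids_b_dc, ids_b_wg,
                              prediction_only = character()) {
  mk <- function(ids, ctry, meth) data.frame(
    sample_id = ids, sample_type = "tablet", country = ctry,
    manufacturing = meth, water_source = "none",
    group_label = paste0(ctry, "-", substr(meth, 1, 2)),
    stringsAsFactors = FALSE)
  sample_sheet(rbind(
    mk(ids_a_dc, "A", "direct_compression"),
    mk(ids_a_wg, "A", "wet_granulation"),
    mk(ids_b_dc, "B", "direct_compression"),
    mk(ids_b_wg, "B", "wet_granulation")
  ), prediction_only = prediction_only)
}
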