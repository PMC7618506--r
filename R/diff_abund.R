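# Country-discriminant ASV detection: poscounts size factors, log2-fold
# ratios, Wald tests and Benjamini-Hochberg FDR control, with the
# manufacturing method controlled for within countries.

#' Drop low-abundance ASVs
#'
#' Retains ASVs whose read total across all samples is at least `min_total`.
#' Focusing differential-abundance testing on abundant phylotypes avoids
#' spending FDR budget on ASVs with no power.
#'
#' @param counts A [count_table()].
#' @param min_total Minimum summed count, inclusive (default 1000).
#' @return A filtered [count_table()].
#' @export
abundance_filter <- function(counts, min_total = 1000) {
  if (min_total < 0) stop("min_total must be >= 0")
  keep <- rowSums(unclass(counts)) >= min_total
  subset_counts(counts, rows = rownames(counts)[keep])
}

#' Poscounts size factors for zero-inflated count tables
#'
#' The median-of-ratios estimator breaks down when most ASVs contain zeros,
#' because the per-ASV geometric mean vanishes. The poscounts variant
#' computes each ASV's reference as the n-th root of the product of its
#' positive counts only (n = number of samples), and takes, per sample, the
#' median ratio of count to reference over ASVs where both are positive.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts A [count_table()] or non-negative matrix.
#' @return Named numeric vector of size factors, one per sample, geometric
#'   mean 1.
#' @export
poscounts_size_factors <- function(counts) {
  m <- unclass(counts)
  if (any(colSums(m) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  n <- ncol(m)
  log_ref <- apply(m, 1, function(row) {
    pos <- row > 0
    if (!any(pos)) -Inf else sum(log(row[pos])) / n
  })
  s <- vapply(seq_len(n), function(j) {
    ratio <- log(m[, j]) - log_ref
    use <- is.finite(log_ref) & m[, j] > 0
    if (!any(use)) stop("sample ", colnames(m)[j],
                        " shares no positive ASV with the reference")
    exp(median(ratio[use]))
  }, numeric(1))
  s <- s / exp(mean(log(s)))
  names(s) <- colnames(m)
  s
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper over `p.adjust(method = "BH")`; rejects p-values
#' outside \[0, 1\] instead of propagating NA.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Normalized per-cell means and their variances under an NB model.
# y: normalized counts for one ASV; s: size factors; cell: factor.
cell_stats <- function(y, cell) {
  mu <- tapply(y, cell, mean)
  n <- tapply(y, cell, length)
  list(mu = mu, n = n)
}

#' Wald test for country-differential ASV abundance
#'
#' For each ASV, counts are normalized by poscounts size factors and
#' modelled with negative-binomial variance
#' \eqn{\mathrm{Var}(K_{ij}) = \mu_{ij} + \alpha_i \mu_{ij}^2}, where the
#' per-ASV dispersion \eqn{\alpha_i} is estimated by method of moments from
#' the within-cell residuals (cells = country x manufacturing method,
#' mirroring the design `~ country + country:method`), moderated by flooring
#' each estimate at the table-wide median MoM dispersion (raw per-ASV
#' moment estimates are too noisy at typical sample sizes), with a hard
#' floor of 1e-8.
#' The reported contrast is the country log2-fold ratio of method-balanced
#' normalized means, its standard error by the delta method, a two-sided
#' normal Wald p, and Benjamini-Hochberg adjusted p. ASVs are flagged
#' overabundant in a country at `padj < q`.
#'
#' When either country mean is zero, a pseudo-mean of 0.5 normalized counts
#' is added to both numerator and denominator of the ratio so the fold
#' change stays finite.
#'
#' @param counts A [count_table()], already decontaminated and
#'   abundance-filtered; tablet samples only.
#' @param sheet A [sample_sheet()] covering the samples; groups listed in its
#'   `prediction_only` attribute (e.g. the foreign-water control group) are
#'   excluded from testing.
#' @param q FDR level in (0, 1) (default 0.05).
#' @param size_factors Optional precomputed size factors.
#' @return A `da_result` data frame with one row per ASV: `asv_id`,
#'   `mean_A`, `mean_B` (normalized means), `lfc`, `se`, `z`, `p`, `padj`,
#'   `overabundant_in` (`"A"`, `"B"` or `"none"`).
#' @export
wald_da_test <- function(counts, sheet, q = 0.05, size_factors = NULL) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  pred_only <- attr(sheet, "prediction_only") %||% character()
  meta <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  if (any(is.na(meta$sample_id)))
    stop("sample(s) missing from metadata: ",
         paste(colnames(counts)[is.na(meta$sample_id)], collapse = ", "))
  use <- meta$sample_type == "tablet" & !(meta$group_label %in% pred_only) &
    meta$country %in% c("A", "B")
  counts <- subset_counts(counts, cols = colnames(counts)[use])
  meta <- meta[use, , drop = FALSE]
  for (ctry in c("A", "B"))
    if (sum(meta$country == ctry) < 2)
      stop("country ", ctry, " has < 2 samples")
  m <- unclass(counts)
  s <- size_factors %||% poscounts_size_factors(counts)
  s <- s[colnames(m)]
  y <- sweep(m, 2, s, "/")                     # normalized counts
  cell <- interaction(meta$country, meta$manufacturing, drop = TRUE)
  country <- meta$country

  # Per-ASV method-of-moments dispersion from within-cell residuals. Raw
  # per-ASV MoM estimates are noisy at these sample sizes and collapse to
  # the floor whenever sampled variance falls below the mean, which makes
  # the Wald test anticonservative; each estimate is therefore floored at
  # the table-wide median MoM dispersion (a moderated MoM, same spirit as
  # the shrinkage the field's NB tools apply) before the hard 1e-8 floor.
  alpha_raw <- apply(y, 1, function(yi) {
    mu_cell <- tapply(yi, cell, mean)
    ss <- 0; df <- 0
    for (cl in names(mu_cell)) {
      idx <- cell == cl
      if (sum(idx) >= 2) {
        ss <- ss + sum((yi[idx] - mu_cell[[cl]])^2)
        df <- df + sum(idx) - 1
      }
    }
    pooled_var <- if (df > 0) ss / df else 0
    pooled_mu <- mean(yi)
    (pooled_var - pooled_mu) / max(pooled_mu^2, 1e-12)
  })
  alpha_prior <- median(alpha_raw[is.finite(alpha_raw) & alpha_raw > 0])
  if (!is.finite(alpha_prior)) alpha_prior <- 0
  alpha_all <- pmax(1e-8, pmax(alpha_raw, alpha_prior))

  res <- t(sapply(seq_len(nrow(y)), function(ii) {
    yi <- y[ii, ]
    alpha <- alpha_all[ii]
    mu_cell <- tapply(yi, cell, mean)
    # country means balanced over the methods present in each country
    mu_country <- se2_country <- setNames(numeric(2), c("A", "B"))
    for (ctry in c("A", "B")) {
      cells_c <- levels(droplevels(cell[country == ctry]))
      mus <- mu_cell[cells_c]
      vars_cellmean <- vapply(cells_c, function(cl) {
        idx <- which(cell == cl)
        sum(mu_cell[[cl]] / s[idx] + alpha * mu_cell[[cl]]^2) / length(idx)^2
      }, numeric(1))
      mu_country[ctry] <- mean(mus)
      se2_country[ctry] <- sum(vars_cellmean) / length(cells_c)^2
    }
    muA <- mu_country[["A"]]; muB <- mu_country[["B"]]
    offset <- if (muA == 0 || muB == 0) 0.5 else 0
    lfc <- log2((muA + offset) / (muB + offset))
    dA <- 1 / ((muA + offset) * log(2))
    dB <- 1 / ((muB + offset) * log(2))
    se <- sqrt(dA^2 * se2_country[["A"]] + dB^2 * se2_country[["B"]])
    se <- max(se, 1e-8)
    z <- lfc / se
    c(muA, muB, lfc, se, z, 2 * pnorm(-abs(z)))
  }))
  rownames(res) <- rownames(y)
  out <- data.frame(asv_id = rownames(m),
                    mean_A = res[, 1], mean_B = res[, 2],
                    lfc = res[, 3], se = res[, 4], z = res[, 5],
                    p = res[, 6], row.names = NULL, stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out$overabundant_in <- ifelse(out$padj < q,
                                ifelse(out$lfc > 0, "A", "B"), "none")
  out$overabundant_in[out$padj < q & out$lfc == 0] <- "none"
  attr(out, "q") <- q
  attr(out, "size_factors") <- s
  class(out) <- c("da_result", "data.frame")
  out
}
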