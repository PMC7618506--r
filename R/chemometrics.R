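# DART-MS spectrum preprocessing and discriminant feature selection:
# background subtraction, relative-intensity normalization, close-mass
# aggregation, cross-measurement feature alignment, ANOVA pre-selection and
# Fisher-ratio ranking.

split_measurements <- function(spectra) {
  split(seq_len(nrow(spectra)), spectra$measurement_id)
}

#' Subtract background signal estimated from blank strips
#'
#' Blank peaks are pooled and clustered within `mz_tol`; the mean intensity
#' per blank feature (summed intensity divided by the number of blank
#' measurements) defines the background level. Each sample peak matched to a
#' blank feature within `mz_tol` has that level subtracted; peaks that drop
#' to zero or below are removed.
#'
#' @param spectra A [spectrum_set()] of tablet measurements.
#' @param blanks A [spectrum_set()] of blank measurements (>= 1).
#' @param mz_tol Matching tolerance in Daltons (default 0.015).
#' @return The background-subtracted `spectrum_set`.
#' @export
subtract_background <- function(spectra, blanks, mz_tol = 0.015) {
  if (mz_tol <= 0) stop("mz_tol must be > 0")
  if (nrow(blanks) == 0 || length(unique(blanks$measurement_id)) == 0)
    stop("at least one blank measurement is required")
  n_blank <- length(unique(blanks$measurement_id))
  bl <- blanks[order(blanks$mz), , drop = FALSE]
  # single-linkage clusters of blank peaks along m/z
  grp <- cumsum(c(1, diff(bl$mz) >= mz_tol))
  bg_mz <- tapply(bl$mz * bl$intensity, grp, sum) /
    tapply(bl$intensity, grp, sum)
  bg_level <- tapply(bl$intensity, grp, sum) / n_blank
  out <- spectra
  if (nrow(out)) {
    idx <- vapply(out$mz, function(mz) {
      k <- which.min(abs(bg_mz - mz))
      if (abs(bg_mz[k] - mz) <= mz_tol) k else NA_integer_
    }, integer(1))
    hit <- !is.na(idx)
    out$intensity[hit] <- out$intensity[hit] - bg_level[idx[hit]]
    out <- out[out$intensity > 0, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Normalize peak intensities to relative scale
#'
#' Per measurement, intensities are rescaled so the base peak equals 100.
#'
#' @param spectra A [spectrum_set()].
#' @return The normalized `spectrum_set` (intensities in (0, 100\]).
#' @export
normalize_relative <- function(spectra) {
  if (nrow(spectra) == 0) stop("no peaks to normalize")
  for (idx in split_measurements(spectra)) {
    mx <- max(spectra$intensity[idx])
    if (mx <= 0) stop("measurement with no positive peak: ",
                      spectra$measurement_id[idx[1]])
    spectra$intensity[idx] <- 100 * spectra$intensity[idx] / mx
  }
  spectra
}

#' Aggregate peaks closer than a mass window
#'
#' Within each measurement, peaks are merged by single-linkage along m/z:
#' runs of consecutive peaks whose gaps are all `< window` collapse into one
#' peak carrying the summed intensity and the intensity-weighted mean m/z.
#' Total intensity is conserved.
#'
#' @param spectra A [spectrum_set()].
#' @param window Mass window in Daltons (default 1.0).
#' @return The aggregated `spectrum_set`.
#' @export
aggregate_masses <- function(spectra, window = 1.0) {
  if (window <= 0) stop("window must be > 0")
  if (nrow(spectra) == 0) return(spectra)
  pieces <- lapply(split_measurements(spectra), function(idx) {
    sub <- spectra[idx, , drop = FALSE]   # already sorted by mz
    grp <- cumsum(c(1, diff(sub$mz) >= window))
    w <- tapply(sub$intensity, grp, sum)
    mz <- tapply(sub$mz * sub$intensity, grp, sum) / w
    first <- sub[!duplicated(grp), , drop = FALSE]
    first$mz <- as.numeric(mz)
    first$intensity <- as.numeric(w)
    first
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- class(spectra)
  out
}

#' Align peaks across measurements into a feature matrix
#'
#' All peaks are pooled, sorted by m/z, and clustered greedily: a peak joins
#' the current cluster while it lies within `mz_tol` of the cluster's
#' intensity-weighted centroid, otherwise it opens a new cluster. Every peak
#' maps to exactly one feature. The result is a measurement x feature
#' intensity matrix (0 where a measurement has no peak in a feature; summed
#' when it has several).
#'
#' @param spectra A [spectrum_set()].
#' @param mz_tol Alignment tolerance in Daltons (default 0.015, i.e. 15 mmu).
#' @return A `feature_matrix`: numeric matrix with measurement ids as rows
#'   and consensus m/z (formatted to 4 decimals) as column names, plus
#'   attributes `mz` (numeric consensus masses), `tablet_id` and
#'   `group_label` (aligned to rows).
#' @export
align_features <- function(spectra, mz_tol = 0.015) {
  if (mz_tol <= 0) stop("mz_tol must be > 0")
  sp <- spectra[order(spectra$mz), , drop = FALSE]
  n <- nrow(sp)
  if (n == 0) stop("no peaks to align")
  feat <- integer(n)
  centroid <- 0; wsum <- 0; k <- 0
  for (i in seq_len(n)) {
    if (k == 0 || sp$mz[i] - centroid > mz_tol) {
      k <- k + 1
      centroid <- sp$mz[i]; wsum <- sp$intensity[i]
    } else {
      w2 <- wsum + sp$intensity[i]
      centroid <- if (w2 > 0) (centroid * wsum + sp$mz[i] * sp$intensity[i]) / w2
                  else (centroid + sp$mz[i]) / 2
      wsum <- w2
    }
    feat[i] <- k
  }
  mz_cons <- tapply(sp$mz * pmax(sp$intensity, 1e-12), feat, sum) /
    tapply(pmax(sp$intensity, 1e-12), feat, sum)
  meas <- sort(unique(spectra$measurement_id))
  mat <- matrix(0, length(meas), k,
                dimnames = list(meas, sprintf("%.4f", mz_cons)))
  for (i in seq_len(n))
    mat[sp$measurement_id[i], feat[i]] <- mat[sp$measurement_id[i], feat[i]] +
      sp$intensity[i]
  map <- sp[!duplicated(sp$measurement_id),
            c("measurement_id", "tablet_id", "group_label")]
  ord <- match(meas, map$measurement_id)
  structure(mat, mz = as.numeric(mz_cons),
            tablet_id = map$tablet_id[ord],
            group_label = map$group_label[ord],
            class = c("feature_matrix", "matrix", "array"))
}

#' ANOVA pre-selection of abundant, group-structured features
#'
#' Candidate features are those whose largest group-mean relative intensity
#' exceeds `min_intensity`. For each candidate, a one-way ANOVA compares the
#' two groups with the largest and smallest mean intensity; the feature is
#' kept when p < `alpha`. Groups contributing a single measurement are
#' excluded from the extremes with a warning.
#'
#' @param features A `feature_matrix` from [align_features()].
#' @param groups Group labels aligned to rows (default: the matrix's
#'   `group_label` attribute).
#' @param alpha Significance level (default 0.05).
#' @param min_intensity Relative-intensity floor in percent (default 10).
#' @return Character vector of selected feature keys (column names).
#' @export
anova_select <- function(features, groups = attr(features, "group_label"),
                         alpha = 0.05, min_intensity = 10) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_intensity < 0 || min_intensity > 100)
    stop("min_intensity must be in [0, 100]")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small))
    warning("group(s) with a single measurement excluded from extremes: ",
            paste(small, collapse = ", "))
  usable <- setdiff(names(sizes), small)
  if (length(usable) < 2) stop("fewer than two groups with >= 2 measurements")
  keep <- character(0)
  for (j in seq_len(ncol(features))) {
    mu <- tapply(features[, j], groups, mean)
    if (max(mu) <= min_intensity) next
    mu_use <- mu[usable]
    g_hi <- names(which.max(mu_use)); g_lo <- names(which.min(mu_use))
    if (g_hi == g_lo) next
    idx <- groups %in% c(g_hi, g_lo)
    x <- features[idx, j]; g <- factor(groups[idx])
    if (var(x) == 0) next   # flat feature, p would be undefined/1
    p <- anova(aov(x ~ g))$`Pr(>F)`[1]
    if (!is.na(p) && p < alpha) keep <- c(keep, colnames(features)[j])
  }
  keep
}

#' Fisher-ratio selection of two-class discriminant features
#'
#' For each feature, the Fisher ratio
#' \eqn{FR = (\bar x_A - \bar x_B)^2 / (s_A^2 + s_B^2)} (variances floored at
#' 1e-12) scores between-class separation against within-class spread.
#' Features whose class-mean fold change (max/min of the two class means,
#' each offset by 1 intensity unit so zero means stay finite) exceeds
#' `min_fold` are ranked by FR and the top `k` returned.
#'
#' @param features A `feature_matrix`.
#' @param labels Two-class labels aligned to rows.
#' @param k Number of features to keep (default 95).
#' @param min_fold Fold-change floor, exclusive (default 1, i.e. any
#'   difference in class means).
#' @return Character vector of feature keys, ranked by decreasing FR.
#' @export
fisher_ratio_select <- function(features, labels, k = 95, min_fold = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("exactly two classes required, got ",
                                 length(classes))
  if (k < 1) stop("k must be >= 1")
  a <- labels == classes[1]
  mA <- colMeans(features[a, , drop = FALSE])
  mB <- colMeans(features[!a, , drop = FALSE])
  vA <- apply(features[a, , drop = FALSE], 2, var)
  vB <- apply(features[!a, , drop = FALSE], 2, var)
  fr <- (mA - mB)^2 / pmax(vA + vB, 1e-12)
  fold <- pmax(mA + 1, mB + 1) / pmin(mA + 1, mB + 1)
  eligible <- which(fold > min_fold)
  eligible <- eligible[order(fr[eligible], decreasing = TRUE)]
  colnames(features)[head(eligible, k)]
}
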