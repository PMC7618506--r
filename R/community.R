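# Rarefaction, alpha/beta diversity, group testing and shared-ASV summaries.
#
# Standard ecology computations (Bray-Curtis, PERMANOVA, dispersion
# homogeneity) are delegated to vegan; the iterative-rarefaction averaging
# and the Dunn post-hoc machinery are implemented here.

round_half_up <- function(x) floor(x + 0.5)

#' Iterative rarefaction of a count table
#'
#' For each sample, draws `n_iter` independent without-replacement subsamples
#' of `depth` reads and returns the per-ASV mean across iterations, rounded
#' half-up. Averaging repeated draws stabilises the rarefied profile against
#' the randomness of a single subsample. Samples with fewer than `depth`
#' total reads are dropped with a warning.
#'
#' @param counts A [count_table()].
#' @param depth Target depth in reads (default 5000).
#' @param n_iter Number of rarefaction iterations (default 100).
#' @param seed Mandatory integer seed.
#' @return A rarefied [count_table()] containing the retained samples.
#' @export
rarefy_iterative <- function(counts, depth = 5000, n_iter = 100, seed) {
  if (missing(seed)) stop("seed is mandatory for rarefaction")
  if (depth < 1) stop("depth must be >= 1")
  if (n_iter < 1) stop("n_iter must be >= 1")
  totals <- colSums(unclass(counts))
  shallow <- names(totals)[totals < depth]
  if (length(shallow)) {
    warning("dropping ", length(shallow), " sample(s) below depth ", depth,
            ": ", paste(shallow, collapse = ", "))
    counts <- subset_counts(counts, cols = setdiff(colnames(counts), shallow))
  }
  if (ncol(counts) == 0) stop("no samples at or above the rarefaction depth")
  m <- t(unclass(counts))  # vegan rarefies rows
  set.seed(seed)
  acc <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  # vegan::rrarefy warns whenever the smallest positive count exceeds 1,
  # which is routine for real count tables; muffle that specific nag
  for (i in seq_len(n_iter)) {
    acc <- acc + withCallingHandlers(
      vegan::rrarefy(m, depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  out <- round_half_up(t(acc / n_iter))
  count_table(out, marker = marker(counts))
}

#' Alpha diversity (richness and Shannon index)
#'
#' Richness S is the number of ASVs with nonzero count; Shannon H is
#' \eqn{-\sum p_i \log p_i} with proportions taken per sample. Natural log by
#' default, following ecology convention.
#'
#' @param counts A [count_table()], typically rarefied.
#' @param base Log base for Shannon (default `exp(1)`; use 2 for bits).
#' @return Data frame with columns `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(counts, base = exp(1)) {
  m <- unclass(counts)
  zero <- colSums(m) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(m)[zero], collapse = ", "))
  data.frame(
    sample_id = colnames(m),
    richness = as.integer(colSums(m > 0)),
    shannon = as.numeric(vegan::diversity(t(m), index = "shannon", base = base)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis rank-sum test across all groups, followed by
#' pairwise Dunn tests on the pooled ranks with Holm step-down adjustment
#' over all pairs. Used for group differences in alpha diversity, where
#' normality and homoscedasticity do not hold.
#'
#' @param values Numeric vector (e.g. a richness or Shannon column).
#' @param groups Factor or character vector of group labels, same length.
#' @return A list with `kw_statistic`, `kw_df`, `kw_p`, and `pairs`, a data
#'   frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  n_per <- table(groups)
  if (any(n_per < 2))
    stop("group(s) with < 2 observations: ",
         paste(names(n_per)[n_per < 2], collapse = ", "))
  kw <- kruskal.test(values, groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, groups, mean)
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
                 (1 / n_per[[g1]] + 1 / n_per[[g2]]))
    z[i] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  list(
    kw_statistic = unname(kw$statistic),
    kw_df = unname(kw$parameter),
    kw_p = kw$p.value,
    pairs = data.frame(group1 = combs[1, ], group2 = combs[2, ],
                       z = z, p = p, p_adj = p.adjust(p, method = "holm"),
                       stringsAsFactors = FALSE)
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d_{ij} = \sum_k |x_{ki} - x_{kj}| / \sum_k (x_{ki} + x_{kj})},
#' computed between sample columns. Conventionally computed on a rarefied
#' table so that depth differences do not masquerade as community turnover.
#'
#' @param counts A [count_table()].
#' @return A symmetric `dist`-backed matrix of class `matrix` with sample ids
#'   as dimnames; entries in \[0, 1\].
#' @export
bray_curtis <- function(counts) {
  m <- unclass(counts)
  zero <- colSums(m) == 0
  if (sum(zero) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the squared dissimilarity matrix and eigendecomposes it.
#' Coordinates are returned for positive-eigenvalue axes only, ordered by
#' non-increasing eigenvalue; negative eigenvalues (from non-Euclidean
#' dissimilarities such as Bray-Curtis) are reported alongside.
#'
#' @param d Square symmetric dissimilarity matrix with zero diagonal.
#' @return A list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   sorted decreasing), and `variance_explained` (proportion per retained
#'   axis, relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("dissimilarity matrix must be square and symmetric")
  n <- nrow(d)
  fit <- cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  rownames(coords) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = eig,
       variance_explained = eig[pos] / sum(eig[pos]))
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance with sequential (Type-I)
#' sums of squares in the order the terms are given, whole-row permutation,
#' and exact p-values \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. Delegates
#' to `vegan::adonis2`.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param design Named list (or data frame) of factors aligned to the rows of
#'   `d`, in the order terms should enter the model. Interaction terms may be
#'   included with formula syntax via `terms`.
#' @param terms Optional character vector of RHS terms (e.g.
#'   `c("country", "country:method")`); defaults to the main effects in
#'   `design` order.
#' @param n_perm Number of permutations (default 1e5, as conventional for
#'   this design; minimum 99).
#' @param seed Mandatory integer seed for the permutations.
#' @return Data frame with columns `term`, `Df`, `SS`, `R2`, `EV_pct`,
#'   `pseudo_F`, `p`, including `Residual` and `Total` rows.
#' @export
permanova <- function(d, design, terms = NULL, n_perm = 1e5, seed) {
  if (missing(seed)) stop("seed is mandatory for permutation tests")
  if (n_perm < 99) stop("n_perm must be >= 99")
  df <- as.data.frame(design, stringsAsFactors = TRUE)
  for (nm in names(df)) {
    f <- as.factor(df[[nm]])
    if (nlevels(droplevels(f)) < 2)
      stop("constant factor: ", nm)
    df[[nm]] <- f
  }
  if (is.null(terms)) terms <- names(df)
  form <- stats::as.formula(paste("dmat ~", paste(terms, collapse = " + ")))
  dmat <- stats::as.dist(as.matrix(d))
  set.seed(seed)
  fit <- vegan::adonis2(form, data = df, permutations = n_perm,
                        by = "terms")
  out <- data.frame(term = rownames(fit),
                    Df = fit$Df,
                    SS = fit$SumOfSqs,
                    R2 = fit$R2,
                    EV_pct = 100 * fit$R2,
                    pseudo_F = fit$F,
                    p = fit$`Pr(>F)`,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Homogeneity of multivariate group dispersions
#'
#' Distances of samples to their group spatial median in the full PCoA
#' embedding (with the standard negative-eigenvalue correction), followed by
#' a permutation test for differences in mean dispersion. Delegates to
#' `vegan::betadisper` / `vegan::permutest`. Groups of size 1 are excluded
#' from the test with a warning; their distances are still returned.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group labels aligned to rows of `d`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Mandatory integer seed.
#' @return A list with `distances` (per-sample distance to group median),
#'   `group_means`, `F`, `p` (`NA` when fewer than two testable groups).
#' @export
betadisper_test <- function(d, groups, n_perm = 999, seed) {
  if (missing(seed)) stop("seed is mandatory for permutation tests")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  bd <- vegan::betadisper(stats::as.dist(as.matrix(d)), groups,
                          type = "median")
  distances <- bd$distances
  sizes <- table(droplevels(groups))
  singletons <- names(sizes)[sizes < 2]
  keep <- !(as.character(groups) %in% singletons)
  Fval <- NA_real_; pval <- NA_real_
  testable <- droplevels(groups[keep])
  if (length(singletons))
    warning("group(s) of size 1 excluded from dispersion test: ",
            paste(singletons, collapse = ", "))
  if (nlevels(testable) >= 2) {
    bd2 <- if (all(keep)) bd else
      vegan::betadisper(stats::as.dist(as.matrix(d)[keep, keep]), testable,
                        type = "median")
    set.seed(seed)
    pt <- vegan::permutest(bd2, permutations = n_perm)
    Fval <- pt$tab$F[1]
    pval <- pt$tab$`Pr(>F)`[1]
  } else {
    warning("fewer than two groups of size >= 2; dispersion test skipped")
  }
  list(distances = distances,
       group_means = tapply(distances, groups, mean),
       F = Fval, p = pval)
}

#' Pairwise shared-ASV counts between sample groups
#'
#' Entry (g, h) is the number of ASVs detected (nonzero) in at least one
#' sample of group g and at least one sample of group h. The diagonal is the
#' group-level richness.
#'
#' @param counts A [count_table()].
#' @param grouping Named character/factor vector mapping every sample in
#'   `counts` to a group, or a list of sample-id vectors per group.
#' @return Symmetric integer matrix, groups as dimnames.
#' @export
shared_asvs <- function(counts, grouping) {
  m <- unclass(counts)
  if (is.list(grouping)) {
    groups <- grouping
  } else {
    if (is.null(names(grouping))) {
      if (length(grouping) != ncol(m))
        stop("unnamed grouping must align with the sample columns")
      names(grouping) <- colnames(m)
    }
    groups <- split(names(grouping), as.character(grouping))
  }
  if (any(!lengths(groups)))
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0], collapse = ", "))
  missing_smp <- setdiff(unlist(groups), colnames(m))
  if (length(missing_smp))
    stop("sample(s) not in table: ", paste(missing_smp, collapse = ", "))
  present <- vapply(groups, function(s)
    rowSums(m[, s, drop = FALSE] > 0) > 0, logical(nrow(m)))
  out <- crossprod(present)  # logical -> numeric inner products
  storage.mode(out) <- "integer"
  out
}
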