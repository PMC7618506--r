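# Origin prediction: discriminant analysis of principal components (DAPC),
# kernel discriminant analysis (KDA), leave-one-out cross-validation and
# held-out group prediction.

as_feature_mat <- function(x) {
  m <- as.matrix(unclass(x))
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' Fit a DAPC model
#'
#' Centers the features, runs PCA, retains the smallest number of principal
#' components whose cumulative variance reaches `var_target` (capped at
#' n - number of classes so the subsequent LDA stays solvable), and fits a
#' linear discriminant analysis with equal class priors on the retained PC
#' scores. Posteriors come from the Gaussian class model of the LDA.
#'
#' @param features Samples x features numeric matrix (e.g. rarefied counts of
#'   differentially abundant ASVs, or spectral intensities).
#' @param labels Class labels, >= 2 classes with >= 2 samples each.
#' @param var_target Cumulative variance to retain in (0, 1\] (default 0.90).
#' @param scale Scale features to unit variance before PCA (default FALSE;
#'   centered raw values are used).
#' @return A `discriminant_model` of kind `"dapc"`.
#' @export
fit_dapc <- function(features, labels, var_target = 0.90, scale = FALSE) {
  x <- as_feature_mat(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  if (var_target <= 0 || var_target > 1) stop("var_target must be in (0, 1]")
  ctr <- colMeans(x)
  scl <- if (scale) {
    s <- apply(x, 2, sd); s[s == 0] <- 1; s
  } else rep(1, ncol(x))
  xc <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  pc <- prcomp(xc, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  pos <- ev > max(ev) * 1e-12
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= var_target)[1]
  k <- min(k, nrow(x) - length(classes), sum(pos))
  if (is.na(k) || k < 1) stop("no usable principal components (k = 0)")
  scores <- pc$x[, seq_len(k), drop = FALSE]
  prior <- rep(1 / length(classes), length(classes))
  fit <- MASS::lda(scores, grouping = factor(labels, levels = classes),
                   prior = prior)
  structure(list(kind = "dapc", classes = classes, center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_pcs = k, cum_variance = cumvar[k], lda = fit,
                 feature_keys = colnames(x)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("discriminant_model [%s]: %d classes (%s)", x$kind,
              length(x$classes), paste(x$classes, collapse = ", ")))
  if (x$kind == "dapc")
    cat(sprintf("; %d PCs retained (%.1f%% variance)", x$n_pcs,
                100 * x$cum_variance))
  cat("\n")
  invisible(x)
}

rbf_kernel <- function(a, b, h) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-pmax(d2, 0) / (2 * h^2))
}

#' Fit a kernel discriminant analysis model
#'
#' Kernel Fisher discriminant analysis with a radial-basis kernel: the
#' between-class and within-class scatter operators are formed in the kernel
#' feature space, the within-class scatter is ridge-regularized (1e-6
#' relative to its mean diagonal), and the leading generalized eigenvectors
#' give up to (classes - 1) nonlinear discriminant axes. Posteriors come
#' from a Gaussian model (class means, pooled covariance, equal priors) on
#' the discriminant projections.
#'
#' @param features Samples x features numeric matrix; conventionally the
#'   flagged discriminant features only.
#' @param labels Class labels, >= 2 classes.
#' @param bandwidth RBF bandwidth; default is the median pairwise Euclidean
#'   distance between training samples (median heuristic).
#' @return A `discriminant_model` of kind `"kda"`.
#' @export
fit_kda <- function(features, labels, bandwidth = NULL) {
  x <- as_feature_mat(features)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need >= 2 classes")
  if (is.null(bandwidth)) {
    bandwidth <- median(dist(x))
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  n <- nrow(x)
  K <- rbf_kernel(x, x, bandwidth)
  m_all <- rowMeans(K)
  M <- matrix(0, n, n); N <- matrix(0, n, n)
  for (cl in classes) {
    idx <- which(labels == cl)
    nc <- length(idx)
    mc <- rowMeans(K[, idx, drop = FALSE])
    M <- M + nc * tcrossprod(mc - m_all)
    Kc <- K[, idx, drop = FALSE]
    N <- N + tcrossprod(Kc) - nc * tcrossprod(mc)
  }
  ridge <- 1e-6 * max(mean(diag(N)), 1)
  Nr <- N + diag(ridge, n)
  eg <- eigen(solve(Nr, M))
  d <- min(length(classes) - 1, n - 1)
  alpha <- Re(eg$vectors[, seq_len(d), drop = FALSE])
  z <- K %*% alpha
  # normalize axes to unit pooled within-class variance for a stable
  # Gaussian posterior model
  for (j in seq_len(d)) {
    wv <- mean(tapply(z[, j], labels, var), na.rm = TRUE)
    sc <- if (is.finite(wv) && wv > 1e-12) sqrt(wv) else max(sd(z[, j]), 1e-6)
    alpha[, j] <- alpha[, j] / sc
  }
  z <- K %*% alpha
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(z[labels == cl, , drop = FALSE])))
  rownames(mu) <- classes
  structure(list(kind = "kda", classes = classes, bandwidth = bandwidth,
                 train_x = x, train_labels = labels, alpha = alpha,
                 class_means = mu, feature_keys = colnames(x)),
            class = "discriminant_model")
}

#' Class membership prediction
#'
#' Projects query samples into the model's discriminant space and returns
#' posterior class probabilities (equal priors). Missing features are
#' imputed as zero with a warning; ties are assigned to the
#' lexicographically first class and flagged.
#'
#' @param model A `discriminant_model` from [fit_dapc()] or [fit_kda()].
#' @param queries Samples x features numeric matrix (row names = sample ids).
#' @return A `membership_prediction` data frame: one row per query with
#'   `sample_id`, `assigned`, `tie`, and one posterior column per class.
#' @export
predict_membership <- function(model, queries) {
  q <- as.matrix(unclass(queries))
  if (is.null(rownames(q))) rownames(q) <- paste0("q", seq_len(nrow(q)))
  keys <- model$feature_keys
  if (!is.null(colnames(q))) {
    overlap <- intersect(keys, colnames(q))
    if (length(overlap) == 0) stop("no overlapping features with the model")
    if (length(overlap) < length(keys))
      warning(length(keys) - length(overlap),
              " model feature(s) missing from queries; imputed as 0")
    full <- matrix(0, nrow(q), length(keys),
                   dimnames = list(rownames(q), keys))
    full[, overlap] <- q[, overlap]
    q <- full
  } else if (ncol(q) != length(keys)) {
    stop("query feature count does not match the model")
  }
  storage.mode(q) <- "double"
  if (model$kind == "dapc") {
    qc <- sweep(sweep(q, 2, model$center), 2, model$scale, "/")
    scores <- qc %*% model$rotation
    post <- stats::predict(model$lda, scores)$posterior
  } else {
    Kq <- rbf_kernel(q, model$train_x, model$bandwidth)
    z <- Kq %*% model$alpha
    d2 <- outer(rowSums(z^2), rowSums(model$class_means^2), "+") -
      2 * tcrossprod(z, model$class_means)
    lp <- -0.5 * pmax(d2, 0)
    lp <- lp - apply(lp, 1, max)
    post <- exp(lp) / rowSums(exp(lp))
    colnames(post) <- rownames(model$class_means)
  }
  post <- post[, model$classes, drop = FALSE]
  best <- apply(post, 1, max)
  tie <- abs(post - best) < 1e-9
  assigned <- model$classes[apply(tie, 1, which.max)]
  out <- data.frame(sample_id = rownames(q), assigned = assigned,
                    tie = rowSums(tie) > 1, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(post))
  rownames(out) <- NULL
  class(out) <- c("membership_prediction", "data.frame")
  out
}

#' Leave-one-out cross-validation
#'
#' For each sample, refits the classifier on the remaining n - 1 samples and
#' predicts the held-out sample. When a `selector` is supplied, feature
#' selection is re-run inside every fold on the training samples only, so
#' the held-out sample never influences which features are used (no
#' leakage). Folds that would leave a class empty are flagged and excluded
#' from the accuracy with a warning.
#'
#' @param features Samples x features numeric matrix.
#' @param labels Class labels aligned to rows.
#' @param fitter Function `(features, labels) -> discriminant_model`, e.g.
#'   `fit_dapc` or a closure fixing its options.
#' @param selector Optional function `(features, labels) -> feature keys`
#'   applied per fold before fitting.
#' @return A list with `predictions` (data frame: `sample_id`, `truth`,
#'   `assigned`, `correct`, `excluded`), `accuracy`, and `fold_features`
#'   (per-fold selected keys when a selector is used).
#' @export
loocv <- function(features, labels, fitter, selector = NULL) {
  x <- as_feature_mat(features)
  labels <- as.character(labels)
  n <- nrow(x)
  classes <- unique(labels)
  if (n < length(classes) + 1) stop("need n >= number of classes + 1")
  ids <- rownames(x) %||% paste0("s", seq_len(n))
  assigned <- character(n); excluded <- logical(n)
  fold_features <- vector("list", n)
  for (i in seq_len(n)) {
    tr_x <- x[-i, , drop = FALSE]; tr_y <- labels[-i]
    if (length(unique(tr_y)) < length(classes)) {
      excluded[i] <- TRUE
      assigned[i] <- NA_character_
      next
    }
    if (!is.null(selector)) {
      keys <- selector(tr_x, tr_y)
      fold_features[[i]] <- keys
      tr_x <- tr_x[, keys, drop = FALSE]
    }
    model <- fitter(tr_x, tr_y)
    qx <- x[i, , drop = FALSE]
    if (!is.null(selector)) qx <- qx[, fold_features[[i]], drop = FALSE]
    assigned[i] <- predict_membership(model, qx)$assigned[1]
  }
  if (any(excluded))
    warning(sum(excluded), " fold(s) excluded: leaving the sample out ",
            "empties its class")
  ok <- !excluded
  preds <- data.frame(sample_id = ids, truth = labels, assigned = assigned,
                      correct = assigned == labels, excluded = excluded,
                      stringsAsFactors = FALSE)
  list(predictions = preds,
       accuracy = mean(preds$correct[ok]),
       fold_features = if (is.null(selector)) NULL else fold_features)
}
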