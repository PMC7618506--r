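test_that("iterative rarefaction matches forced and hypergeometric cases", {
  # single-ASV sample is forced to the full depth
  one <- make_counts(matrix(6000, 1, 1, dimnames = list("a", "s")))
  r <- rarefy_iterative(one, depth = 5000, n_iter = 3, seed = 1)
  expect_identical(as.integer(r[1, 1]), 5000L)

  # sample below depth is dropped with a warning
  two <- make_counts(matrix(c(6000, 4999), 1, 2,
                            dimnames = list("a", c("deep", "shallow"))))
  expect_warning(r2 <- rarefy_iterative(two, depth = 5000, n_iter = 2,
                                        seed = 1), "shallow")
  expect_identical(colnames(r2), "deep")

  # hypergeometric expectation: 9000/1000 split at depth 5000 -> ~4500
  mix <- make_counts(matrix(c(9000, 1000), 2, 1,
                            dimnames = list(c("a1", "a2"), "s")))
  r3 <- rarefy_iterative(mix, depth = 5000, n_iter = 200, seed = 7)
  expect_lt(abs(r3["a1", "s"] - 4500), 50)

  # column sums conserved within the per-ASV rounding slack
  x <- random_counts(30, 5, lambda = 300, seed = 2)
  r4 <- rarefy_iterative(x, depth = 1000, n_iter = 20, seed = 3)
  expect_true(all(abs(colSums(unclass(r4)) - 1000) <= nrow(r4) * 0.5))

  expect_error(rarefy_iterative(x, depth = 1000, n_iter = 0, seed = 1),
               "n_iter")
  expect_error(rarefy_iterative(x, depth = 1000, n_iter = 5), "seed")
})

test_that("alpha diversity matches closed forms and the uniform maximum", {
  m <- make_counts(matrix(c(5000, 0, 0, 0,
                            2500, 2500, 0, 0,
                            1000, 1000, 1000, 1000), 4, 3,
                          dimnames = list(paste0("a", 1:4), c("s1", "s2", "s3"))))
  a <- alpha_diversity(m)
  expect_identical(a$richness, c(1L, 2L, 4L))
  expect_equal(a$shannon, c(0, log(2), log(4)), tolerance = 1e-12)

  bad <- matrix(c(1, 0), 1, 2, dimnames = list("a", c("ok", "empty")))
  expect_error(alpha_diversity(make_counts(bad)), "empty")

  # H maximal (= ln S) iff counts uniform
  set.seed(11)
  for (i in 1:10) {
    v <- rpois(8, 30) + 1
    x <- make_counts(matrix(v, 8, 1, dimnames = list(paste0("a", 1:8), "s")))
    h <- alpha_diversity(x)$shannon
    if (length(unique(v)) == 1) expect_equal(h, log(8)) else
      expect_lt(h, log(8))
  }
})

test_that("Kruskal-Wallis/Dunn matches brute force and respects symmetry", {
  # extreme separation attains the maximal statistic over all rank splits
  v <- c(1, 2, 3, 101, 102, 103)
  g <- rep(c("lo", "hi"), each = 3)
  res <- kruskal_dunn(v, g)
  all_stats <- apply(utils::combn(6, 3), 2, function(idx) {
    gg <- rep("b", 6); gg[idx] <- "a"
    kruskal.test(v, factor(gg))$statistic
  })
  expect_equal(unname(res$kw_statistic), max(all_stats), tolerance = 1e-12)

  # label symmetry
  res2 <- kruskal_dunn(v, rev(g))
  expect_equal(res2$kw_statistic, res$kw_statistic)

  # Dunn z against an independent hand computation (pooled ranks, ties)
  v2 <- c(1, 2, 2, 5, 7, 8, 3, 9, 10)
  g2 <- rep(c("a", "b", "c"), each = 3)
  d <- kruskal_dunn(v2, g2)
  r <- rank(v2); N <- 9
  ties <- table(v2); tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tiecor) * (2 / 3))
  z_ab <- (mean(r[1:3]) - mean(r[4:6])) / se
  expect_equal(d$pairs$z[d$pairs$group1 == "a" & d$pairs$group2 == "b"],
               z_ab, tolerance = 1e-12)
  # Holm adjustment is monotone and >= raw p
  expect_true(all(d$pairs$p_adj >= d$pairs$p - 1e-15))

  expect_error(kruskal_dunn(1:4, c("a", "a", "a", "b")), "< 2 observations")
})

test_that("Kruskal-Wallis rejects at close to nominal rate under the null", {
  set.seed(21)
  rej <- mean(replicate(400, {
    kruskal_dunn(rnorm(20), rep(c("a", "b"), each = 10))$kw_p <= 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("Bray-Curtis matches the formula on hand examples", {
  m <- make_counts(matrix(c(6, 4, 0,
                            2, 4, 4,
                            6, 4, 0,
                            0, 0, 9), 3, 4,
                          dimnames = list(paste0("a", 1:3),
                                          c("x", "y", "x2", "disjoint"))))
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 8 / 20)       # sum|x-y| / sum(x+y)
  expect_equal(d["x", "x2"], 0)
  expect_equal(d["x", "disjoint"], 1)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))

  mz <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3,
               dimnames = list(c("a", "b"), c("s1", "z1", "z2")))
  expect_error(bray_curtis(make_counts(mz)), "all-zero")
})

test_that("PCoA reconstructs Euclidean geometry", {
  # colinear points: axis-1 inter-point distances reproduce the input
  pts <- c(0, 1, 3, 7)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-9)

  # equal off-diagonals -> equilateral configuration
  d3 <- matrix(0.5, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  pd <- dist(pcoa(d3)$coordinates)
  expect_lt(diff(range(pd)), 1e-9)

  # two samples at d = 0.4 -> +-0.2 on axis 1
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(sort(unname(pcoa(d2)$coordinates[, 1])), c(-0.2, 0.2),
               tolerance = 1e-9)

  d_asym <- d; d_asym[1, 2] <- 9
  expect_error(pcoa(d_asym), "symmetric")
})

test_that("PERMANOVA attains the permutation minimum and partitions variance", {
  set.seed(31)
  x <- cbind(matrix(rpois(15 * 10, 5), 15, 10),
             matrix(rpois(15 * 10, 60), 15, 10))
  rownames(x) <- paste0("a", 1:15); colnames(x) <- paste0("s", 1:20)
  d <- bray_curtis(make_counts(x))
  g <- rep(c("lo", "hi"), each = 10)
  pt <- permanova(d, list(group = g), n_perm = 999, seed = 5)
  expect_equal(pt$p[1], 1 / 1000)
  expect_equal(sum(pt$R2[pt$term != "Total"]), 1, tolerance = 1e-9)
  expect_equal(sum(pt$Df[pt$term != "Total"]), 20 - 1)
  expect_equal(pt$EV_pct, 100 * pt$R2)

  expect_error(permanova(d, list(g = rep("x", 20)), n_perm = 99, seed = 1),
               "constant")
  expect_error(permanova(d, list(g = g), n_perm = 99), "seed")
})

test_that("dispersion test sees inflation and respects symmetry", {
  # mirror-symmetric groups: equal mean dispersions
  set.seed(41)
  base <- matrix(rnorm(8 * 3), 8, 3)
  pts <- rbind(base, base + 10)    # same shape, translated
  d <- as.matrix(dist(pts)); dimnames(d) <- list(paste0("s", 1:16),
                                                 paste0("s", 1:16))
  g <- rep(c("g1", "g2"), each = 8)
  bd <- betadisper_test(d, g, n_perm = 199, seed = 1)
  expect_equal(unname(bd$group_means["g1"]), unname(bd$group_means["g2"]),
               tolerance = 1e-9)

  # inflated cluster detected
  hits <- replicate(20, {
    a <- matrix(rnorm(8 * 3, sd = 1), 8, 3)
    b <- matrix(rnorm(8 * 3, sd = 10), 8, 3)
    dd <- as.matrix(dist(rbind(a, b)))
    dimnames(dd) <- list(paste0("s", 1:16), paste0("s", 1:16))
    betadisper_test(dd, g, n_perm = 199, seed = 2)$p <= 0.05
  })
  expect_gte(mean(hits), 0.95)

  # singleton group excluded with warning; distances still returned
  g1 <- c(rep("g1", 15), "solo")
  w <- capture_warnings(b1 <- betadisper_test(d, g1, n_perm = 99, seed = 3))
  expect_true(any(grepl("size 1", w)))       # singleton exclusion
  expect_true(any(grepl("skipped", w)))      # only one testable group left
  expect_length(b1$distances, 16)
  expect_true(is.na(b1$p))
})

test_that("shared-ASV counts equal the set-intersection oracle", {
  m <- matrix(c(1, 0, 0,
                1, 1, 0,
                0, 1, 0,
                0, 0, 2), 4, 3, byrow = TRUE,
              dimnames = list(paste0("a", 1:4), c("s1", "s2", "s3")))
  x <- make_counts(m)
  grp <- list(g1 = "s1", g2 = "s2", g3 = "s3")
  sh <- shared_asvs(x, grp)
  expect_identical(sh["g1", "g3"], 0L)           # disjoint supports
  expect_identical(sh["g1", "g1"], 2L)           # identical group = richness
  expect_identical(sh["g1", "g2"], 1L)

  set.seed(51)
  big <- random_counts(100, 12, lambda = 1, seed = 51)
  grouping <- setNames(rep(c("u", "v", "w"), each = 4), colnames(big))
  sh2 <- shared_asvs(big, grouping)
  support <- lapply(split(names(grouping), grouping), function(s)
    rownames(big)[rowSums(unclass(big)[, s, drop = FALSE] > 0) > 0])
  for (a in names(support)) for (b in names(support))
    expect_identical(sh2[a, b],
                     length(intersect(support[[a]], support[[b]])))

  expect_error(shared_asvs(x, list(g1 = character(0), g2 = "s1")), "empty")
})
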