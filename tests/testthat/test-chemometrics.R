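sp_df <- function(meas, mz, int, grp = "G", tab = meas) {
  data.frame(measurement_id = meas, tablet_id = tab, group_label = grp,
             mz = mz, intensity = int, stringsAsFactors = FALSE)
}

test_that("background subtraction zeroes matched peaks and spares the rest", {
  blanks <- spectrum_set(sp_df(rep(c("b1", "b2"), each = 1),
                               c(100.000, 100.004), c(10, 14)),
                         blank_groups = "G")
  sp <- spectrum_set(sp_df("m1", c(100.002, 250.0), c(12, 40)))
  out <- subtract_background(sp, blanks, mz_tol = 0.015)
  # peak equal to the blank mean (24/2 = 12) is removed entirely
  expect_identical(out$mz, 250.0)
  expect_identical(out$intensity, 40)

  expect_error(subtract_background(sp, sp[0, ], 0.015), "blank")

  # randomized fixture vs brute-force nearest-match oracle
  set.seed(71)
  bmz <- sort(runif(10, 60, 790)); bint <- runif(10, 5, 20)
  blanks2 <- spectrum_set(sp_df("b1", bmz, bint), blank_groups = "G")
  smz <- sort(runif(40, 60, 790)); sint <- runif(40, 1, 100)
  sp2 <- spectrum_set(sp_df("m1", smz, sint))
  out2 <- subtract_background(sp2, blanks2, mz_tol = 0.2)
  expected <- sint
  for (i in seq_along(smz)) {
    k <- which.min(abs(bmz - smz[i]))
    if (abs(bmz[k] - smz[i]) <= 0.2) expected[i] <- sint[i] - bint[k]
  }
  keep <- expected > 0
  expect_equal(out2$mz, smz[keep])
  expect_equal(out2$intensity, expected[keep], tolerance = 1e-9)
})

test_that("relative normalization scales the base peak to 100", {
  sp <- spectrum_set(sp_df("m1", c(100, 200), c(10, 5)))
  out <- normalize_relative(sp)
  expect_equal(out$intensity, c(100, 50))

  one <- normalize_relative(spectrum_set(sp_df("m1", 100, 3)))
  expect_equal(one$intensity, 100)

  # scale invariance
  sp7 <- sp; sp7$intensity <- sp7$intensity * 7
  expect_equal(normalize_relative(spectrum_set(as.data.frame(sp7)))$intensity,
               out$intensity)
})

test_that("mass aggregation merges sub-window gaps and conserves intensity", {
  sp <- spectrum_set(sp_df("m1", c(100.2, 100.9, 103.0, 104.5),
                           c(4, 6, 2, 8)))
  out <- aggregate_masses(sp, window = 1.0)
  expect_identical(nrow(out), 3L)
  # merged peak: intensity sum 10, intensity-weighted mean m/z
  expect_equal(out$intensity[1], 10)
  expect_equal(out$mz[1], (100.2 * 4 + 100.9 * 6) / 10)
  # peaks >= 1 Da apart stay distinct
  expect_true(all(c(103.0, 104.5) %in% out$mz))

  set.seed(72)
  big <- spectrum_set(sp_df("m1", sort(runif(200, 50, 800)),
                            runif(200, 1, 50)))
  agg <- aggregate_masses(big, window = 1.0)
  expect_equal(sum(agg$intensity), sum(big$intensity), tolerance = 1e-9)
})

test_that("feature alignment clusters at tolerance and maps every peak", {
  sp <- spectrum_set(rbind(sp_df("m1", c(200.000, 300.0), c(10, 5)),
                           sp_df("m2", c(200.010, 300.5), c(20, 5))))
  fm <- align_features(sp, mz_tol = 0.015)
  expect_identical(ncol(fm), 3L)   # 200.00x shared; 300.0 and 300.5 distinct
  expect_equal(unname(fm["m1", 1]), 10)
  expect_equal(unname(fm["m2", 1]), 20)

  # column count equals a brute-force gap-clustering oracle on separated data
  set.seed(73)
  centers <- seq(100, 700, by = 3)
  rows <- do.call(rbind, lapply(1:5, function(m) {
    picked <- sample(centers, 60)
    sp_df(paste0("m", m), sort(picked + runif(60, -0.005, 0.005)),
          runif(60, 1, 100))
  }))
  spb <- spectrum_set(rows)
  fmb <- align_features(spb, mz_tol = 0.015)
  mz_all <- sort(spb$mz)
  oracle_k <- sum(diff(mz_all) > 0.015) + 1
  expect_identical(ncol(fmb), as.integer(oracle_k))
  # peak conservation: total intensity preserved in the matrix
  expect_equal(sum(fmb), sum(spb$intensity), tolerance = 1e-9)
})

test_that("ANOVA pre-selection enforces the intensity floor and finds shifts", {
  set.seed(74)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  flat <- rnorm(12, 50, 1)
  low <- rnorm(12, 5, 1)                     # < 10% everywhere
  shift <- c(rnorm(4, 80, 2), rnorm(4, 40, 2), rnorm(4, 20, 2))
  fm <- structure(cbind(flat = flat, low = low, shift = shift),
                  group_label = grp,
                  class = c("feature_matrix", "matrix", "array"))
  rownames(fm) <- paste0("m", 1:12)
  sel <- anova_select(fm, grp, alpha = 0.05, min_intensity = 10)
  expect_true("shift" %in% sel)
  expect_false("low" %in% sel)

  # planted group shift (delta = 50, sigma = 5, n = 12) found essentially always
  hits <- replicate(50, {
    x <- cbind(feat = c(rnorm(6, 70, 5), rnorm(6, 20, 5)))
    fmx <- structure(x, group_label = rep(c("hi", "lo"), each = 6),
                     class = c("feature_matrix", "matrix", "array"))
    rownames(fmx) <- paste0("m", 1:12)
    "feat" %in% anova_select(fmx, rep(c("hi", "lo"), each = 6))
  })
  expect_gte(mean(hits), 0.99)

  # single-measurement group warned and excluded from extremes
  g2 <- c(rep("a", 5), rep("b", 6), "solo")
  expect_warning(anova_select(fm, g2), "single measurement")
})

test_that("Fisher-ratio selection ranks planted discriminants first", {
  set.seed(75)
  lab <- rep(c("A", "B"), each = 10)
  ranks_ok <- replicate(50, {
    nulls <- matrix(rnorm(20 * 30, 50, 5), 20, 30)
    planted <- c(rnorm(10, 80, 5), rnorm(10, 30, 5))
    fm <- cbind(planted = planted, nulls)
    colnames(fm) <- c("planted", paste0("n", 1:30))
    sel <- fisher_ratio_select(fm, lab, k = 5)
    sel[1] == "planted"
  })
  expect_gte(mean(ranks_ok), 0.99)

  # equal class means give FR 0 and never beat a shifted feature
  fm0 <- cbind(same = rep(c(5, 5), each = 4), diff = rep(c(9, 1), each = 4))
  rownames(fm0) <- paste0("m", 1:8)
  sel0 <- fisher_ratio_select(fm0, rep(c("A", "B"), each = 4), k = 1)
  expect_identical(sel0, "diff")

  # k beyond the feature count returns all eligible features
  expect_length(fisher_ratio_select(fm0, rep(c("A", "B"), each = 4), k = 50), 1)

  # symmetry under class swap; invariance under common affine shift
  set.seed(76)
  fm1 <- matrix(rnorm(16 * 6, 40, 8), 16, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
  labs <- rep(c("A", "B"), each = 8)
  s1 <- fisher_ratio_select(fm1, labs, k = 6)
  s2 <- fisher_ratio_select(fm1, rev(labs), k = 6)
  expect_identical(s1, s2)
  s3 <- fisher_ratio_select(fm1 + 100, labs, k = 6, min_fold = 0)
  expect_identical(fisher_ratio_select(fm1, labs, k = 6, min_fold = 0), s3)

  expect_error(fisher_ratio_select(fm1, rep("A", 16), k = 5), "two classes")
})

test_that("preprocessing is invariant to measurement order", {
  set.seed(77)
  rows <- rbind(sp_df("m1", sort(runif(20, 60, 790)), runif(20, 1, 100)),
                sp_df("m2", sort(runif(20, 60, 790)), runif(20, 1, 100)))
  sp_fwd <- spectrum_set(rows)
  sp_rev <- spectrum_set(rows[rev(seq_len(nrow(rows))), ])
  chain <- function(sp) {
    fm <- align_features(aggregate_masses(normalize_relative(sp), 1.0), 0.015)
    fm[order(rownames(fm)), , drop = FALSE]
  }
  expect_equal(chain(sp_fwd), chain(sp_rev), ignore_attr = TRUE)
})
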