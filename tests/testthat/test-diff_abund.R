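test_that("abundance filter keeps ASVs at the inclusive total threshold", {
  m <- make_counts(matrix(c(999, 0, 500, 500, 10, 10), 3, 2, byrow = TRUE,
                          dimnames = list(c("below", "at", "low"),
                                          c("s1", "s2"))))
  out <- abundance_filter(m, 1000)
  expect_identical(rownames(out), "at")

  expect_identical(rownames(abundance_filter(m, 0)), rownames(m))

  set.seed(6)
  x <- random_counts(60, 6, lambda = 150, seed = 6)
  out2 <- abundance_filter(x, 900)
  expect_setequal(rownames(out2),
                  rownames(x)[sapply(seq_len(nrow(x)), function(i)
                    sum(unclass(x)[i, ]) >= 900)])
})

test_that("poscounts size factors match symmetry, equivariance and oracle", {
  # identical samples -> all 1
  m <- make_counts(matrix(rep(c(5, 0, 9, 2), 4), 4, 4,
                          dimnames = list(paste0("a", 1:4), paste0("s", 1:4))))
  expect_equal(unname(poscounts_size_factors(m)), rep(1, 4))

  # doubling one sample doubles its factor relative to others
  m2 <- unclass(m); m2[, 2] <- m2[, 2] * 2L
  s <- poscounts_size_factors(make_counts(m2))
  expect_equal(unname(s[2] / s[1]), 2, tolerance = 1e-9)

  # sparse random table vs an independently coded brute-force oracle
  set.seed(61)
  x <- matrix(rpois(80 * 6, 2) * rbinom(80 * 6, 1, 0.5), 80, 6,
              dimnames = list(paste0("a", 1:80), paste0("s", 1:6)))
  x[1, ] <- x[1, ] + 1   # keep every sample non-empty
  s2 <- poscounts_size_factors(make_counts(x))
  # oracle: literal per-row positive products; per-sample medians of the
  # count/reference ratios are taken on the log scale (geometric
  # interpolation at even counts, the reference estimator's convention)
  n <- ncol(x)
  ref <- apply(x, 1, function(r) if (any(r > 0)) prod(r[r > 0])^(1 / n) else 0)
  s_or <- sapply(seq_len(n), function(j) {
    ok <- ref > 0 & x[, j] > 0
    exp(median(log(x[ok, j] / ref[ok])))
  })
  s_or <- s_or / prod(s_or)^(1 / n)
  expect_equal(unname(s2), s_or, tolerance = 1e-9)
  expect_equal(prod(s2)^(1 / n), 1, tolerance = 1e-9)

  # row-permutation invariance
  s3 <- poscounts_size_factors(make_counts(x[sample(nrow(x)), ]))
  expect_equal(s3, s2, tolerance = 1e-12)

  expect_error(poscounts_size_factors(make_counts(
    matrix(c(1, 0), 1, 2, dimnames = list("a", c("s1", "s2"))))), "all-zero")
})

test_that("poscounts agrees with the DESeq2 reference estimator", {
  set.seed(62)
  x <- matrix(rpois(60 * 8, 3) * rbinom(60 * 8, 1, 0.6), 60, 8,
              dimnames = list(paste0("a", 1:60), paste0("s", 1:8)))
  x[1, ] <- x[1, ] + 2
  ours <- poscounts_size_factors(make_counts(x))
  ref <- DESeq2::estimateSizeFactorsForMatrix(x, type = "poscounts")
  ref <- ref / exp(mean(log(ref)))   # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Wald test recovers exact fold changes and the null point case", {
  # 3 tablets per country x method cell; counts chosen so normalized country
  # means are exactly 8 (A) and 2 (B) for asv1, equal for asv2
  ids <- list(a_dc = paste0("adc", 1:3), a_wg = paste0("awg", 1:3),
              b_dc = paste0("bdc", 1:3), b_wg = paste0("bwg", 1:3))
  sheet <- two_country_sheet(ids$a_dc, ids$a_wg, ids$b_dc, ids$b_wg)
  m <- rbind(asv1 = c(rep(8, 6), rep(2, 6)),
             asv2 = rep(5, 12),
             filler = rep(c(10, 20, 30, 10, 20, 30), 2))
  colnames(m) <- unlist(ids)
  ct <- make_counts(m)
  da <- wald_da_test(ct, sheet, size_factors = setNames(rep(1, 12),
                                                        colnames(m)))
  expect_equal(da$lfc[da$asv_id == "asv1"], 2)          # log2(8/2)
  expect_equal(da$lfc[da$asv_id == "asv2"], 0)
  expect_equal(da$p[da$asv_id == "asv2"], 1)
  expect_true(all(da$padj >= da$p - 1e-15))

  expect_error(wald_da_test(ct, sheet, q = 1.5), "q must be")
})

test_that("the country contrast is antisymmetric under label swap", {
  sim <- suppressWarnings(simulate_counts(da_benchmark_config(n_asvs = 120,
                                                              n_planted = 12),
                                          seed = 3))
  meta <- sim$sheet[match(colnames(sim$counts), sim$sheet$sample_id), ]
  tab <- pharmatrace:::subset_counts(
    sim$counts, cols = colnames(sim$counts)[meta$sample_type == "tablet"])
  tab <- abundance_filter(tab, 500)
  da1 <- wald_da_test(tab, sim$sheet)

  swapped <- as.data.frame(sim$sheet)
  swapped$country <- chartr("AB", "BA", swapped$country)
  sheet2 <- sample_sheet(swapped,
                         prediction_only = attr(sim$sheet, "prediction_only"))
  da2 <- wald_da_test(tab, sheet2)
  expect_equal(da2$lfc, -da1$lfc, tolerance = 1e-9)
  expect_equal(da2$p, da1$p, tolerance = 1e-9)
  expect_identical(da2$overabundant_in == "A", da1$overabundant_in == "B")
})

test_that("no-effect tables produce few overabundance flags", {
  # null benchmark: no planted effects, shared pool only
  fdr_flags <- sapply(1:3, function(s) {
    sim <- suppressWarnings(simulate_counts(
      da_benchmark_config(n_asvs = 300, n_planted = 0), seed = 100 + s))
    meta <- sim$sheet[match(colnames(sim$counts), sim$sheet$sample_id), ]
    tab <- pharmatrace:::subset_counts(
      sim$counts, cols = colnames(sim$counts)[meta$sample_type == "tablet"])
    da <- wald_da_test(abundance_filter(tab), sim$sheet)
    mean(da$overabundant_in != "none")
  })
  expect_lt(mean(fdr_flags), 0.05)
})
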