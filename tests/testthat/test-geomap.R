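test_that("overabundant-ASV selection applies all three rules", {
  # 6-sample fixture, hand enumeration: 3 tablets per country
  ids_a <- paste0("a", 1:3); ids_b <- paste0("b", 1:3)
  sheet <- two_country_sheet(ids_a[1:2], ids_a[3], ids_b[1:2], ids_b[3])
  m <- rbind(
    good_A   = c(5, 9, 0, 0, 0, 0),   # 2 A samples, absent in B -> in
    rare_A   = c(7, 0, 0, 0, 0, 0),   # only 1 A sample -> out
    leaky_A  = c(5, 9, 0, 1, 0, 0),   # present in B -> out
    good_B   = c(0, 0, 0, 3, 0, 4),
    unflagged = c(9, 9, 9, 0, 0, 0)   # not flagged by the DA test -> out
  )
  colnames(m) <- c(ids_a, ids_b)
  counts <- make_counts(m)
  da <- data.frame(asv_id = rownames(m),
                   overabundant_in = c("A", "A", "A", "B", "none"),
                   stringsAsFactors = FALSE)
  class(da) <- c("da_result", "data.frame")
  sel <- select_overabundant_asvs(da, counts, sheet, min_samples = 2)
  expect_identical(sel$A, "good_A")
  expect_identical(sel$B, "good_B")

  empty <- da[0, ]
  expect_warning(sel0 <- select_overabundant_asvs(empty, counts, sheet),
                 "empty")
  expect_length(sel0$A, 0)
})

test_that("LPI resolution follows the tied-hit rules and ignores row order", {
  h <- make_hits(rep("q1", 3), c("Sp X", "Sp Y", "Sp X"),
                 pid = c(99.1, 99.1, 98.0))
  r <- resolve_lpi(h, "q1")
  expect_identical(r$resolution, "species_set")
  expect_identical(r$taxa, c("Sp X", "Sp Y"))
  expect_equal(r$lpi, 99.1)

  # two tied hits to the same species -> single species
  h2 <- make_hits(rep("q2", 2), c("Sp X", "Sp X"), pid = c(99.1, 99.1))
  r2 <- resolve_lpi(h2, "q2")
  expect_identical(r2$resolution, "single_species")
  expect_identical(r2$taxa, "Sp X")

  # one LPI hit -> single species, lower hits ignored
  h3 <- make_hits(rep("q3", 2), c("Sp Z", "Sp W"), pid = c(99.5, 97.2))
  expect_identical(resolve_lpi(h3, "q3")$taxa, "Sp Z")

  # no hits -> unassigned
  expect_identical(resolve_lpi(h, "missing")$resolution, "unassigned")

  # row-order invariance
  hrev <- blast_hits(as.data.frame(h)[3:1, ])
  expect_equal(resolve_lpi(hrev, "q1"), r)
})

test_that("genus fallback applies only when no species-level assignment exists", {
  hits <- blast_hits(rbind(
    as.data.frame(make_hits("s1", "Sp X", "species", 99)),
    as.data.frame(make_hits("s1", "GenX", "genus", 99)),
    as.data.frame(make_hits("g1", "GenY", "genus", 98)),
    as.data.frame(make_hits("g2", "GenY", "genus", 97))
  ))
  # one species-level present: species assignments only
  res <- genus_fallback(hits, c("s1", "g1", "g2"))
  expect_identical(res$fallback, "species")
  expect_identical(res$taxa, "Sp X")

  # none at species level: genus rank used
  res2 <- genus_fallback(hits, c("g1", "g2"))
  expect_identical(res2$fallback, "genus")
  expect_identical(res2$taxa, "GenY")

  # neither: empty, flagged
  res3 <- genus_fallback(hits, "absent_asv")
  expect_identical(res3$fallback, "none")
  expect_length(res3$taxa, 0)
})

test_that("unified point maps pool records and conserve counts", {
  one <- occurrence_set(data.frame(species_name = "S1", longitude = 10.2,
                                   latitude = 45.3))
  pm <- unified_point_map(one, "S1", bin_width = 5)
  expect_identical(nrow(pm), 1L)
  expect_identical(pm$count, 1L)

  # pooling: two species x 5 records in the same spot -> one bin of 10
  pool <- occurrence_set(data.frame(
    species_name = rep(c("S1", "S2"), each = 5),
    longitude = 10.0, latitude = 45.0))
  pm2 <- unified_point_map(pool, c("S1", "S2"), bin_width = 5)
  expect_identical(pm2$count, 10L)

  # conservation at multiple widths, hex and square, vs point-in-bin oracle
  set.seed(81)
  occ <- occurrence_set(data.frame(
    species_name = sample(c("S1", "S2", "S3"), 300, TRUE),
    longitude = runif(300, -180, 180), latitude = runif(300, -90, 90)))
  for (w in c(2, 5, 15)) {
    hexm <- unified_point_map(occ, c("S1", "S2", "S3"), bin_width = w)
    sqm <- unified_point_map(occ, c("S1", "S2", "S3"), bin_width = w,
                             shape = "square")
    expect_identical(sum(hexm$count), 300L)
    expect_identical(sum(sqm$count), 300L)
  }
  # square oracle: counts per floor-indexed cell
  sqm5 <- unified_point_map(occ, c("S1", "S2", "S3"), bin_width = 5,
                            shape = "square")
  key <- paste(floor((occ$longitude + 180) / 5),
               floor((occ$latitude + 90) / 5))
  oracle <- table(key)
  expect_setequal(as.integer(sqm5$count), as.integer(oracle))
  expect_identical(sort(sqm5$count, decreasing = TRUE),
                   sort(as.integer(oracle), decreasing = TRUE))

  # species with zero records is warned about and listed
  expect_warning(pm3 <- unified_point_map(one, c("S1", "ghost"), 5), "ghost")
  expect_identical(attr(pm3, "missing_species"), "ghost")
})

test_that("unified region maps superimpose presences", {
  m <- matrix(c(1, 1, 0,
                0, 1, 1), 2, 3, byrow = TRUE,
              dimnames = list(c("A sp", "B sp"), c("R1", "R2", "R3")))
  rp <- region_presence(m)
  u <- unified_region_map(rp, c("A sp", "B sp"))
  expect_identical(u, c(R1 = 1L, R2 = 2L, R3 = 1L))

  # single-species group equals its own row
  expect_identical(unname(unified_region_map(rp, "A sp")), c(1L, 1L, 0L))

  # empty group: all-zero map
  expect_identical(unname(unified_region_map(rp, character(0))),
                   rep(0L, 3))

  # monotone when species are added
  expect_true(all(unified_region_map(rp, c("A sp", "B sp")) >=
                    unified_region_map(rp, "A sp")))

  expect_warning(unified_region_map(rp, c("A sp", "ghost")), "ghost")
})

test_that("site recovery: the modal bin of a site map falls near the site", {
  hits <- sapply(1:25, function(seed) {
    bio <- simulate_biogeography(seed = seed)
    sp_a <- bio$truth$species$species_name[bio$truth$species$pool == "site_A"]
    pm <- unified_point_map(bio$occurrences, sp_a, bin_width = 5)
    ctr <- default_biogeo_config()$site_a
    sqrt((pm$center_lon[1] - ctr[1])^2 + (pm$center_lat[1] - ctr[2])^2) <=
      default_biogeo_config()$range_radius
  })
  expect_gte(mean(hits), 0.9)
})
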