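# Habitat compilation: wetland merging, SAV persistence, classification,
# patchification.

test_that("wetland merge: inventory absent, idempotent, and precedence cases", {
  lc <- matrix("other", 12, 12)
  lc[2:4, 2:4] <- "open_wetland"
  lc[8:10, 8:10] <- "forested_wetland"
  lcr <- bc_raster(lc, 10)

  p0 <- merge_wetland_layers(lcr)
  expect_setequal(p0$habitat_class, c("open_wetland", "forested_wetland"))
  expect_equal(sum(p0$n_cells), 18L)

  # identical inventory: union equals either input
  nnk <- matrix(NA_character_, 12, 12)
  nnk[2:4, 2:4] <- "open_wetland"
  nnk[8:10, 8:10] <- "forested_wetland"
  p1 <- merge_wetland_layers(lcr, bc_raster(nnk, 10))
  expect_equal(sum(p1$n_cells), 18L)
  expect_equal(sort(p1$n_cells), sort(p0$n_cells))

  # conflicting class at an overlap: the inventory (vector source) wins
  nnk2 <- matrix(NA_character_, 12, 12)
  nnk2[2:4, 2:4] <- "forested_wetland"
  p2 <- merge_wetland_layers(lcr, bc_raster(nnk2, 10))
  fw <- sum(p2$n_cells[p2$habitat_class == "forested_wetland"])
  ow <- sum(p2$n_cells[p2$habitat_class == "open_wetland"])
  # per-cell oracle with precedence
  cls <- ifelse(!is.na(nnk2), nnk2,
                ifelse(lc %in% c("open_wetland", "forested_wetland"),
                       lc, NA))
  expect_equal(fw, sum(cls == "forested_wetland", na.rm = TRUE))
  expect_equal(ow, sum(cls == "open_wetland", na.rm = TRUE))

  lc_bad <- lc
  lc_bad[1, 1] <- "glacier"
  expect_error(merge_wetland_layers(bc_raster(lc_bad, 10)), "glacier")
})

test_that("SAV persistence filter honours the 4-of-5 rule and is monotone", {
  counts <- matrix(0L, 6, 6)
  counts[1, 1] <- 4L
  counts[1, 2] <- 3L
  counts[2, 1] <- 5L
  r <- bc_raster(counts, 10)
  m4 <- filter_sav_persistence(r, 4)
  expect_true(m4$values[1, 1])   # exactly 4 of 5 is retained
  expect_false(m4$values[1, 2])
  m1 <- filter_sav_persistence(r, 1)
  expect_equal(sum(m1$values), sum(counts >= 1)) # maximal extent

  set.seed(9)
  rnd <- bc_raster(matrix(sample(0:5, 400, TRUE), 20, 20), 10)
  prev <- NULL
  for (k in 5:1) {
    mk <- filter_sav_persistence(rnd, k)$values
    expect_equal(sum(mk), sum(rnd$values >= k)) # counting oracle
    if (!is.null(prev)) expect_true(all(mk[prev])) # k+1 mask inside k mask
    prev <- mk
  }
  expect_error(filter_sav_persistence(bc_raster(matrix(6L, 2, 2), 10)),
               "0-5")
  expect_error(filter_sav_persistence(rnd, 0), "1..5")
})

test_that("SAV classification follows the regional rules exactly", {
  nr <- 9
  nc <- 6
  region <- matrix(rep(c("north", "middle", "south"), each = 3), nr, nc)
  sav <- matrix(TRUE, nr, nc)
  model <- matrix(FALSE, nr, nc)
  model[5, ] <- TRUE # one modelled row inside the middle band
  out <- classify_sav(bc_raster(sav, 10), bc_raster(model, 10),
                      bc_raster(region, 10), default_region_rules())
  expect_true(all(out$values[1:3, ] == "other_rooted_macrophytes"))
  expect_true(all(out$values[5, ] == "seagrass"))          # model overlap
  expect_true(all(out$values[c(4, 6), ] == "other_rooted_macrophytes"))
  expect_true(all(out$values[7:9, ] == "seagrass"))        # all_seagrass

  # totality: every SAV cell gets exactly one submerged label
  set.seed(11)
  sav2 <- matrix(runif(nr * nc) < 0.5, nr, nc)
  out2 <- classify_sav(bc_raster(sav2, 10), bc_raster(model, 10),
                       bc_raster(region, 10), default_region_rules())
  expect_identical(!is.na(out2$values), sav2)
  # brute-force per-cell rule application
  expected <- matrix(NA_character_, nr, nc)
  for (ix in which(sav2)) {
    rule <- c(north = "all_other", middle = "model_overlap",
              south = "all_seagrass")[region[ix]]
    expected[ix] <- switch(rule,
      all_other = "other_rooted_macrophytes",
      all_seagrass = "seagrass",
      model_overlap = if (model[ix]) "seagrass" else
        "other_rooted_macrophytes")
  }
  expect_identical(out2$values, expected)

  expect_error(classify_sav(bc_raster(sav, 10), bc_raster(model, 10),
                            bc_raster(matrix("elsewhere", nr, nc), 10),
                            default_region_rules()),
               "missing classification rule")
})

test_that("patchification: connectivity, areas, and a component-count oracle", {
  cls <- matrix(NA_character_, 8, 8)
  cls[2, 2:6] <- "seagrass"
  cls[3, 2:6] <- "seagrass" # one 10-cell blob
  p <- patchify(bc_raster(cls, 10))
  expect_equal(nrow(p), 1L)
  expect_equal(p$area_km2, 0.001)
  expect_equal(p$realm, "submerged")

  # diagonal-touching blobs are two patches under 4-connectivity
  cls2 <- matrix(NA_character_, 6, 6)
  cls2[2, 2] <- "open_wetland"
  cls2[3, 3] <- "open_wetland"
  expect_equal(nrow(patchify(bc_raster(cls2, 10))), 2L)
  expect_equal(nrow(patchify(bc_raster(cls2, 10), connectivity = 8)), 1L)

  set.seed(21)
  for (rep in 1:6) {
    m <- matrix(runif(625) < 0.35, 25, 25)
    cls3 <- matrix(NA_character_, 25, 25)
    cls3[m] <- "seagrass"
    p3 <- patchify(bc_raster(cls3, 10))
    expect_equal(nrow(p3), oracle_component_count(m))
    # area conservation, exact
    expect_equal(sum(p3$n_cells), sum(m))
    expect_equal(sum(p3$area_km2), sum(m) * 1e-4)
  }

  expect_equal(nrow(patchify(bc_raster(matrix(NA_character_, 4, 4), 10))),
               0L)
})

test_that("subbasin assignment uses majority cell membership", {
  region <- matrix("south", 10, 10)
  region[1:6, ] <- "north"
  cells <- c(1:4, 7:8) # rows 1:4 north, rows 7:8 south (column 1)
  p <- assign_subbasins(toy_patches(list(cells), "open_wetland", 10, 10),
                        bc_raster(region, 10))
  expect_equal(p$subbasin, "north")
})
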