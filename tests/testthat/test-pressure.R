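# The three pressure components and the cumulative impact score.

test_that("proximity components match a brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:6) {
    nr <- 30
    nc <- 30
    m <- matrix(runif(nr * nc) < 0.3, nr, nc)
    cls <- matrix(NA_character_, nr, nc)
    cls[m] <- "seagrass"
    patches <- patchify(bc_raster(cls, 10))
    agri <- matrix(runif(nr * nc) < 0.02, nr, nc) & !m
    va <- agricultural_pressure(patches, lraster(agri))
    expected <- vapply(patches$cells, function(ix)
      oracle_distance_class(oracle_min_dist(ix, which(agri), nr, 10)),
      integer(1))
    expect_identical(va, expected)
  }
})

test_that("zero distance and absent stressors hit the scale ends", {
  cells <- 1:5
  p <- toy_patches(list(cells), "open_wetland", 10, 10)
  agri <- lmat(10, 10)
  agri[3] <- TRUE # overlaps the patch -> d = 0
  expect_identical(agricultural_pressure(p, lraster(agri)), 4L)
  expect_identical(agricultural_pressure(p, lraster(lmat(10, 10))), 0L)
  expect_identical(urban_pressure(p, lraster(lmat(10, 10))), 0L)
})

test_that("buffer-ring and distance-classified urban pressure agree", {
  # 50 m from an urban polygon -> innermost (100 m) zone -> 4
  p <- toy_patches(list(55L), "seagrass", 10, 30) # row 5, col 6
  urb <- lmat(10, 30)
  urb[5, 1] <- TRUE # 5 cells away -> 50 m
  expect_identical(urban_pressure(p, lraster(urb)), 4L)
  expect_identical(urban_pressure_rings(p, lraster(urb)), 4L)

  set.seed(33)
  for (rep in 1:25) {
    nr <- 25
    nc <- 25
    m <- matrix(runif(nr * nc) < 0.25, nr, nc)
    cls <- matrix(NA_character_, nr, nc)
    cls[m] <- "seagrass"
    patches <- patchify(bc_raster(cls, 10))
    urb <- matrix(runif(nr * nc) < 0.03, nr, nc) & !m
    expect_identical(urban_pressure(patches, lraster(urb)),
                     urban_pressure_rings(patches, lraster(urb)))
  }
})

test_that("basin linking: membership, spanning mean, nearest, exclusion", {
  nr <- 20
  nc <- 40
  lab <- matrix(0L, nr, nc)
  lab[1:10, 1:20] <- 1L
  lab[11:20, 1:20] <- 2L
  basins <- drainage_basins(bc_raster(lab, 10),
                            modified_proportion = c(25, 65)) # v = 1, 3
  expect_identical(basins$table$v_basin, c(1L, 3L))

  inside1 <- toy_patches(list(c(5L, 6L)), "open_wetland", nr, nc)
  expect_equal(basin_pressure(inside1, basins)$v_basin, 1)

  # spanning both basins: unweighted mean of 1 and 3
  span <- toy_patches(list(c(10L, 11L)), "open_wetland", nr, nc)
  expect_equal(basin_pressure(span, basins)$v_basin, 2)

  # submerged patch seaward of basin 2 -> nearest basin's value
  near <- toy_patches(list((23L - 1L) * nr + 15L), "seagrass", nr, nc)
  # col 23 is 3 cells (30 m) from basin edge at col 20
  res <- basin_pressure(near, basins)
  expect_equal(res$v_basin, 3)
  expect_false(res$basin_excluded)

  # farther than 500 m from every basin -> excluded
  far <- toy_patches(list((40L - 1L) * nr + 15L), "seagrass", nr, nc)
  # col 40 is 20 cells = 200 m away; use a tighter radius to test exclusion
  resfar <- basin_pressure(far, basins, link_radius = 150)
  expect_true(resfar$basin_excluded)
  expect_equal(resfar$v_basin, 0)

  # empty basin set -> everything excluded
  nob <- drainage_basins(bc_raster(matrix(0L, nr, nc), 10))
  expect_true(all(basin_pressure(inside1, nob)$basin_excluded))
})

test_that("basin modified proportion matches a per-cell counting oracle", {
  nr <- 15
  nc <- 15
  lab <- matrix(0L, nr, nc)
  lab[, 1:10] <- 1L
  lc <- matrix("other", nr, nc)
  lc[, 11:15] <- NA # sea
  b <- drainage_basins(bc_raster(lab, 10))

  lc_all <- lc
  lc_all[, 1:10] <- "urban"
  expect_equal(basin_modified_proportion(
    b, bc_raster(lc_all, 10))$table$modified_proportion, 100)
  expect_equal(basin_modified_proportion(
    b, bc_raster(lc, 10))$table$modified_proportion, 0)

  set.seed(35)
  lc_rnd <- lc
  pick <- sample(which(lab == 1L), 40)
  lc_rnd[pick[1:25]] <- "agriculture"
  lc_rnd[pick[26:40]] <- "urban"
  got <- basin_modified_proportion(b, bc_raster(lc_rnd, 10))
  expect_equal(got$table$modified_proportion, 100 * 40 / 150)
  expect_identical(got$table$v_basin,
                   oracle_proportion_class(100 * 40 / 150))
})

test_that("cumulative index sums, bounds and the inclusive 6-12 band", {
  expect_equal(cumulative_pressure(4, 4, 4)$cumulative, 12)
  expect_true(cumulative_pressure(4, 4, 4)$high_pressure)
  expect_false(cumulative_pressure(0, 0, 0)$high_pressure)
  expect_true(cumulative_pressure(2, 2, 2)$high_pressure) # exactly 6
  expect_error(cumulative_pressure(5, 0, 0), "\\[0, 4\\]")
  expect_error(cumulative_pressure(1, -1, 0), "\\[0, 4\\]")

  set.seed(37)
  v <- matrix(runif(3 * 2000, 0, 4), ncol = 3)
  cp <- cumulative_pressure(v[, 1], v[, 2], v[, 3])
  expect_true(all(cp$cumulative >= 0 & cp$cumulative <= 12))
  expect_equal(cp$cumulative, rowSums(v))
  expect_identical(cp$high_pressure, rowSums(v) >= 6)
})

test_that("pressure is monotone in stressor proximity and basin modification", {
  # moving the stressor closer never decreases the component
  nr <- 10
  nc <- 120
  p <- toy_patches(list(5L), "open_wetland", nr, nc) # row 5, col 1
  prev <- -1L
  for (col in c(110, 60, 20, 8, 2)) {
    urb <- lmat(nr, nc)
    urb[5, col] <- TRUE
    v <- urban_pressure(p, lraster(urb))
    expect_gte(v, prev)
    prev <- v
  }
  expect_true(all(diff(classify_proportion(seq(0, 100, 5))) >= 0))
})
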