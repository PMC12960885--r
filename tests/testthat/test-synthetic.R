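# The synthetic landscape generator and its ground-truth record.

small_config <- function(seed = 1, n_field_points = 30, ...) {
  simulation_config(seed = seed, grid_width = 150, grid_height = 150,
                    n_field_points = n_field_points, ...)
}

test_that("a fixed configuration reproduces an identical scene", {
  a <- generate_landscape(small_config(5))
  b <- generate_landscape(small_config(5))
  expect_identical(a, b)
  c <- generate_landscape(small_config(6))
  expect_false(identical(a$landcover$values, c$landcover$values))
})

test_that("no sea means no coast", {
  cfg <- simulation_config(seed = 2, grid_width = 60, grid_height = 60,
                           sea_fraction = 0,
                           n_habitat_patches = c(open_wetland = 0L),
                           stressor_layout = NULL, n_basins = 1,
                           basin_modified_props = 0, n_protected = 0,
                           protected_cover_target = 0,
                           n_field_points = 0, n_lakes = 0)
  sc <- generate_landscape(cfg)
  expect_false(any(sc$sea_mask$values))
  expect_false(any(sc$truth$true_coastal_mask$values))
  expect_false(any(sc$feasibility_mask$values))
})

test_that("stressor placement honours the requested distance classes", {
  for (seed in 1:3) {
    sc <- generate_landscape(small_config(seed))
    sa <- sc$truth$stressor_assignment
    expect_gt(nrow(sa), 0)
    nr <- nrow(sc$landcover$values)
    for (k in seq_len(nrow(sa))) {
      cells <- sc$truth$patches$cells[[sa$patch[k]]]
      d <- oracle_min_dist(cells, sa$block[[k]], nr,
                           sc$landcover$cell_size)
      expect_identical(oracle_distance_class(d), sa$class[k])
      # closed-open interval of the requested class
      lo <- c(`4` = 0, `3` = 100, `2` = 400, `1` = 1000)[
        as.character(sa$class[k])]
      hi <- c(`4` = 100, `3` = 400, `2` = 1000, `1` = 5000)[
        as.character(sa$class[k])]
      expect_true(d > lo - 1e-9 && d <= hi)
    }
  }
})

test_that("an unachievable distance class raises a configuration error", {
  # class 1 needs 1000-5000 m of land; a 600 m grid cannot host it
  cfg <- simulation_config(seed = 3, grid_width = 60, grid_height = 60,
                           stressor_layout = data.frame(
                             type = "urban", class = 1L),
                           n_field_points = 0)
  expect_error(generate_landscape(cfg), "configuration error")
})

test_that("the truth record agrees with an independent per-patch oracle", {
  sc <- generate_landscape(small_config(11))
  lc <- sc$landcover$values
  nr <- nrow(lc)
  cs <- sc$landcover$cell_size
  agri <- which(!is.na(lc) & lc == "agriculture")
  urb <- which(!is.na(lc) & lc == "urban")
  lab <- sc$basins$labels$values
  # achieved basin proportions recounted from the land cover
  props <- vapply(seq_len(nrow(sc$basins$table)), function(b) {
    cells <- which(lab == b)
    100 * sum(lc[cells] %in% c("agriculture", "urban")) / length(cells)
  }, numeric(1))
  expect_equal(props, sc$truth$basin_modified_prop)
  tp <- sc$truth$patches
  for (i in seq_len(nrow(tp))) {
    va <- oracle_distance_class(oracle_min_dist(tp$cells[[i]], agri, nr, cs))
    vu <- oracle_distance_class(oracle_min_dist(tp$cells[[i]], urb, nr, cs))
    touched <- unique(lab[tp$cells[[i]]])
    touched <- touched[touched > 0]
    vb <- if (length(touched)) mean(oracle_proportion_class(props)[touched])
    else {
      d <- oracle_min_dist(tp$cells[[i]], which(lab > 0), nr, cs)
      if (d <= 500) oracle_proportion_class(props)[tp$basin[i]] else 0
    }
    expect_equal(va, tp$v_agri[i])
    expect_equal(vu, tp$v_urban[i])
    expect_equal(vb, tp$v_basin[i])
    expect_equal(tp$high_pressure[i], va + vu + vb >= 6)
  }
  # recorded fractions match the oracle recomputation exactly
  for (cl in unique(tp$habitat_class)) {
    sel <- tp$habitat_class == cl
    expect_equal(sum(tp$n_cells[sel & tp$high_pressure]) /
                   sum(tp$n_cells[sel]),
                 sc$truth$true_high_pressure_fraction[[cl]])
  }
})

test_that("scene invariants hold: shared grid, SAV inside feasibility, fractions", {
  sc <- generate_landscape(small_config(13))
  dims <- lapply(list(sc$elevation, sc$sea_mask, sc$landcover,
                      sc$sav_year_count, sc$seagrass_model,
                      sc$feasibility_mask, sc$region_labels,
                      sc$protected), dim)
  expect_true(all(vapply(dims, identical, logical(1), dims[[1]])))
  expect_true(all(sc$feasibility_mask$values[sc$sav_year_count$values > 0]))
  fr <- c(sc$truth$true_high_pressure_fraction,
          sc$truth$true_protected_fraction)
  fr <- fr[!is.na(fr)]
  expect_true(all(fr >= 0 & fr <= 1))
  # land mask and sea never intersect in the derived domain
  m <- delimit_coastal_land(sc$elevation, sc$sea_mask,
                            barriers = sc$barriers, lakes = sc$lakes)
  expect_false(any(m$values & sc$sea_mask$values))
})

test_that("field points: zero noise lands inside own-class patches; n = 0 empty", {
  sc <- generate_landscape(small_config(17, gps_noise_sd = 0))
  fp <- sc$field_points
  tc <- sc$truth$true_habitat_class$values
  nr <- nrow(tc)
  idx <- floor(fp$x / 10) * nr + floor(fp$y / 10) + 1
  expect_identical(tc[idx], fp$observed_class)

  expect_equal(nrow(generate_field_points(sc, 0)), 0L)
  expect_error(generate_field_points(sc, -1), ">= 0")
})

test_that("large GPS noise displaces some points beyond the 30 m rule", {
  sc <- generate_landscape(small_config(19, gps_noise_sd = 50,
                                        n_field_points = 60))
  mapped <- patchify(sc$truth$true_habitat_class)
  rep_ <- match_points(sc$field_points, mapped, max_dist = 30)
  expect_gt(sum(!rep_$points$verdict), 0)
  expect_lt(rep_$accuracy, 100)
})
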