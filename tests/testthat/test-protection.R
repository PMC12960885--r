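# Protected-area overlay, area accounting and the inside/outside t test.

test_that("protection split is conservative and matches a membership oracle", {
  nr <- 12
  nc <- 12
  cellsA <- c(1:6)            # column 1, rows 1-6
  cellsB <- c(49:52)          # column 5, rows 1-4
  p <- toy_patches(list(cellsA, cellsB), c("seagrass", "open_wetland"),
                   nr, nc)
  prot <- lmat(nr, nc)
  prot[, 1] <- TRUE           # covers all of A
  prot[49:50] <- TRUE         # covers half of B
  ov <- overlay_protection(p, lraster(prot))
  expect_equal(ov$protected_km2[1], 6 * 1e-4)
  expect_equal(ov$unprotected_km2[1], 0)
  expect_equal(ov$protected_km2[2], 2 * 1e-4)
  expect_equal(ov$protected_km2 + ov$unprotected_km2, p$area_km2)

  none <- overlay_protection(p, lraster(lmat(nr, nc)))
  expect_true(all(none$protected_km2 == 0))
})

test_that("area summary percentages follow the printed-table conventions", {
  nr <- 100
  nc <- 100
  land <- lmat(nr, nc)
  land[, 1:50] <- TRUE # 0.5 km2 domain
  dom <- coastal_domain(lraster(land), lraster(lmat(nr, nc)))
  cells <- 1:500 # 0.05 km2 habitat = 10% of the domain
  p <- toy_patches(list(cells), "seagrass", nr, nc)
  scores <- data.frame(patch_id = 1L, v_agri = 2L, v_urban = 2L,
                       v_basin = 2, cumulative = 6, high_pressure = TRUE,
                       basin_excluded = FALSE)
  prot <- lmat(nr, nc)
  prot[1:100] <- TRUE
  ov <- overlay_protection(p, lraster(prot))
  s <- summarize_areas(p, scores, ov, dom)
  all_row <- s[s$habitat_class == "all" & s$subbasin == "all", ]
  expect_equal(all_row$area_pct, 10L)
  expect_equal(all_row$high_pressure_pct, 100L)
  expect_equal(all_row$protected_pct, 20L)
  # every percentage is recomputable from its own area columns
  for (i in seq_len(nrow(s))) {
    if (s$total_area_km2[i] > 0) {
      expect_equal(s$high_pressure_pct[i],
                   compute_percent(s$high_pressure_km2[i],
                                   s$total_area_km2[i]))
      expect_equal(s$protected_pct[i],
                   compute_percent(s$protected_km2[i], s$total_area_km2[i]))
    }
  }
  expect_error(summarize_areas(p, scores, ov,
                               coastal_domain(lraster(lmat(2, 2)),
                                              lraster(lmat(2, 2)))),
               "zero area")
})

test_that("the pooled t test matches the closed-form oracle on fixed vectors", {
  x <- c(1.2, 2.3, 0.7, 1.9, 2.2, 1.1)   # inside protection
  y <- c(3.4, 2.9, 4.1, 3.8, 2.6, 3.3, 4.4) # outside
  n <- length(x) + length(y)
  p <- toy_patches(as.list(seq_len(n)), "seagrass", 20, 20)
  scores <- data.frame(patch_id = seq_len(n), v_agri = 0L, v_urban = 0L,
                       v_basin = 0, cumulative = c(x, y),
                       high_pressure = FALSE, basin_excluded = FALSE)
  ov <- data.frame(patch_id = seq_len(n),
                   protected_km2 = 0, unprotected_km2 = 0,
                   protected_share = rep(c(1, 0), c(length(x), length(y))))
  got <- compare_pressure_inside_outside(p, scores, ov, unit = "patch")
  exp <- oracle_pooled_t(x, y)
  expect_equal(got$t, exp$t, tolerance = 1e-10)
  expect_equal(got$df, exp$df)
  expect_equal(got$p, exp$p, tolerance = 1e-10)
  # lower mean pressure inside protection gives a negative t
  expect_lt(got$t, 0)
})

test_that("degenerate groups: identical -> t = 0; maximal separation -> tiny p", {
  n <- 8
  p <- toy_patches(as.list(seq_len(n)), "seagrass", 10, 10)
  ovr <- data.frame(patch_id = seq_len(n), protected_km2 = 0,
                    unprotected_km2 = 0,
                    protected_share = rep(c(1, 0), each = 4))
  same <- data.frame(patch_id = seq_len(n), v_agri = 0L, v_urban = 0L,
                     v_basin = 0, cumulative = 5, high_pressure = FALSE,
                     basin_excluded = FALSE)
  g0 <- compare_pressure_inside_outside(p, same, ovr, unit = "patch")
  expect_equal(g0$t, 0)
  expect_equal(g0$p, 1)

  extreme <- same
  extreme$cumulative <- rep(c(0, 12), each = 4)
  g1 <- compare_pressure_inside_outside(p, extreme, ovr, unit = "patch")
  expect_lt(g1$p, 0.001)
  expect_error(compare_pressure_inside_outside(
    p[1:3, ], same[1:3, ], ovr[1:3, ], unit = "patch"),
    "two observations")
})

test_that("stratum unit aggregates class x subbasin x protection means", {
  # two classes x two subbasins, every stratum twice with distinct values
  n <- 16
  cls <- rep(c("seagrass", "open_wetland"), each = 8)
  sb <- rep(rep(c("north", "south"), each = 4), 2)
  p <- toy_patches(as.list(seq_len(n)), cls, 20, 20, subbasins = sb)
  cum <- c(1, 3, 5, 7, 2, 4, 6, 8, 1, 1, 9, 9, 2, 2, 8, 8)
  inside <- rep(c(TRUE, TRUE, FALSE, FALSE), 4)
  scores <- data.frame(patch_id = seq_len(n), v_agri = 0L, v_urban = 0L,
                       v_basin = 0, cumulative = cum,
                       high_pressure = FALSE, basin_excluded = FALSE)
  ov <- data.frame(patch_id = seq_len(n), protected_km2 = 0,
                   unprotected_km2 = 0,
                   protected_share = as.numeric(inside))
  got <- compare_pressure_inside_outside(p, scores, ov, unit = "stratum")
  # oracle: stratum means, then pooled t
  df <- data.frame(cls, sb, inside, cum)
  agg <- aggregate(cum ~ cls + sb + inside, df, mean)
  exp <- oracle_pooled_t(agg$cum[agg$inside], agg$cum[!agg$inside])
  expect_equal(got$t, exp$t, tolerance = 1e-10)
  expect_equal(got$df, exp$df)
  expect_equal(got$n_inside, 4)
})
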