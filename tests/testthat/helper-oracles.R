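# Brute-force oracles, independent of the package's compiled primitives.

# reachability by iterative frontier dilation (4-connectivity)
oracle_reach <- function(open, seeds) {
  nr <- nrow(open)
  nc <- ncol(open)
  shift_or <- function(m) {
    up <- rbind(m[-1, , drop = FALSE], matrix(FALSE, 1, nc))
    down <- rbind(matrix(FALSE, 1, nc), m[-nr, , drop = FALSE])
    left <- cbind(m[, -1, drop = FALSE], matrix(FALSE, nr, 1))
    right <- cbind(matrix(FALSE, nr, 1), m[, -nc, drop = FALSE])
    up | down | left | right
  }
  reach <- matrix(FALSE, nr, nc)
  frontier <- seeds
  repeat {
    newr <- shift_or(frontier) & open & !reach
    if (!any(newr)) break
    reach <- reach | newr
    frontier <- newr
  }
  reach
}

# connected-component count by repeated single-seed flood fill
oracle_component_count <- function(mask) {
  left <- mask
  k <- 0L
  while (any(left)) {
    seed <- matrix(FALSE, nrow(mask), ncol(mask))
    seed[which(left)[1]] <- TRUE
    comp <- oracle_reach(left, seed) | seed
    left <- left & !comp
    k <- k + 1L
  }
  k
}

# minimum centre-to-centre distance (metres) between two cell index sets
oracle_min_dist <- function(idx_a, idx_b, nr, cs) {
  if (!length(idx_a) || !length(idx_b)) return(Inf)
  ax <- (((idx_a - 1) %/% nr)) * cs + cs / 2
  ay <- (((idx_a - 1) %% nr)) * cs + cs / 2
  bx <- (((idx_b - 1) %/% nr)) * cs + cs / 2
  by <- (((idx_b - 1) %% nr)) * cs + cs / 2
  sqrt(min(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2))
}

# interval-scan classification oracles (Table 2 conventions)
oracle_distance_class <- function(d) {
  vapply(d, function(x) {
    if (x <= 100) 4L else if (x <= 400) 3L else if (x <= 1000) 2L
    else if (x <= 5000) 1L else 0L
  }, integer(1))
}
oracle_proportion_class <- function(p) {
  vapply(p, function(x) {
    if (x >= 80) 4L else if (x >= 60) 3L else if (x >= 40) 2L
    else if (x >= 20) 1L else 0L
  }, integer(1))
}

# textbook pooled-variance two-sample t statistic and two-sided p
oracle_pooled_t <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

# build a bc_patches table directly from cell-index lists
toy_patches <- function(cells_list, classes, nr, nc, cs = 10,
                        subbasins = NA_character_) {
  cls_raster <- matrix(NA_character_, nr, nc)
  df <- data.frame(id = seq_along(cells_list),
                   habitat_class = rep_len(classes, length(cells_list)),
                   stringsAsFactors = FALSE)
  df$realm <- ifelse(df$habitat_class %in% c("open_wetland",
                                             "forested_wetland"),
                     "land", "submerged")
  df$subbasin <- rep_len(subbasins, length(cells_list))
  df$n_cells <- lengths(cells_list)
  df$area_km2 <- df$n_cells * (cs / 1000)^2
  df$cells <- cells_list
  attr(df, "grid") <- list(dim = c(as.integer(nr), as.integer(nc)),
                           cell_size = as.numeric(cs))
  class(df) <- c("bc_patches", "data.frame")
  df
}

lraster <- function(m, cs = 10) bc_raster(m, cs)

# a quick all-FALSE / all-TRUE logical matrix
lmat <- function(nr, nc, val = FALSE) matrix(val, nr, nc)

# A controlled scene family for exact ground-truth recovery: wetland-only
# patches of fixed size in two well-separated basins, pressure driven by the
# basin fill (heavily modified basin 1 vs. lightly modified basin 3, with a
# wide unmodified buffer basin between them), no request-driven stressors.
recovery_config <- function(basins_for_patches, seed = 1, gps_noise_sd = 0,
                            n_field_points = 40) {
  simulation_config(
    seed = seed,
    grid_width = 150, grid_height = 270, cell_size = 10,
    sea_fraction = 0.2,
    n_habitat_patches = c(open_wetland = length(basins_for_patches)),
    patch_size_cells = 40,
    sav_detection_prob = 1,
    stressor_layout = NULL,
    n_basins = 3,
    basin_modified_props = c(90, 0, 10),
    basin_row_weights = c(70, 110, 90),
    habitat_basin = list(open_wetland = basins_for_patches),
    n_protected = 2, protected_cover_target = 0.5,
    n_field_points = n_field_points, gps_noise_sd = gps_noise_sd,
    n_lakes = 0, road_barrier = FALSE, patch_margin_m = 30)
}
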