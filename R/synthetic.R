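# Synthetic coastal landscapes with known ground truth. The generator
# emulates the input inventory of the real analysis: a coastline separating
# sea from land, a low-elevation coastal fringe, patchy habitat mosaics of
# the four blue carbon classes, a 5-year SAV detection-count layer, a
# boolean modelled-seagrass surface, coastal drainage basins with controlled
# modified-land proportions, urban/agricultural stressor geometries placed
# at requested distance classes, protected areas, and ground-truthed field
# points with positional noise. Every derived quantity the pipeline should
# recover is recorded in a truth record at construction time.

#' Configuration for a synthetic coastal landscape
#'
#' Defaults describe a 2 km x 2 km coastal scene at the 10 m resolution of
#' the national input products, with a 300 m low-lying coastal fringe, a
#' 400 m-wide submerged mapping-feasibility strip, three drainage basins and
#' three habitat patches per class.
#'
#' @param seed Integer RNG seed; a fixed config (including seed) yields a
#'   byte-identical scene.
#' @param grid_width,grid_height Grid size in cells.
#' @param cell_size Cell edge in metres (default 10).
#' @param sea_fraction Fraction of grid columns that are sea, in `[0, 1]`.
#' @param coastal_relief Maximum inland elevation in metres.
#' @param n_habitat_patches Named integer vector of patch counts per class
#'   (names among [HABITAT_CLASSES]).
#' @param patch_size_cells Length-1 (fixed) or length-2 (range) target patch
#'   size in cells.
#' @param sav_detection_prob Per-year detection probability of a true SAV
#'   cell, in `[0, 1]`; year counts are Binomial(5, p) inside true SAV
#'   patches and 0 elsewhere.
#' @param stressor_layout Data frame (or list of pairs) with columns `type`
#'   (`urban` / `agriculture`), `class` (target distance class 0-4) and
#'   optionally `realm` (`land`, `submerged` or `any`, default `any`);
#'   entries are assigned cyclically to the habitat patches of the matching
#'   realm. NULL places no request-driven stressors. The default requests
#'   the innermost class only for land patches: stressors sit on land, so a
#'   submerged patch can only reach the 0-100 m class when it happens to hug
#'   the shoreline.
#' @param n_basins Number of coastal drainage basins (contiguous row bands
#'   covering the land).
#' @param basin_modified_props Target percent modified land per basin
#'   (recycled).
#' @param basin_row_weights Optional relative row-band heights per basin.
#' @param habitat_basin Optional named list: per class, basin ids assigned
#'   to its patches (recycled). Default assigns basins round-robin.
#' @param n_protected Maximum number of protected areas (each protects one
#'   whole habitat patch plus a one-cell halo).
#' @param protected_cover_target Fraction of total habitat area to protect.
#' @param n_field_points Number of ground-truthed field points.
#' @param gps_noise_sd Isotropic positional noise (sd, metres) on field
#'   points.
#' @param fringe_width_m Width of the low-lying (<= 2 m) coastal fringe.
#' @param feasibility_width_m Width of the submerged feasibility strip.
#' @param n_lakes Number of small lakes in the fringe.
#' @param road_barrier Place a shore-parallel road across the fringe,
#'   severing its inland half from the sea.
#' @param patch_margin_m Margin kept between patches and basin/region band
#'   boundaries.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              grid_width = 200L, grid_height = 200L,
                              cell_size = 10,
                              sea_fraction = 0.5,
                              coastal_relief = 20,
                              n_habitat_patches = c(seagrass = 3L,
                                                    other_rooted_macrophytes = 3L,
                                                    open_wetland = 3L,
                                                    forested_wetland = 3L),
                              patch_size_cells = c(20L, 60L),
                              sav_detection_prob = 0.9,
                              stressor_layout = data.frame(
                                type = c("urban", "agriculture",
                                         "urban", "agriculture"),
                                class = c(4L, 3L, 3L, 3L),
                                realm = c("land", "land",
                                          "submerged", "submerged")),
                              n_basins = 3L,
                              basin_modified_props = c(10, 30, 50),
                              basin_row_weights = NULL,
                              habitat_basin = NULL,
                              n_protected = 4L,
                              protected_cover_target = 0.3,
                              n_field_points = 60L,
                              gps_noise_sd = 5,
                              fringe_width_m = 300,
                              feasibility_width_m = 400,
                              n_lakes = 1L,
                              road_barrier = FALSE,
                              patch_margin_m = 20) {
  cfg <- list(seed = as.integer(seed), grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              cell_size = as.numeric(cell_size),
              sea_fraction = sea_fraction, coastal_relief = coastal_relief,
              n_habitat_patches = n_habitat_patches,
              patch_size_cells = patch_size_cells,
              sav_detection_prob = sav_detection_prob,
              stressor_layout = normalize_layout(stressor_layout),
              n_basins = as.integer(n_basins),
              basin_modified_props = basin_modified_props,
              basin_row_weights = basin_row_weights,
              habitat_basin = habitat_basin,
              n_protected = as.integer(n_protected),
              protected_cover_target = protected_cover_target,
              n_field_points = as.integer(n_field_points),
              gps_noise_sd = gps_noise_sd,
              fringe_width_m = fringe_width_m,
              feasibility_width_m = feasibility_width_m,
              n_lakes = as.integer(n_lakes),
              road_barrier = isTRUE(road_barrier),
              patch_margin_m = patch_margin_m)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

normalize_layout <- function(layout) {
  if (is.null(layout)) return(NULL)
  if (!is.data.frame(layout))
    layout <- do.call(rbind, lapply(layout, function(e)
      data.frame(type = as.character(e[[1]]),
                 class = as.integer(e[[2]]))))
  if (!nrow(layout)) return(NULL)
  if (!all(c("type", "class") %in% names(layout)))
    stop("stressor_layout needs columns `type` and `class`")
  if (is.null(layout$realm)) layout$realm <- "any"
  if (!all(layout$type %in% c("urban", "agriculture")))
    stop("stressor types must be `urban` or `agriculture`")
  if (!all(layout$class %in% 0:4))
    stop("target distance classes must be in 0..4")
  if (!all(layout$realm %in% c("land", "submerged", "any")))
    stop("stressor realms must be `land`, `submerged` or `any`")
  layout
}

validate_config <- function(cfg) {
  stopifnot(cfg$grid_width >= 4, cfg$grid_height >= 4, cfg$cell_size > 0)
  fr <- c(cfg$sea_fraction, cfg$sav_detection_prob,
          cfg$protected_cover_target)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (is.null(names(cfg$n_habitat_patches)) ||
      !all(names(cfg$n_habitat_patches) %in% HABITAT_CLASSES))
    stop("n_habitat_patches must be named by habitat class")
  if (any(cfg$n_habitat_patches < 0)) stop("patch counts must be >= 0")
  if (cfg$n_basins < 1) stop("need at least one basin")
  if (any(cfg$basin_modified_props < 0 | cfg$basin_modified_props > 100))
    stop("basin modified proportions must lie in [0, 100]")
  if (cfg$gps_noise_sd < 0) stop("gps_noise_sd must be >= 0")
  if (cfg$n_field_points < 0) stop("n_field_points must be >= 0")
  invisible(cfg)
}

#' Default regional classification rules for the synthetic bands
#'
#' Horizontal thirds of the grid emulate the latitudinal rule: the northern
#' band classifies all SAV as other rooted macrophytes, the middle band uses
#' overlap with the modelled seagrass surface, and the southern band
#' classifies all SAV as seagrass.
#' @return A [region_rules()] table.
#' @export
default_region_rules <- function() {
  region_rules(c("north", "middle", "south"),
               c("all_other", "model_overlap", "all_seagrass"))
}

# contiguous row bands: list of integer row vectors
split_rows <- function(nr, n, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("need one row weight per band")
  if (nr < n) stop("fewer rows than bands")
  cuts <- round(cumsum(weights) / sum(weights) * nr)
  cuts <- pmax(cuts, seq_len(n)) # every band non-empty
  for (i in seq_len(n)[-1]) cuts[i] <- max(cuts[i], cuts[i - 1] + 1L)
  cuts[n] <- nr
  lo <- c(1L, head(cuts, -1) + 1L)
  Map(function(a, b) seq.int(a, b), lo, cuts)
}

resample1 <- function(x) x[sample.int(length(x), 1L)]

# Seeded region growing: one connected blob of `target` cells inside
# `allowed & !blocked`; NULL when growth stalls.
grow_blob <- function(allowed, blocked, target, nr, nc) {
  ok <- which(allowed & !blocked)
  if (!length(ok)) return(NULL)
  seedc <- resample1(ok)
  cells <- seedc
  in_patch <- logical(nr * nc)
  in_patch[seedc] <- TRUE
  frontier <- integer(0)
  nbrs <- function(ix) {
    r <- ((ix - 1L) %% nr) + 1L
    out <- c(if (r > 1L) ix - 1L, if (r < nr) ix + 1L,
             if (ix > nr) ix - nr, if (ix <= nr * (nc - 1L)) ix + nr)
    out
  }
  add_frontier <- function(frontier, ix) {
    nb <- nbrs(ix)
    nb <- nb[allowed[nb] & !blocked[nb] & !in_patch[nb]]
    unique(c(frontier, nb))
  }
  frontier <- add_frontier(frontier, seedc)
  while (length(cells) < target && length(frontier)) {
    nxt <- resample1(frontier)
    frontier <- setdiff(frontier, nxt)
    if (in_patch[nxt]) next
    in_patch[nxt] <- TRUE
    cells <- c(cells, nxt)
    frontier <- add_frontier(frontier, nxt)
  }
  if (length(cells) < target) return(NULL)
  sort(cells)
}

# cells + their 4-neighbour halo (linear indices)
with_halo <- function(cells, nr, nc) {
  r <- ((cells - 1L) %% nr) + 1L
  out <- c(cells,
           cells[r > 1L] - 1L, cells[r < nr] + 1L,
           cells[cells > nr] - nr, cells[cells <= nr * (nc - 1L)] + nr)
  unique(out)
}

# independent construction-time lookups (deliberately not the pipeline's
# classification tables)
scan_distance_class <- function(d) {
  vapply(d, function(x) {
    if (x <= 100) 4L else if (x <= 400) 3L else if (x <= 1000) 2L
    else if (x <= 5000) 1L else 0L
  }, integer(1))
}
scan_proportion_class <- function(p) {
  vapply(p, function(x) {
    if (x >= 80) 4L else if (x >= 60) 3L else if (x >= 40) 2L
    else if (x >= 20) 1L else 0L
  }, integer(1))
}

# brute-force minimum centre-to-centre distance (metres) between cell sets
bf_min_dist <- function(idx_a, idx_b, nr, cs) {
  if (!length(idx_a) || !length(idx_b)) return(Inf)
  a <- cell_xy(idx_a, nr, cs)
  b <- cell_xy(idx_b, nr, cs)
  best <- Inf
  step <- 20000L
  for (s in seq(1L, length(idx_b), by = step)) {
    e <- min(s + step - 1L, length(idx_b))
    d2 <- outer(a$x, b$x[s:e], "-")^2 + outer(a$y, b$y[s:e], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# Place a 2x2 stressor block whose minimum centre-to-centre distance to the
# patch lies inside the requested distance-class interval, scanning columns
# within a narrow row window around the patch. Returns linear indices or
# NULL when no valid placement exists.
place_stressor_block <- function(patch_cells, free, cls, nr, nc, cs) {
  lo_hi <- switch(as.character(cls),
                  "4" = c(-1, 100), "3" = c(100, 400), "2" = c(400, 1000),
                  "1" = c(1000, 5000), "0" = c(5000, Inf))
  mid <- switch(as.character(cls),
                "4" = 50, "3" = 250, "2" = 700, "1" = 3000, "0" = 7500)
  pr <- ((patch_cells - 1L) %% nr) + 1L
  anchor_row <- round(mean(range(pr)))
  rows <- intersect(seq.int(anchor_row - 4L, anchor_row + 5L), seq_len(nr))
  p <- cell_xy(patch_cells, nr, cs)
  # distance from every window cell to the patch
  wx <- rep((seq_len(nc) - 0.5) * cs, each = length(rows))
  wy <- rep((rows - 0.5) * cs, times = nc)
  dmin <- matrix(sqrt(do.call(pmin, c(lapply(seq_along(p$x), function(k)
    (wx - p$x[k])^2 + (wy - p$y[k])^2), list(Inf)))),
    nrow = length(rows), ncol = nc)
  fwin <- free[rows, , drop = FALSE]
  nrw <- length(rows)
  if (nrw < 2L) return(NULL)
  # block candidates: top-left at window row i (i+1 exists), column j (j+1)
  bd <- pmin(dmin[-nrw, -nc], dmin[-1L, -nc], dmin[-nrw, -1L],
             dmin[-1L, -1L])
  ok <- fwin[-nrw, -nc] & fwin[-1L, -nc] & fwin[-nrw, -1L] & fwin[-1L, -1L] &
    bd > lo_hi[1] & bd <= lo_hi[2]
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  pick <- cand[which.min(abs(bd[cand] - mid))]
  i <- ((pick - 1L) %% (nrw - 1L)) + 1L
  j <- ((pick - 1L) %/% (nrw - 1L)) + 1L
  r0 <- rows[i]
  c((j - 1L) * nr + r0, (j - 1L) * nr + r0 + 1L,
    j * nr + r0, j * nr + r0 + 1L)
}

#' Generate a synthetic coastal landscape
#'
#' Builds a complete scene (all rasters on one shared grid, basins,
#' protected areas, field points) together with its ground-truth record.
#' Stressor placement honours each patch's requested distance class and
#' raises a configuration error when a request cannot be met on the grid.
#' The truth record is filled from construction bookkeeping plus a direct
#' pairwise-distance check, never by running the mapping pipeline.
#'
#' @param config A [simulation_config()].
#' @return A `bc_scene` list: `elevation`, `sea_mask`, `landcover`, `nnk`
#'   (inventory wetlands inside protected areas), `sav_year_count`,
#'   `seagrass_model`, `feasibility_mask`, `region_labels`, `rules`,
#'   `basins`, `barriers`, `lakes`, `protected`, `field_points`, `truth`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nr <- config$grid_height
  nc <- config$grid_width
  cs <- config$cell_size
  ncell <- nr * nc

  coast_col <- nc - round(nc * config$sea_fraction)
  has_sea <- coast_col < nc
  sea <- matrix(FALSE, nr, nc)
  if (has_sea) sea[, (coast_col + 1L):nc] <- TRUE

  fw <- max(1L, round(config$fringe_width_m / cs))
  fr_lo <- if (has_sea) max(1L, coast_col - fw + 1L) else NA_integer_

  # elevation: flat sea, low fringe, rising inland
  elev <- matrix(0, nr, nc)
  if (has_sea && fr_lo <= coast_col)
    elev[, fr_lo:coast_col] <- matrix(
      runif(nr * (coast_col - fr_lo + 1L), 0.2, 1.8),
      nr, coast_col - fr_lo + 1L)
  inland_cols <- seq_len(if (has_sea) fr_lo - 1L else nc)
  if (length(inland_cols)) {
    ramp <- 2.5 + (rev(seq_along(inland_cols)) / length(inland_cols)) *
      max(0, config$coastal_relief - 2.5)
    elev[, inland_cols] <- matrix(rep(ramp, each = nr), nr,
                                  length(inland_cols))
  }

  landcover <- matrix(ifelse(sea, NA_character_, "other"), nr, nc)
  barriers <- matrix(FALSE, nr, nc)
  lakes <- matrix(FALSE, nr, nc)

  # optional shore-parallel road severing the inland fringe half
  road_col <- NA_integer_
  if (config$road_barrier && has_sea) {
    road_col <- coast_col - fw %/% 2L
    if (road_col < fr_lo) stop("configuration error: fringe too narrow for road")
    barriers[, road_col] <- TRUE
    landcover[, road_col] <- "road"
  }

  # lakes: 2x2 blocks inside the sea-side fringe
  if (config$n_lakes > 0L && has_sea) {
    lk_lo <- if (is.na(road_col)) fr_lo else road_col + 1L
    for (k in seq_len(config$n_lakes)) {
      if (coast_col - lk_lo < 3L || nr < 6L) break
      r0 <- sample(2:(nr - 2L), 1L)
      c0 <- sample(lk_lo:(coast_col - 2L), 1L)
      lakes[r0:(r0 + 1L), c0:(c0 + 1L)] <- TRUE
      landcover[r0:(r0 + 1L), c0:(c0 + 1L)] <- "lake"
    }
  }

  # ground-truth coastal land: fringe reachable from sea, minus lakes
  true_coastal <- matrix(FALSE, nr, nc)
  if (has_sea) {
    reach_lo <- if (is.na(road_col)) fr_lo else road_col + 1L
    true_coastal[, reach_lo:coast_col] <- TRUE
    true_coastal[barriers | lakes] <- FALSE
  }

  # submerged feasibility strip
  feas <- matrix(FALSE, nr, nc)
  fe_w <- max(1L, round(config$feasibility_width_m / cs))
  if (has_sea)
    feas[, (coast_col + 1L):min(nc, coast_col + fe_w)] <- TRUE

  # region bands (horizontal thirds) and basin row bands
  bands <- split_rows(nr, 3L)
  region <- matrix(NA_character_, nr, nc)
  region[bands[[1]], ] <- "north"
  region[bands[[2]], ] <- "middle"
  region[bands[[3]], ] <- "south"

  basin_rows <- split_rows(nr, config$n_basins, config$basin_row_weights)
  basin_lab <- matrix(0L, nr, nc)
  if (coast_col >= 1L)
    for (b in seq_along(basin_rows))
      basin_lab[basin_rows[[b]], seq_len(coast_col)] <- b

  # habitat patches: seeded region-grown blobs, one basin band and one
  # region band each, mutually separated by a one-cell halo
  margin <- ceiling(config$patch_margin_m / cs)
  band_of_class <- list(seagrass = c("middle", "south"),
                        other_rooted_macrophytes = c("north", "middle"),
                        open_wetland = c("north", "middle", "south"),
                        forested_wetland = c("north", "middle", "south"))
  props <- rep_len(config$basin_modified_props, config$n_basins)
  blocked <- matrix(FALSE, nr, nc)
  true_class <- matrix(NA_character_, nr, nc)
  patch_list <- list()
  pid <- 0L
  for (cl in HABITAT_CLASSES) {
    n_cl <- if (cl %in% names(config$n_habitat_patches))
      config$n_habitat_patches[[cl]] else 0L
    if (n_cl == 0L) next
    basins_for <- if (!is.null(config$habitat_basin[[cl]])) {
      rep_len(config$habitat_basin[[cl]], n_cl)
    } else {
      # cycle over basins whose row band overlaps an allowed region band
      feas_b <- Filter(function(b) any(vapply(band_of_class[[cl]],
        function(tag) length(intersect(
          bands[[match(tag, c("north", "middle", "south"))]],
          basin_rows[[b]])) > 2L * margin + 3L, logical(1))),
        seq_len(config$n_basins))
      if (!length(feas_b))
        stop(sprintf("configuration error: no basin band can host %s", cl))
      rep_len(feas_b, n_cl)
    }
    for (j in seq_len(n_cl)) {
      b <- basins_for[j]
      target <- if (length(config$patch_size_cells) == 1L)
        config$patch_size_cells else
          sample(config$patch_size_cells[1]:config$patch_size_cells[2], 1L)
      placed <- NULL
      for (tag in sample(band_of_class[[cl]])) {
        rows_ok <- intersect(bands[[match(tag, c("north", "middle",
                                                 "south"))]],
                             basin_rows[[b]])
        if (length(rows_ok) > 2L * margin)
          rows_ok <- rows_ok[(margin + 1L):(length(rows_ok) - margin)]
        if (!length(rows_ok)) next
        allowed <- matrix(FALSE, nr, nc)
        if (HABITAT_REALM[[cl]] == "land") {
          allowed[rows_ok, ] <- true_coastal[rows_ok, ]
        } else {
          allowed[rows_ok, ] <- feas[rows_ok, ]
        }
        for (try in seq_len(25L)) {
          placed <- grow_blob(allowed, blocked, target, nr, nc)
          if (!is.null(placed)) break
        }
        if (!is.null(placed)) break
      }
      if (is.null(placed))
        stop(sprintf(paste0("configuration error: cannot place a %d-cell ",
                            "%s patch in basin %d"), target, cl, b))
      pid <- pid + 1L
      true_class[placed] <- cl
      if (HABITAT_REALM[[cl]] == "land") landcover[placed] <- cl
      blocked[with_halo(placed, nr, nc)] <- TRUE
      patch_list[[pid]] <- list(id = pid, habitat_class = cl, basin = b,
                                cells = placed)
    }
  }
  np <- length(patch_list)

  # request-driven stressor placement (2x2 blocks), verified exactly
  sa_rows <- list()
  sa_blocks <- list()
  if (!is.null(config$stressor_layout) && np > 0L) {
    lay <- config$stressor_layout
    realm_count <- c(land = 0L, submerged = 0L)
    for (i in seq_len(np)) {
      realm_i <- unname(HABITAT_REALM[[patch_list[[i]]$habitat_class]])
      rows_i <- which(lay$realm %in% c(realm_i, "any"))
      if (!length(rows_i)) next
      e <- lay[rows_i[(realm_count[[realm_i]] %% length(rows_i)) + 1L], ]
      realm_count[[realm_i]] <- realm_count[[realm_i]] + 1L
      free <- !sea & landcover == "other" & !blocked
      free[is.na(free)] <- FALSE
      if (e$class == 0L) {
        # absence request: verified after all placement, nothing placed
        sa_rows[[length(sa_rows) + 1L]] <- data.frame(
          patch = i, type = e$type, class = 0L, achieved_m = NA_real_)
        sa_blocks[[length(sa_rows)]] <- integer(0)
        next
      }
      block <- place_stressor_block(patch_list[[i]]$cells, free,
                                    as.integer(e$class), nr, nc, cs)
      if (is.null(block))
        stop(sprintf(paste0("configuration error: no feasible %s placement ",
                            "at distance class %d for patch %d"),
                     e$type, e$class, i))
      landcover[block] <- e$type
      d <- bf_min_dist(patch_list[[i]]$cells, block, nr, cs)
      sa_rows[[length(sa_rows) + 1L]] <- data.frame(
        patch = i, type = e$type, class = as.integer(e$class),
        achieved_m = d)
      sa_blocks[[length(sa_rows)]] <- block
    }
  }
  stressor_assign <- if (length(sa_rows)) do.call(rbind, sa_rows) else
    data.frame(patch = integer(), type = character(), class = integer(),
               achieved_m = numeric())
  stressor_assign$block <- sa_blocks

  # basin fill: paint agriculture from the inland edge until each basin
  # reaches its target modified proportion
  for (b in seq_len(config$n_basins)) {
    bc_cells <- which(basin_lab == b)
    n_b <- length(bc_cells)
    if (!n_b) next
    want <- round(props[b] / 100 * n_b)
    have <- sum(landcover[bc_cells] %in% c("agriculture", "urban"))
    if (want > have) {
      # ascending linear index = inland (low) columns first
      paintable <- bc_cells[landcover[bc_cells] == "other"]
      if (length(paintable) < want - have)
        stop("configuration error: basin modified proportion unattainable")
      landcover[paintable[seq_len(want - have)]] <- "agriculture"
    }
  }
  achieved_prop <- vapply(seq_len(config$n_basins), function(b) {
    bc_cells <- which(basin_lab == b)
    if (!length(bc_cells)) return(0)
    100 * sum(landcover[bc_cells] %in% c("agriculture", "urban")) /
      length(bc_cells)
  }, numeric(1))

  # verify the placement contract (distance to the assigned stressor block
  # in the requested class interval; absence requests against all cells of
  # the type)
  agri_cells <- which(!is.na(landcover) & landcover == "agriculture")
  urban_cells <- which(!is.na(landcover) & landcover == "urban")
  if (nrow(stressor_assign)) {
    for (k in seq_len(nrow(stressor_assign))) {
      a <- stressor_assign[k, ]
      d <- if (a$class == 0L) {
        all_of <- if (a$type == "urban") urban_cells else agri_cells
        bf_min_dist(patch_list[[a$patch]]$cells, all_of, nr, cs)
      } else a$achieved_m
      if (scan_distance_class(min(d, 1e9)) != a$class && !(a$class == 0L &&
                                                           !is.finite(d)))
        stop(sprintf(paste0("configuration error: patch %d achieved ",
                            "distance %.0f m, not class %d"),
                     a$patch, d, a$class))
      stressor_assign$achieved_m[k] <- d
    }
  }

  # SAV year counts and the modelled seagrass surface
  sav <- matrix(0L, nr, nc)
  model <- matrix(FALSE, nr, nc)
  for (p in patch_list) {
    if (HABITAT_REALM[[p$habitat_class]] != "submerged") next
    sav[p$cells] <- rbinom(length(p$cells), 5L, config$sav_detection_prob)
    if (p$habitat_class == "seagrass") {
      tags <- region[p$cells]
      model[p$cells[tags == "middle"]] <- TRUE
    }
  }

  # protected areas: whole patches (plus a one-cell halo), interleaved
  # across classes until the cover target or the polygon budget is reached
  protected <- matrix(FALSE, nr, nc)
  prot_ids <- integer(0)
  total_cells <- sum(!is.na(true_class))
  if (np > 0L && config$n_protected > 0L &&
      config$protected_cover_target > 0 && total_cells > 0L) {
    cls_of <- vapply(patch_list, function(p) p$habitat_class, character(1))
    within_idx <- stats::ave(seq_len(np), cls_of, FUN = seq_along)
    ord <- order(within_idx, match(cls_of, HABITAT_CLASSES))
    got <- 0L
    for (i in ord) {
      if (length(prot_ids) >= config$n_protected) break
      if (got / total_cells >= config$protected_cover_target) break
      prot_ids <- c(prot_ids, i)
      got <- got + length(patch_list[[i]]$cells)
      protected[with_halo(patch_list[[i]]$cells, nr, nc)] <- TRUE
    }
  }

  # inventory (vector-source) wetland layer: protected wetland patches
  nnk <- matrix(NA_character_, nr, nc)
  for (i in prot_ids) {
    p <- patch_list[[i]]
    if (HABITAT_REALM[[p$habitat_class]] == "land")
      nnk[p$cells] <- p$habitat_class
  }

  # truth pressure bookkeeping: full brute-force distances against all
  # stressor cells of each type, basin values from achieved proportions
  vb_by_basin <- scan_proportion_class(achieved_prop)
  truth_patches <- do.call(rbind, lapply(patch_list, function(p) {
    da <- bf_min_dist(p$cells, agri_cells, nr, cs)
    du <- bf_min_dist(p$cells, urban_cells, nr, cs)
    v_a <- if (is.finite(da)) scan_distance_class(da) else 0L
    v_u <- if (is.finite(du)) scan_distance_class(du) else 0L
    if (HABITAT_REALM[[p$habitat_class]] == "land") {
      v_b <- vb_by_basin[p$basin]
      excl <- FALSE
    } else {
      dsea <- bf_min_dist(p$cells, which(basin_lab > 0L), nr, cs)
      if (dsea <= 500) {
        v_b <- vb_by_basin[p$basin]
        excl <- FALSE
      } else {
        v_b <- 0
        excl <- TRUE
      }
    }
    cum <- v_a + v_u + v_b
    data.frame(id = p$id, habitat_class = p$habitat_class, basin = p$basin,
               n_cells = length(p$cells),
               dist_agri_m = da, dist_urban_m = du,
               v_agri = v_a, v_urban = v_u, v_basin = v_b,
               cumulative = cum, high_pressure = cum >= 6,
               basin_excluded = excl,
               protected = p$id %in% prot_ids,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(truth_patches))
    truth_patches$cells <- lapply(patch_list, function(p) p$cells)

  frac_by_class <- function(num, den) {
    vapply(HABITAT_CLASSES, function(cl) {
      sel <- truth_patches$habitat_class == cl
      if (!any(sel)) return(NA_real_)
      sum(num[sel]) / sum(den[sel])
    }, numeric(1))
  }
  truth <- list(
    true_coastal_mask = bc_raster(true_coastal, cs),
    true_habitat_class = bc_raster(true_class, cs),
    patches = if (is.null(truth_patches))
      data.frame() else truth_patches,
    stressor_assignment = stressor_assign,
    basin_modified_prop = achieved_prop,
    basin_v = vb_by_basin,
    true_high_pressure_fraction = if (np) frac_by_class(
      truth_patches$n_cells * truth_patches$high_pressure,
      truth_patches$n_cells) else
        setNames(rep(NA_real_, length(HABITAT_CLASSES)), HABITAT_CLASSES),
    true_protected_fraction = if (np) frac_by_class(
      truth_patches$n_cells * truth_patches$protected,
      truth_patches$n_cells) else
        setNames(rep(NA_real_, length(HABITAT_CLASSES)), HABITAT_CLASSES)
  )

  scene <- structure(list(
    config = config,
    elevation = bc_raster(elev, cs),
    sea_mask = bc_raster(sea, cs),
    landcover = bc_raster(landcover, cs),
    nnk = bc_raster(nnk, cs),
    sav_year_count = bc_raster(sav, cs),
    seagrass_model = bc_raster(model, cs),
    feasibility_mask = bc_raster(feas, cs),
    region_labels = bc_raster(region, cs),
    rules = default_region_rules(),
    basins = drainage_basins(bc_raster(basin_lab, cs)),
    barriers = bc_raster(barriers, cs),
    lakes = bc_raster(lakes, cs),
    protected = bc_raster(protected, cs),
    truth = truth
  ), class = "bc_scene")
  scene$field_points <- generate_field_points(scene, config$n_field_points,
                                              config$gps_noise_sd)
  scene
}

#' @export
print.bc_scene <- function(x, ...) {
  cat(sprintf(paste0("<bc_scene> %d x %d cells (%.0f m), %d habitat ",
                     "patches, %d basins, %d field points\n"),
              nrow(x$elevation$values), ncol(x$elevation$values),
              x$elevation$cell_size, nrow(x$truth$patches),
              nrow(x$basins$table), nrow(x$field_points)))
  invisible(x)
}

#' Generate ground-truthed field points for a scene
#'
#' Samples habitat cells uniformly, drops a point uniformly inside each
#' sampled cell (so at zero noise every point lies inside a patch of its own
#' class), then displaces it with isotropic Gaussian noise emulating GPS and
#' digitising error. Each point carries the true habitat class of its source
#' cell.
#'
#' @param scene A `bc_scene`.
#' @param n Number of points (`n = 0` gives an empty set).
#' @param gps_noise_sd Displacement sd in metres.
#' @param seed Optional seed for standalone use (the scene generator calls
#'   this with the generator's RNG stream).
#' @return A [field_points()] table with columns `x`, `y`,
#'   `observed_class`, `source`, `true_x`, `true_y`.
#' @export
generate_field_points <- function(scene, n, gps_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(scene, "bc_scene"))
  if (n < 0) stop("`n` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tc <- scene$truth$true_habitat_class$values
  cs <- scene$truth$true_habitat_class$cell_size
  nr <- nrow(tc)
  hab <- which(!is.na(tc))
  if (n > 0L && !length(hab)) stop("scene has no habitat cells")
  if (n == 0L) {
    fp <- field_points(numeric(0), numeric(0), character(0))
    fp$true_x <- numeric(0)
    fp$true_y <- numeric(0)
    return(fp)
  }
  pick <- hab[sample.int(length(hab), n, replace = TRUE)]
  cc <- cell_xy(pick, nr, cs)
  tx <- (cc$col - 1) * cs + runif(n) * cs
  ty <- (cc$row - 1) * cs + runif(n) * cs
  fp <- field_points(tx + rnorm(n, 0, gps_noise_sd),
                     ty + rnorm(n, 0, gps_noise_sd),
                     tc[pick])
  fp$true_x <- tx
  fp$true_y <- ty
  fp
}
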