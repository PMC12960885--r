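# The three-component landscape pressure index: proximity to agriculture,
# proximity to urban areas, and the modified-land proportion of the linked
# coastal drainage basin; each component on a relative 0-4 scale, summed to
# a cumulative impact value on 0-12. Values of 6 and above (50% or more of
# the maximum) mark areas of higher-level pressure.

#' Coastal drainage basins on the shared grid
#'
#' @param label_raster Integer [bc_raster]; basin id per cell (`0` outside
#'   all basins). Ids must be `1..n` for `n` basins.
#' @param modified_proportion Optional numeric vector, percent modified
#'   (agricultural + urban) land per basin; if supplied, `v_basin` is
#'   derived immediately via [classify_proportion()].
#' @return A `drainage_basins` object: the label raster plus a per-basin
#'   table (`id`, `n_cells`, `modified_proportion`, `v_basin`).
#' @export
drainage_basins <- function(label_raster, modified_proportion = NULL) {
  stopifnot(is_bc_raster(label_raster))
  v <- label_raster$values
  if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
    stop("basin labels must be non-negative integers")
  n <- max(0L, max(v))
  tab <- data.frame(id = seq_len(n),
                    n_cells = tabulate(v[v > 0L], nbins = n))
  if (any(tab$n_cells == 0L)) stop("basin ids must be contiguous 1..n")
  if (!is.null(modified_proportion)) {
    if (length(modified_proportion) != n)
      stop("need one modified proportion per basin")
    tab$modified_proportion <- as.numeric(modified_proportion)
    tab$v_basin <- classify_proportion(tab$modified_proportion)
  } else {
    tab$modified_proportion <- rep(NA_real_, n)
    tab$v_basin <- rep(NA_integer_, n)
  }
  structure(list(labels = label_raster, table = tab),
            class = "drainage_basins")
}

#' @export
print.drainage_basins <- function(x, ...) {
  cat(sprintf("<drainage_basins> %d basins\n", nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Percent modified land within each basin
#'
#' The proportion (0-100%) of a basin's area covered by agricultural plus
#' urban land-cover cells.
#'
#' @param basins A [drainage_basins()] object.
#' @param landcover Character [bc_raster] of land-cover codes.
#' @return The `drainage_basins` object with `modified_proportion` and
#'   `v_basin` filled.
#' @export
basin_modified_proportion <- function(basins, landcover) {
  stopifnot(inherits(basins, "drainage_basins"), is_bc_raster(landcover))
  check_same_grid(basins$labels, landcover)
  lab <- basins$labels$values
  if (any(basins$table$n_cells == 0L)) stop("zero-area basin")
  mod <- !is.na(landcover$values) &
    landcover$values %in% c("agriculture", "urban")
  n <- nrow(basins$table)
  nmod <- tabulate(lab[mod & lab > 0L], nbins = n)
  basins$table$modified_proportion <- 100 * nmod / basins$table$n_cells
  basins$table$v_basin <- classify_proportion(basins$table$modified_proportion)
  basins
}

# Minimum distance (metres, between cell centres) from each patch to the
# nearest TRUE cell of `mask`, via the exact Euclidean distance transform.
patch_nearest_distance <- function(patches, mask) {
  stopifnot(inherits(patches, "bc_patches"), is_bc_raster(mask))
  gi <- attr(patches, "grid")
  if (!identical(gi$dim, dim(mask$values)))
    stop("patches and stressor raster do not share one grid geometry")
  if (!any(mask$values, na.rm = TRUE))
    return(rep(Inf, nrow(patches)))
  d <- distance_to(mask)$values
  vapply(patches$cells, function(ix) min(d[ix]), numeric(1))
}

#' Proximity-to-agriculture pressure component
#'
#' Per patch, the nearest Euclidean distance from any part of the patch to
#' agricultural land, classified on the 0-4 distance scale. With no
#' agriculture anywhere the component is 0 for every patch.
#'
#' @param patches A `bc_patches` table.
#' @param agriculture Logical [bc_raster] of agricultural cells.
#' @param table A [distance_class_table()].
#' @return Integer vector `v_agri`, one value per patch.
#' @export
agricultural_pressure <- function(patches, agriculture,
                                  table = distance_class_table()) {
  classify_distance(patch_nearest_distance(patches, agriculture), table)
}

#' Proximity-to-urban pressure component
#'
#' Per patch, the value of the innermost urban buffer zone the patch
#' intersects; computed as the classified nearest distance to urban cells,
#' which is equivalent to the explicit buffer-ring construction (see
#' [urban_pressure_rings()]).
#'
#' @inheritParams agricultural_pressure
#' @param urban Logical [bc_raster] of urban cells.
#' @return Integer vector `v_urban`, one value per patch.
#' @export
urban_pressure <- function(patches, urban, table = distance_class_table()) {
  classify_distance(patch_nearest_distance(patches, urban), table)
}

#' Urban pressure via explicit buffer rings
#'
#' Independent construction of the urban component: buffer zones with the
#' table's radii are built around urban cells (a cell is inside the zone of
#' radius r if its centre lies within r of an urban cell centre, computed by
#' direct pairwise distances, not by a distance transform) and each patch
#' receives the value of the innermost zone it intersects. Used as a
#' cross-check against [urban_pressure()].
#'
#' @inheritParams urban_pressure
#' @return Integer vector `v_urban`, one value per patch.
#' @export
urban_pressure_rings <- function(patches, urban,
                                 table = distance_class_table()) {
  stopifnot(inherits(patches, "bc_patches"), is_bc_raster(urban))
  gi <- attr(patches, "grid")
  if (!identical(gi$dim, dim(urban$values)))
    stop("patches and urban raster do not share one grid geometry")
  uidx <- which(urban$values)
  out <- rep(table$beyond, nrow(patches))
  if (!length(uidx) || !nrow(patches)) return(out)
  nr <- gi$dim[1]
  u <- cell_xy(uidx, nr, gi$cell_size)
  for (i in seq_len(nrow(patches))) {
    p <- cell_xy(patches$cells[[i]], nr, gi$cell_size)
    d2min <- Inf
    for (j in seq_along(u$x)) { # pairwise, intentionally naive
      d2 <- (p$x - u$x[j])^2 + (p$y - u$y[j])^2
      m <- min(d2)
      if (m < d2min) d2min <- m
    }
    dmin <- sqrt(d2min)
    hit <- which(dmin <= table$breaks) # innermost intersected buffer zone
    out[i] <- if (length(hit)) table$values[hit[1]] else table$beyond
  }
  out
}

#' Basin-linked pressure component
#'
#' Links each patch to coastal drainage basins and assigns the basin's
#' modified-land pressure value: a patch overlapping exactly one basin gets
#' that basin's value; a patch spanning several basins gets the unweighted
#' mean of their values (kept fractional); a patch outside all basins but
#' within `link_radius` of one gets the nearest basin's value; a patch
#' farther than `link_radius` from every basin is excluded from this
#' component (`v_basin = 0`, flagged `basin_excluded`).
#'
#' @param patches A `bc_patches` table.
#' @param basins A [drainage_basins()] object with `v_basin` filled.
#' @param link_radius Maximum linking distance in metres (default 500).
#' @return Data frame with `v_basin` (numeric) and `basin_excluded`
#'   (logical), one row per patch.
#' @export
basin_pressure <- function(patches, basins, link_radius = 500) {
  stopifnot(inherits(patches, "bc_patches"),
            inherits(basins, "drainage_basins"))
  gi <- attr(patches, "grid")
  if (!identical(gi$dim, dim(basins$labels$values)))
    stop("patches and basins do not share one grid geometry")
  np <- nrow(patches)
  out <- data.frame(v_basin = numeric(np), basin_excluded = logical(np))
  if (!np) return(out)
  if (!nrow(basins$table) || all(basins$labels$values == 0L)) {
    out$basin_excluded <- TRUE
    return(out)
  }
  if (any(is.na(basins$table$v_basin)))
    stop("basins carry no v_basin; run basin_modified_proportion() first")
  lab <- basins$labels$values
  vb <- basins$table$v_basin
  nr <- gi$dim[1]
  for (i in seq_len(np)) {
    ix <- patches$cells[[i]]
    touched <- unique(lab[ix])
    touched <- touched[touched > 0L]
    if (length(touched)) {
      out$v_basin[i] <- mean(vb[touched]) # unweighted mean, kept fractional
    } else {
      cc <- cell_xy(ix, nr, gi$cell_size)
      near <- cpp_nearest_label(lab, cc$row, cc$col)
      k <- which.min(near$distance)
      dmin <- near$distance[k] * gi$cell_size
      if (dmin <= link_radius) {
        out$v_basin[i] <- vb[near$label[k]]
      } else {
        out$basin_excluded[i] <- TRUE
      }
    }
  }
  out
}

#' Cumulative impact score from the three components
#'
#' Sums the agricultural, urban and basin components into a relative
#' cumulative impact value on 0-12 and flags higher-level pressure
#' (cumulative >= 6, i.e. 50% or more of the maximum; band inclusive).
#'
#' @param v_agri,v_urban,v_basin Component values in `[0, 4]` (recycled to a
#'   common length; `v_basin` may be fractional after multi-basin
#'   averaging).
#' @param high_threshold Cumulative value at or above which a habitat counts
#'   as under higher-level pressure (default 6).
#' @return Data frame: `v_agri`, `v_urban`, `v_basin`, `cumulative`,
#'   `high_pressure`.
#' @export
cumulative_pressure <- function(v_agri, v_urban, v_basin,
                                high_threshold = 6) {
  n <- max(length(v_agri), length(v_urban), length(v_basin))
  v_agri <- rep_len(v_agri, n)
  v_urban <- rep_len(v_urban, n)
  v_basin <- rep_len(v_basin, n)
  comp <- c(v_agri, v_urban, v_basin)
  if (any(is.na(comp)) || any(comp < 0 | comp > 4))
    stop("pressure components must lie in [0, 4]")
  cum <- v_agri + v_urban + v_basin
  data.frame(v_agri = v_agri, v_urban = v_urban, v_basin = v_basin,
             cumulative = cum, high_pressure = cum >= high_threshold)
}

#' Score all patches with the full three-component pressure index
#'
#' @param patches A `bc_patches` table.
#' @param agriculture,urban Logical [bc_raster] stressor masks.
#' @param basins A [drainage_basins()] with `v_basin` filled.
#' @param link_radius Basin linking radius in metres (default 500).
#' @param table A [distance_class_table()].
#' @param high_threshold Higher-level pressure cutoff on the cumulative
#'   scale (default 6).
#' @return Data frame keyed by `patch_id` with the three components, the
#'   cumulative value, `high_pressure` and `basin_excluded`.
#' @export
pressure_scores <- function(patches, agriculture, urban, basins,
                            link_radius = 500,
                            table = distance_class_table(),
                            high_threshold = 6) {
  va <- agricultural_pressure(patches, agriculture, table)
  vu <- urban_pressure(patches, urban, table)
  vb <- basin_pressure(patches, basins, link_radius)
  out <- cumulative_pressure(va, vu, vb$v_basin, high_threshold)
  cbind(data.frame(patch_id = patches$id), out,
        data.frame(basin_excluded = vb$basin_excluded))
}
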