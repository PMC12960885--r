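# Coastal analysis domain: low-lying land hydrologically connected to the
# sea, minus lakes and road-severed enclaves, plus the submerged area where
# satellite-derived mapping was feasible.

#' Delimit low-lying coastal land connected to the sea
#'
#' Returns the mask of land cells with elevation at or below `threshold`
#' (default 2 m) that are reachable from any sea cell through a connected
#' path of such cells. Barrier cells (e.g. roads and other man-made
#' structures) block the path, so areas severed from the sea by a road are
#' excluded. Lake cells neither count as coastal land nor carry the flood
#' fill: a lake is not a marine connection, so areas connected to the sea
#' only through a lake stay excluded.
#'
#' @param elevation Numeric [bc_raster] of elevation in metres.
#' @param sea_mask Logical [bc_raster]; TRUE at sea cells.
#' @param barriers Optional logical [bc_raster] of barrier cells (roads etc.).
#' @param lakes Optional logical [bc_raster] of lake cells.
#' @param threshold Elevation threshold in metres (default 2; ties included,
#'   i.e. "2 m or less").
#' @param connectivity 4 (edge-sharing, default) or 8.
#' @return Logical [bc_raster]: the delimited coastal land mask.
#' @export
delimit_coastal_land <- function(elevation, sea_mask, barriers = NULL,
                                 lakes = NULL, threshold = 2,
                                 connectivity = 4) {
  stopifnot(is_bc_raster(elevation), is_bc_raster(sea_mask))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("`threshold` must be a single positive number")
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  check_same_grid(elevation, sea_mask, barriers, lakes)
  if (!is.logical(sea_mask$values)) stop("`sea_mask` must be logical")

  sea <- sea_mask$values
  open <- (elevation$values <= threshold) & !sea
  open[is.na(open)] <- FALSE
  if (!is.null(barriers)) {
    if (!is.logical(barriers$values)) stop("`barriers` must be logical")
    open <- open & !barriers$values
  }
  if (!is.null(lakes)) {
    if (!is.logical(lakes$values)) stop("`lakes` must be logical")
    open <- open & !lakes$values
  }
  reach <- cpp_flood_reach(open, sea, as.integer(connectivity))
  bc_raster(reach, elevation$cell_size)
}

#' Submerged analysis domain from the mapping-feasibility layer
#'
#' The submerged part of the coastal domain is the area where
#' satellite-derived mapping of submerged vegetation was feasible. This is a
#' validated pass-through of the feasibility mask.
#'
#' @param feasibility_mask Logical [bc_raster].
#' @return The validated logical [bc_raster].
#' @export
submerged_domain <- function(feasibility_mask) {
  stopifnot(is_bc_raster(feasibility_mask))
  if (!is.logical(feasibility_mask$values))
    stop("feasibility mask must be a boolean raster")
  feasibility_mask
}

#' Assemble the coastal analysis domain
#'
#' @param land_mask Logical [bc_raster] from [delimit_coastal_land()].
#' @param submerged_mask Logical [bc_raster] from [submerged_domain()].
#' @param threshold Elevation threshold (metres) used for the land side.
#' @return A `coastal_domain` with the two masks and the combined area.
#' @export
coastal_domain <- function(land_mask, submerged_mask, threshold = 2) {
  check_same_grid(land_mask, submerged_mask)
  stopifnot(is.logical(land_mask$values), is.logical(submerged_mask$values))
  structure(list(
    land_mask = land_mask,
    submerged_mask = submerged_mask,
    elevation_threshold = threshold,
    land_area_km2 = mask_area_km2(land_mask),
    submerged_area_km2 = mask_area_km2(submerged_mask),
    combined_area_km2 = mask_area_km2(land_mask) + mask_area_km2(submerged_mask)
  ), class = "coastal_domain")
}

#' @export
print.coastal_domain <- function(x, ...) {
  cat(sprintf(paste0("<coastal_domain> land %.4f km2 (<= %g m), ",
                     "submerged %.4f km2, combined %.4f km2\n"),
              x$land_area_km2, x$elevation_threshold,
              x$submerged_area_km2, x$combined_area_km2))
  invisible(x)
}

domain_mask <- function(domain) {
  bc_raster(domain$land_mask$values | domain$submerged_mask$values,
            domain$land_mask$cell_size)
}

#' Clip a layer to the coastal domain
#'
#' Restricts a raster layer or a patch set to the combined coastal domain
#' (land plus submerged). Logical rasters are set FALSE outside the domain;
#' other rasters are set NA. Patches lose cells outside the domain and are
#' dropped entirely when nothing remains. Output area never exceeds input
#' area; an empty domain yields an empty result.
#'
#' @param layer A [bc_raster] or a [bc_patches] table.
#' @param domain A [coastal_domain].
#' @return Same kind of object as `layer`.
#' @export
clip_to_domain <- function(layer, domain) {
  stopifnot(inherits(domain, "coastal_domain"))
  inside <- domain_mask(domain)$values
  if (is_bc_raster(layer)) {
    check_same_grid(layer, domain$land_mask)
    v <- layer$values
    if (is.logical(v)) v[!inside] <- FALSE else v[!inside] <- NA
    return(bc_raster(v, layer$cell_size))
  }
  if (inherits(layer, "bc_patches")) {
    gi <- attr(layer, "grid")
    if (!identical(gi$dim, dim(domain$land_mask$values)))
      stop("patches and domain do not share one grid geometry")
    kept <- lapply(layer$cells, function(ix) ix[inside[ix]])
    keep <- lengths(kept) > 0L
    out <- layer[keep, , drop = FALSE]
    out$cells <- kept[keep]
    out$n_cells <- lengths(out$cells)
    out$area_km2 <- out$n_cells * cell_area_km2(gi$cell_size)
    attr(out, "grid") <- gi
    class(out) <- class(layer)
    return(out)
  }
  stop("`layer` must be a bc_raster or bc_patches")
}
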