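# Habitat compilation: merge wetland sources, filter submerged aquatic
# vegetation (SAV) by multi-year persistence, split SAV into seagrass vs.
# other rooted macrophytes by regional rule, and patchify class rasters into
# discrete habitat units.

#' The four mapped blue carbon habitat classes
#' @export
HABITAT_CLASSES <- c("seagrass", "other_rooted_macrophytes",
                     "open_wetland", "forested_wetland")

# land vs submerged realm per class
HABITAT_REALM <- c(seagrass = "submerged",
                   other_rooted_macrophytes = "submerged",
                   open_wetland = "land",
                   forested_wetland = "land")

WETLAND_CLASSES <- c("open_wetland", "forested_wetland")
LANDCOVER_CODES <- c("open_wetland", "forested_wetland", "agriculture",
                     "urban", "lake", "road", "other")

new_bc_patches <- function(df, grid_dim, cell_size) {
  rownames(df) <- NULL
  attr(df, "grid") <- list(dim = grid_dim, cell_size = cell_size)
  class(df) <- c("bc_patches", "data.frame")
  df
}

empty_patches <- function(grid_dim, cell_size) {
  df <- data.frame(id = integer(), habitat_class = character(),
                   realm = character(), subbasin = character(),
                   n_cells = integer(), area_km2 = numeric(),
                   stringsAsFactors = FALSE)
  df$cells <- list()
  new_bc_patches(df, grid_dim, cell_size)
}

#' @export
print.bc_patches <- function(x, ...) {
  gi <- attr(x, "grid")
  cat(sprintf("<bc_patches> %d patches on a %d x %d grid (%.1f m cells)\n",
              nrow(x), gi$dim[1], gi$dim[2], gi$cell_size))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[setdiff(names(x), "cells")], 10))
  invisible(x)
}

#' Convert a labelled class raster into discrete habitat patches
#'
#' One patch per connected component per class, under the configured
#' connectivity. The sum of patch areas equals the labelled cell count times
#' the cell area exactly.
#'
#' @param class_raster Character [bc_raster]; habitat class per cell, NA
#'   where unlabelled.
#' @param connectivity 4 (default) or 8.
#' @return A `bc_patches` data frame: `id`, `habitat_class`, `realm`,
#'   `subbasin` (NA until assigned), `n_cells`, `area_km2`, and a `cells`
#'   list-column of linear cell indices into the grid.
#' @export
patchify <- function(class_raster, connectivity = 4) {
  stopifnot(is_bc_raster(class_raster))
  if (!connectivity %in% c(4, 8)) stop("`connectivity` must be 4 or 8")
  v <- class_raster$values
  if (!is.character(v)) stop("`class_raster` must carry character class labels")
  classes <- sort(unique(v[!is.na(v)]))
  rows <- list()
  for (cl in classes) {
    lab <- cpp_label(!is.na(v) & v == cl, as.integer(connectivity))
    k <- max(lab)
    if (k == 0L) next
    idx_by <- split(which(lab > 0L), lab[lab > 0L])
    rows[[cl]] <- data.frame(
      habitat_class = cl,
      realm = unname(HABITAT_REALM[cl]),
      n_cells = lengths(idx_by),
      stringsAsFactors = FALSE
    )
    rows[[cl]]$cells <- unname(idx_by)
  }
  if (!length(rows))
    return(empty_patches(dim(v), class_raster$cell_size))
  df <- do.call(rbind, rows)
  df$id <- seq_len(nrow(df))
  df$subbasin <- NA_character_
  df$area_km2 <- df$n_cells * cell_area_km2(class_raster)
  df <- df[, c("id", "habitat_class", "realm", "subbasin",
               "n_cells", "area_km2", "cells")]
  new_bc_patches(df, dim(v), class_raster$cell_size)
}

#' Merge wetland habitat layers into habitat patches
#'
#' Combines the raster land-cover wetland classes (open and forested
#' wetland) with an optional quality-controlled habitat inventory available
#' inside protected areas (a vector-type source, here rasterised onto the
#' shared grid). Where the two sources disagree on the class at a cell, the
#' inventory source wins.
#'
#' @param primary_landcover Character [bc_raster] of land-cover codes
#'   (must use codes among `open_wetland`, `forested_wetland`,
#'   `agriculture`, `urban`, `lake`, `road`, `other`).
#' @param protected_area_habitats Optional character [bc_raster] with wetland
#'   classes where the inventory maps them, NA elsewhere.
#' @param connectivity Patch connectivity, 4 (default) or 8.
#' @return A `bc_patches` table of wetland patches (land realm).
#' @export
merge_wetland_layers <- function(primary_landcover,
                                 protected_area_habitats = NULL,
                                 connectivity = 4) {
  stopifnot(is_bc_raster(primary_landcover))
  lc <- primary_landcover$values
  bad <- setdiff(unique(lc[!is.na(lc)]), LANDCOVER_CODES)
  if (length(bad))
    stop("unknown land-cover class code(s): ", paste(bad, collapse = ", "))
  cls <- matrix(NA_character_, nrow(lc), ncol(lc))
  cls[lc %in% WETLAND_CLASSES] <- lc[lc %in% WETLAND_CLASSES]
  if (!is.null(protected_area_habitats)) {
    check_same_grid(primary_landcover, protected_area_habitats)
    nn <- protected_area_habitats$values
    if (!is.character(nn)) stop("inventory layer must carry class labels")
    badn <- setdiff(unique(nn[!is.na(nn)]), WETLAND_CLASSES)
    if (length(badn))
      stop("unknown wetland class code(s): ", paste(badn, collapse = ", "))
    cls[!is.na(nn)] <- nn[!is.na(nn)] # vector-source precedence
  }
  patchify(bc_raster(cls, primary_landcover$cell_size), connectivity)
}

#' Filter submerged aquatic vegetation by multi-year persistence
#'
#' Keeps cells detected as vegetated in at least `min_years` of the 5
#' observation years (map default: 4 of 5).
#'
#' @param sav_year_count Integer [bc_raster] of per-cell detection counts
#'   (0-5).
#' @param min_years Minimum years required, 1-5 (default 4).
#' @return Logical [bc_raster]: TRUE where `count >= min_years`.
#' @export
filter_sav_persistence <- function(sav_year_count, min_years = 4) {
  stopifnot(is_bc_raster(sav_year_count))
  v <- sav_year_count$values
  if (any(is.na(v)) || any(v < 0 | v > 5) || any(v != round(v)))
    stop("SAV year counts must be integers in 0-5")
  if (!min_years %in% 1:5) stop("`min_years` must be in 1..5")
  bc_raster(v >= min_years, sav_year_count$cell_size)
}

#' Regional classification rules for submerged vegetation
#'
#' Maps each region tag to one of three rules: `model_overlap` (seagrass
#' where the modelled potential seagrass distribution overlaps the SAV
#' layer, other rooted macrophytes elsewhere), `all_seagrass` (southern and
#' west-coast regions), or `all_other` (northern regions).
#'
#' @param region_tag Character vector of region labels.
#' @param rule Character vector of rules, one per tag.
#' @return A data frame of class `region_rules`.
#' @export
region_rules <- function(region_tag, rule) {
  if (length(region_tag) != length(rule)) stop("lengths differ")
  if (anyDuplicated(region_tag)) stop("duplicated region tags")
  ok <- c("model_overlap", "all_seagrass", "all_other")
  if (!all(rule %in% ok))
    stop("rules must be among: ", paste(ok, collapse = ", "))
  structure(data.frame(region_tag = region_tag, rule = rule,
                       stringsAsFactors = FALSE),
            class = c("region_rules", "data.frame"))
}

#' Split retained SAV cells into seagrass vs. other rooted macrophytes
#'
#' Applies the per-region classification rule: under `model_overlap`, a SAV
#' cell is seagrass iff the modelled seagrass surface is TRUE there; under
#' `all_seagrass` every SAV cell is seagrass; under `all_other` every SAV
#' cell is other rooted macrophytes. Cells without SAV stay unlabelled (NA).
#'
#' @param sav_mask Logical [bc_raster] of retained SAV cells.
#' @param seagrass_model Logical [bc_raster]: modelled potential seagrass
#'   distribution.
#' @param region_labels Character [bc_raster] of region tags (total over the
#'   SAV cells).
#' @param rules A [region_rules()] table covering every tag present on a SAV
#'   cell.
#' @return Character [bc_raster] with values `seagrass` /
#'   `other_rooted_macrophytes`, NA elsewhere.
#' @export
classify_sav <- function(sav_mask, seagrass_model, region_labels, rules) {
  stopifnot(is_bc_raster(sav_mask), is_bc_raster(seagrass_model),
            is_bc_raster(region_labels), inherits(rules, "region_rules"))
  check_same_grid(sav_mask, seagrass_model, region_labels)
  sav <- sav_mask$values
  if (!is.logical(sav)) stop("`sav_mask` must be logical")
  mod <- seagrass_model$values
  tags <- region_labels$values
  need <- unique(tags[sav & !is.na(sav)])
  missing_tags <- setdiff(need, rules$region_tag)
  if (length(missing_tags) || any(is.na(need)))
    stop("missing classification rule for region tag(s): ",
         paste(missing_tags, collapse = ", "))
  rule_of <- setNames(rules$rule, rules$region_tag)
  out <- matrix(NA_character_, nrow(sav), ncol(sav))
  on <- which(sav)
  r <- rule_of[tags[on]]
  out[on[r == "all_seagrass"]] <- "seagrass"
  out[on[r == "all_other"]] <- "other_rooted_macrophytes"
  mo <- on[r == "model_overlap"]
  out[mo] <- ifelse(mod[mo], "seagrass", "other_rooted_macrophytes")
  bc_raster(out, sav_mask$cell_size)
}

#' Assign each patch to a subbasin by majority cell membership
#'
#' @param patches A `bc_patches` table.
#' @param region_labels Character [bc_raster] of subbasin / region tags.
#' @return `patches` with the `subbasin` column filled.
#' @export
assign_subbasins <- function(patches, region_labels) {
  stopifnot(inherits(patches, "bc_patches"), is_bc_raster(region_labels))
  gi <- attr(patches, "grid")
  if (!identical(gi$dim, dim(region_labels$values)))
    stop("patches and region raster do not share one grid geometry")
  tags <- region_labels$values
  patches$subbasin <- vapply(patches$cells, function(ix) {
    tb <- table(tags[ix])
    if (!length(tb)) return(NA_character_)
    names(tb)[which.max(tb)]
  }, character(1))
  patches
}
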