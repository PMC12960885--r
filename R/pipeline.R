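# End-to-end orchestration: simulate (or accept) a scene, delimit the
# coastal domain, compile habitats, score pressure, overlay protection,
# run the field-point quality control, and export plain-text tables.

#' Pipeline configuration
#'
#' Bundles the simulation settings with every numeric constant of the
#' analysis, all defaulting to the mapped study's values: 2 m elevation
#' threshold, 100/400/1000/5000 m distance classes, 20/40/60/80% proportion
#' classes, higher-level pressure cutoff 6, 500 m basin link radius, 30 m
#' quality-control radius and the 4-of-5-year SAV persistence minimum.
#'
#' @param simulation A [simulation_config()].
#' @param elevation_threshold Coastal land elevation limit, metres.
#' @param min_years SAV persistence minimum (1-5).
#' @param link_radius Basin linking radius, metres.
#' @param qc_max_dist Quality-control matching radius, metres.
#' @param high_threshold Higher-level pressure cutoff on the 0-12 scale.
#' @param distance_table A [distance_class_table()].
#' @param proportion_table A [proportion_class_table()].
#' @param connectivity Raster connectivity (4 or 8) for flood fill and
#'   patchification.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            elevation_threshold = 2,
                            min_years = 4,
                            link_radius = 500,
                            qc_max_dist = 30,
                            high_threshold = 6,
                            distance_table = distance_class_table(),
                            proportion_table = proportion_class_table(),
                            connectivity = 4) {
  structure(list(simulation = simulation,
                 elevation_threshold = elevation_threshold,
                 min_years = min_years, link_radius = link_radius,
                 qc_max_dist = qc_max_dist, high_threshold = high_threshold,
                 distance_table = distance_table,
                 proportion_table = proportion_table,
                 connectivity = connectivity),
            class = "pipeline_config")
}

# concatenate two patch tables on the same grid, renumbering ids
rbind_patches <- function(a, b) {
  gi <- attr(a, "grid")
  if (!identical(gi, attr(b, "grid")))
    stop("patch tables do not share one grid geometry")
  out <- rbind(as.data.frame(a), as.data.frame(b))
  out$id <- seq_len(nrow(out))
  new_bc_patches(out, gi$dim, gi$cell_size)
}

#' Run the full mapping and pressure pipeline
#'
#' Generates (or accepts) a synthetic scene, then: delimits the coastal
#' domain from elevation, sea, barrier and lake layers; compiles wetland
#' patches from the land-cover and inventory sources; filters SAV by
#' multi-year persistence and splits it into seagrass vs. other rooted
#' macrophytes by regional rule; patchifies and clips to the domain; scores
#' every patch with the three-component pressure index; overlays protected
#' areas; summarises areas; validates against the scene's field points; and
#' compares pressure inside vs. outside protection. Fully deterministic
#' under a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param scene Optional pre-built `bc_scene` (otherwise generated from
#'   `config$simulation`).
#' @return A `bc_pipeline_result` list: `scene`, `domain`, `patches`,
#'   `scores`, `protection`, `summary`, `qc`, `ttest` (NULL when group
#'   sizes do not allow it), `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), scene = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(scene)) scene <- generate_landscape(config$simulation)
  conn <- config$connectivity

  land <- delimit_coastal_land(scene$elevation, scene$sea_mask,
                               barriers = scene$barriers,
                               lakes = scene$lakes,
                               threshold = config$elevation_threshold,
                               connectivity = conn)
  domain <- coastal_domain(land, submerged_domain(scene$feasibility_mask),
                           config$elevation_threshold)

  wet <- merge_wetland_layers(scene$landcover, scene$nnk, conn)
  wet <- clip_to_domain(wet, domain)

  sav_mask <- filter_sav_persistence(scene$sav_year_count, config$min_years)
  sav_cls <- classify_sav(sav_mask, scene$seagrass_model,
                          scene$region_labels, scene$rules)
  sav_cls <- clip_to_domain(sav_cls, domain)
  subm <- patchify(sav_cls, conn)

  patches <- rbind_patches(wet, subm)
  patches <- assign_subbasins(patches, scene$region_labels)

  basins <- basin_modified_proportion(scene$basins, scene$landcover)
  agri <- bc_raster(!is.na(scene$landcover$values) &
                      scene$landcover$values == "agriculture",
                    scene$landcover$cell_size)
  urb <- bc_raster(!is.na(scene$landcover$values) &
                     scene$landcover$values == "urban",
                   scene$landcover$cell_size)
  scores <- pressure_scores(patches, agri, urb, basins,
                            link_radius = config$link_radius,
                            table = config$distance_table,
                            high_threshold = config$high_threshold)

  protection <- overlay_protection(patches, scene$protected)
  summary <- summarize_areas(patches, scores, protection, domain,
                             region_labels = scene$region_labels)
  qc <- if (nrow(scene$field_points))
    match_points(scene$field_points, patches,
                 max_dist = config$qc_max_dist) else NULL
  ttest <- tryCatch(
    compare_pressure_inside_outside(patches, scores, protection),
    error = function(e) NULL)

  structure(list(scene = scene, domain = domain, patches = patches,
                 scores = scores, protection = protection,
                 summary = summary, qc = qc, ttest = ttest,
                 provenance = list(
                   seed = config$simulation$seed,
                   constants = config[setdiff(names(config),
                                              c("simulation"))],
                   package_version =
                     as.character(utils::packageVersion("coastbc")))),
            class = "bc_pipeline_result")
}

#' @export
print.bc_pipeline_result <- function(x, ...) {
  cat("Blue carbon mapping pipeline result\n")
  print(x$domain)
  cat(sprintf("  %d habitat patches\n", nrow(x$patches)))
  all_row <- x$summary[x$summary$habitat_class == "all" &
                         x$summary$subbasin == "all", ]
  cat(sprintf(paste0("  total habitat %.4f km2 (%d%% of coastal area); ",
                     "%d%% under higher-level pressure; %d%% protected\n"),
              all_row$total_area_km2, all_row$area_pct,
              all_row$high_pressure_pct, all_row$protected_pct))
  if (!is.null(x$qc))
    cat(sprintf("  field-point accuracy %.1f%% (%d of %d)\n",
                x$qc$accuracy, x$qc$n_correct, x$qc$n))
  if (!is.null(x$ttest))
    cat(sprintf("  pressure inside vs outside protection: t = %.3f, df = %d, p = %.4g\n",
                x$ttest$t, x$ttest$df, x$ttest$p))
  invisible(x)
}

#' Write pipeline outputs as plain-text tables
#'
#' Exports the patch table (with scores and protection split), the area
#' summary, the per-point quality-control table and the t-test result as
#' CSV files, plus a provenance record. Re-running an identical
#' configuration reproduces byte-identical files.
#'
#' @param result A `bc_pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "bc_pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  pt <- as.data.frame(result$patches)
  pt$cells <- NULL
  pt <- merge(merge(pt, result$scores, by.x = "id", by.y = "patch_id"),
              result$protection, by.x = "id", by.y = "patch_id")
  w(pt, "patches.csv")
  w(as.data.frame(result$summary), "area_summary.csv")
  if (!is.null(result$qc)) {
    w(result$qc$points, "qc_points.csv")
    w(result$qc$by_class, "qc_by_class.csv")
  }
  if (!is.null(result$ttest))
    w(data.frame(t = result$ttest$t, df = result$ttest$df,
                 p = result$ttest$p, unit = result$ttest$unit),
      "ttest.csv")
  prov <- result$provenance
  writeLines(c(sprintf("seed: %d", prov$seed),
               sprintf("package_version: %s", prov$package_version)),
             file.path(dir, "provenance.txt"))
  paths <- c(paths, file.path(dir, "provenance.txt"))
  invisible(paths)
}
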