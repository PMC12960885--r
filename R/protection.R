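# Protected-area overlap: per-patch protected/unprotected area split, the
# area-accounting summary (per habitat class and subbasin), and the
# inside-vs-outside comparison of cumulative pressure.

#' Split each patch's area by protected-area membership
#'
#' @param patches A `bc_patches` table.
#' @param protected Logical [bc_raster]: TRUE inside protected areas.
#' @return Data frame: `patch_id`, `protected_km2`, `unprotected_km2`,
#'   `protected_share` (fraction of patch area protected). The two areas sum
#'   to the patch area exactly at cell resolution.
#' @export
overlay_protection <- function(patches, protected) {
  stopifnot(inherits(patches, "bc_patches"), is_bc_raster(protected))
  gi <- attr(patches, "grid")
  if (!identical(gi$dim, dim(protected$values)))
    stop("patches and protected raster do not share one grid geometry")
  if (!is.logical(protected$values)) stop("`protected` must be logical")
  pv <- protected$values
  ca <- cell_area_km2(gi$cell_size)
  npro <- vapply(patches$cells, function(ix) sum(pv[ix]), integer(1))
  data.frame(patch_id = patches$id,
             protected_km2 = npro * ca,
             unprotected_km2 = (patches$n_cells - npro) * ca,
             protected_share = ifelse(patches$n_cells > 0,
                                      npro / patches$n_cells, 0))
}

#' Area accounting per habitat class and subbasin
#'
#' Produces the per-class/per-subbasin table of total habitat area, areal
#' cover relative to the delimited coastal area, area under higher-level
#' pressure, and protected-area overlap. `"all"` rows aggregate over classes
#' and/or subbasins. Percentages follow the printed-table conventions:
#' `area_pct` is relative to the coastal domain (restricted to the row's
#' subbasin when `region_labels` is given); `high_pressure_pct` and
#' `protected_pct` are relative to the row's own habitat area; all are
#' rounded to the nearest integer (half away from zero). Unrounded fractions
#' are kept alongside.
#'
#' @param patches A `bc_patches` table (with `subbasin` filled if subbasin
#'   rows are wanted).
#' @param scores Output of [pressure_scores()].
#' @param protection Output of [overlay_protection()].
#' @param domain A [coastal_domain()].
#' @param region_labels Optional character [bc_raster] of subbasin tags,
#'   used to compute per-subbasin coastal areas.
#' @return A data frame of class `area_summary`.
#' @export
summarize_areas <- function(patches, scores, protection, domain,
                            region_labels = NULL) {
  stopifnot(inherits(patches, "bc_patches"),
            inherits(domain, "coastal_domain"))
  if (domain$combined_area_km2 <= 0) stop("coastal domain has zero area")
  if (!identical(sort(patches$id), sort(scores$patch_id)) ||
      !identical(sort(patches$id), sort(protection$patch_id)))
    stop("every patch needs a pressure score and a protection split")
  df <- merge(merge(as.data.frame(patches)[
    c("id", "habitat_class", "subbasin", "area_km2")],
    scores, by.x = "id", by.y = "patch_id"),
    protection, by.x = "id", by.y = "patch_id")
  df$hp_km2 <- ifelse(df$high_pressure, df$area_km2, 0)

  dom_area <- function(sb) {
    if (sb == "all" || is.null(region_labels))
      return(domain$combined_area_km2)
    inside <- domain_mask(domain)$values & region_labels$values == sb
    sum(inside, na.rm = TRUE) * cell_area_km2(domain$land_mask)
  }
  classes <- c(sort(unique(df$habitat_class)), "all")
  subbasins <- if (all(is.na(df$subbasin))) "all" else
    c(sort(unique(df$subbasin)), "all")
  rows <- list()
  for (sb in subbasins) {
    for (cl in classes) {
      sel <- (cl == "all" | df$habitat_class == cl) &
        (sb == "all" | (!is.na(df$subbasin) & df$subbasin == sb))
      tot <- sum(df$area_km2[sel])
      hp <- sum(df$hp_km2[sel])
      pr <- sum(df$protected_km2[sel])
      da <- dom_area(sb)
      rows[[length(rows) + 1L]] <- data.frame(
        habitat_class = cl, subbasin = sb,
        total_area_km2 = tot,
        coastal_area_km2 = da,
        area_pct = if (da > 0) compute_percent(tot, da) else NA_integer_,
        high_pressure_km2 = hp,
        high_pressure_frac = if (tot > 0) hp / tot else NA_real_,
        high_pressure_pct = if (tot > 0) compute_percent(hp, tot)
                            else NA_integer_,
        protected_km2 = pr,
        protected_frac = if (tot > 0) pr / tot else NA_real_,
        protected_pct = if (tot > 0) compute_percent(pr, tot)
                        else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("area_summary", "data.frame")
  out
}

#' Compare cumulative pressure inside vs. outside protected areas
#'
#' Classical two-sample Student's t test (pooled variance, two-sided) on
#' cumulative pressure, with protected habitats as the first group so that
#' lower pressure inside protection yields a negative t. A patch counts as
#' "inside" when more than half of its area is protected. With
#' `unit = "stratum"` (default) the sampling unit is the mean cumulative
#' pressure per habitat-class x subbasin x protection cell; with
#' `unit = "patch"` every patch is an observation. Identical groups (zero
#' pooled variance, equal means) give `t = 0`, `p = 1`.
#'
#' @param patches A `bc_patches` table.
#' @param scores Output of [pressure_scores()].
#' @param protection Output of [overlay_protection()].
#' @param unit `"stratum"` or `"patch"`.
#' @return A list of class `bc_ttest`: `t`, `df`, `p`, `unit`,
#'   `mean_inside`, `mean_outside`, `n_inside`, `n_outside`.
#' @export
compare_pressure_inside_outside <- function(patches, scores, protection,
                                            unit = c("stratum", "patch")) {
  unit <- match.arg(unit)
  df <- merge(merge(as.data.frame(patches)[
    c("id", "habitat_class", "subbasin")],
    scores, by.x = "id", by.y = "patch_id"),
    protection, by.x = "id", by.y = "patch_id")
  df$inside <- df$protected_share > 0.5
  if (unit == "stratum") {
    agg <- stats::aggregate(cumulative ~ habitat_class + subbasin + inside,
                            data = df, FUN = mean)
    x <- agg$cumulative[agg$inside]   # inside first: lower pressure => t < 0
    y <- agg$cumulative[!agg$inside]
  } else {
    x <- df$cumulative[df$inside]
    y <- df$cumulative[!df$inside]
  }
  if (length(x) < 2 || length(y) < 2)
    stop("need at least two observations per group")
  res <- if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      list(statistic = 0, parameter = length(x) + length(y) - 2, p.value = 1)
    } else {
      list(statistic = sign(mean(x) - mean(y)) * Inf,
           parameter = length(x) + length(y) - 2, p.value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
         p.value = tt$p.value)
  }
  structure(list(t = res$statistic, df = res$parameter, p = res$p.value,
                 unit = unit,
                 mean_inside = mean(x), mean_outside = mean(y),
                 n_inside = length(x), n_outside = length(y)),
            class = "bc_ttest")
}

#' @export
print.bc_ttest <- function(x, ...) {
  cat(sprintf(paste0("Student's t test (pooled variance), unit = %s:\n",
                     "  df = %d, t = %.3f, p = %.4g\n",
                     "  mean inside protection = %.3f (n = %d), ",
                     "outside = %.3f (n = %d)\n"),
              x$unit, x$df, x$t, x$p,
              x$mean_inside, x$n_inside, x$mean_outside, x$n_outside))
  invisible(x)
}
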