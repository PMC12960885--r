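# Quality control: validate a compiled habitat map against ground-truthed
# field points with the 30 m rule, and select the SAV persistence threshold
# by agreement with reference presence/absence points.

#' Field survey points
#'
#' @param x,y Planar coordinates in metres.
#' @param observed_class Habitat class observed in the field at each point.
#' @param source Optional provenance label.
#' @return A data frame of class `field_points`.
#' @export
field_points <- function(x, y, observed_class, source = "field") {
  if (length(observed_class) == 1L && length(x) > 1L)
    observed_class <- rep(observed_class, length(x))
  if (length(x) != length(y) || length(x) != length(observed_class))
    stop("x, y and observed_class must have equal length")
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  structure(data.frame(x = as.numeric(x), y = as.numeric(y),
                       observed_class = as.character(observed_class),
                       source = rep_len(source, length(x)),
                       stringsAsFactors = FALSE),
            class = c("field_points", "data.frame"))
}

# Distance (metres) from a point to the nearest cell *square* of a patch:
# zero when the point lies inside a patch cell, else Euclidean distance to
# the closest cell boundary. Vectorised over patch cells.
point_patch_distance <- function(px, py, cells, nr, cell_size) {
  cc <- cell_xy(cells, nr, cell_size)
  dx <- pmax(0, abs(px - cc$x) - cell_size / 2)
  dy <- pmax(0, abs(py - cc$y) - cell_size / 2)
  min(sqrt(dx^2 + dy^2))
}

#' Validate a habitat map against field points (the 30 m rule)
#'
#' A point is correctly mapped when a patch of its observed class lies
#' within `max_dist` metres (boundary distance, inclusive at exactly
#' `max_dist`); farther than that it is classified as incorrect. With
#' `class_aware = FALSE` the nearest patch of any class is matched instead
#' and the verdict additionally requires the class to agree (sensitivity
#' mode).
#'
#' @param points A [field_points()] table.
#' @param patches A `bc_patches` table.
#' @param max_dist Accepted error radius in metres (default 30, covering
#'   GPS and map uncertainty).
#' @param class_aware Match distance to the nearest patch of the observed
#'   class (default TRUE).
#' @return A list of class `qc_report`: per-point table (`distance`,
#'   `matched_patch`, `verdict`), per-class accuracy table, overall `n`,
#'   `n_correct` and `accuracy` (percent).
#' @export
match_points <- function(points, patches, max_dist = 30, class_aware = TRUE) {
  stopifnot(inherits(patches, "bc_patches"))
  if (max_dist < 0) stop("`max_dist` must be non-negative")
  gi <- attr(patches, "grid")
  n <- nrow(points)
  per <- data.frame(distance = numeric(n), matched_patch = integer(n),
                    verdict = logical(n))
  for (i in seq_len(n)) {
    cand <- if (class_aware)
      which(patches$habitat_class == points$observed_class[i])
    else seq_len(nrow(patches))
    if (!length(cand)) {
      per$distance[i] <- Inf
      per$matched_patch[i] <- NA_integer_
      per$verdict[i] <- FALSE
      next
    }
    dists <- vapply(cand, function(j)
      point_patch_distance(points$x[i], points$y[i], patches$cells[[j]],
                           gi$dim[1], gi$cell_size), numeric(1))
    k <- which.min(dists)
    ok <- dists[k] <= max_dist
    if (!class_aware && ok)
      ok <- patches$habitat_class[cand[k]] == points$observed_class[i]
    per$distance[i] <- dists[k]
    per$matched_patch[i] <- patches$id[cand[k]]
    per$verdict[i] <- ok
  }
  cls <- sort(unique(points$observed_class))
  by_class <- do.call(rbind, lapply(cls, function(cl) {
    sel <- points$observed_class == cl
    data.frame(habitat_class = cl, n_points = sum(sel),
               n_correct = sum(per$verdict[sel]),
               accuracy = 100 * sum(per$verdict[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    points = cbind(as.data.frame(points), per),
    by_class = if (is.null(by_class))
      data.frame(habitat_class = character(), n_points = integer(),
                 n_correct = integer(), accuracy = numeric())
      else by_class,
    n = n, n_correct = sum(per$verdict),
    accuracy = if (n > 0) 100 * sum(per$verdict) / n else NA_real_,
    max_dist = max_dist
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d of %d points correctly mapped (%.1f%%) at %g m\n",
              x$n_correct, x$n, x$accuracy, x$max_dist))
  if (nrow(x$by_class)) print(x$by_class)
  invisible(x)
}

#' Select the SAV persistence threshold against reference points
#'
#' For each candidate threshold k, the mask of cells detected in >= k of the
#' 5 years is compared with reference presence/absence points; agreement is
#' balanced accuracy (mean of sensitivity and specificity, so an empty or
#' all-covering mask scores 0.5). The best threshold maximises agreement,
#' ties resolved towards the larger (stricter) k.
#'
#' @param sav_year_count Integer [bc_raster] of 0-5 detection counts.
#' @param reference_points Data frame with `x`, `y` (metres) and `present`
#'   (logical ground truth). Must contain both classes.
#' @param candidate_k Candidate thresholds (default 1:5).
#' @return List: `best_k` and `agreement` (data frame of k, sensitivity,
#'   specificity, balanced accuracy).
#' @export
select_persistence_threshold <- function(sav_year_count, reference_points,
                                         candidate_k = 1:5) {
  stopifnot(is_bc_raster(sav_year_count))
  if (!all(c("x", "y", "present") %in% names(reference_points)))
    stop("reference points need columns x, y, present")
  pres <- as.logical(reference_points$present)
  if (all(pres) || all(!pres))
    stop("reference points must include both presence and absence")
  nr <- nrow(sav_year_count$values)
  nc <- ncol(sav_year_count$values)
  idx <- point_cell(reference_points$x, reference_points$y, nr, nc,
                    sav_year_count$cell_size)
  if (any(is.na(idx))) stop("reference points outside the grid")
  counts <- sav_year_count$values[idx]
  tab <- do.call(rbind, lapply(sort(candidate_k), function(k) {
    pred <- counts >= k
    sens <- if (any(pres)) mean(pred[pres]) else NA_real_
    spec <- if (any(!pres)) mean(!pred[!pres]) else NA_real_
    data.frame(k = k, sensitivity = sens, specificity = spec,
               balanced_accuracy = (sens + spec) / 2)
  }))
  best <- tab$k[max(which(tab$balanced_accuracy ==
                            max(tab$balanced_accuracy)))]
  list(best_k = best, agreement = tab)
}
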