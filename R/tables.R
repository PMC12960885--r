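# The two classification tables behind the landscape pressure index: a
# distance table for the two proximity maps (agriculture, urban) and a
# proportion table for the basin modified-land map. Both assign a relative
# pressure value on a 0-4 scale.

#' Distance classification table for the proximity pressure maps
#'
#' Distances (metres) to the nearest stressor are classed into relative
#' pressure values: `d <= 100 -> 4`, `100 < d <= 400 -> 3`,
#' `400 < d <= 1000 -> 2`, `1000 < d <= 5000 -> 1`, `d > 5000 -> 0`.
#' Intervals are closed on the upper end.
#'
#' @param breaks Strictly increasing distance breaks in metres.
#' @param values Strictly decreasing pressure values, one per break.
#' @param beyond Value beyond the last break.
#' @return A `distance_class_table`.
#' @export
distance_class_table <- function(breaks = c(100, 400, 1000, 5000),
                                 values = c(4L, 3L, 2L, 1L),
                                 beyond = 0L) {
  if (length(breaks) != length(values))
    stop("`breaks` and `values` must have equal length")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (any(diff(values) >= 0)) stop("`values` must be strictly decreasing")
  structure(list(breaks = as.numeric(breaks), values = as.integer(values),
                 beyond = as.integer(beyond)),
            class = "distance_class_table")
}

#' Proportion classification table for the basin pressure map
#'
#' Percent modified land (agricultural + urban) in a coastal drainage basin
#' is classed into relative pressure values: `p >= 80 -> 4`,
#' `60 <= p < 80 -> 3`, `40 <= p < 60 -> 2`, `20 <= p < 40 -> 1`,
#' `p < 20 -> 0`. Intervals are closed on the lower end.
#'
#' @param breaks Strictly increasing percentage breaks.
#' @param values Pressure value at/above each break.
#' @param below Value below the first break.
#' @return A `proportion_class_table`.
#' @export
proportion_class_table <- function(breaks = c(20, 40, 60, 80),
                                   values = c(1L, 2L, 3L, 4L),
                                   below = 0L) {
  if (length(breaks) != length(values))
    stop("`breaks` and `values` must have equal length")
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (any(diff(values) <= 0)) stop("`values` must be strictly increasing")
  structure(list(breaks = as.numeric(breaks), values = as.integer(values),
                 below = as.integer(below)),
            class = "proportion_class_table")
}

#' Classify a distance into a relative pressure value
#'
#' @param d Distances in metres (vectorised); must be non-negative
#'   (`Inf` allowed, meaning no stressor anywhere).
#' @param table A [distance_class_table()].
#' @return Integer pressure values on the table's scale (default 0-4).
#' @examples
#' classify_distance(c(0, 100, 101, 5000, 6000))
#' @export
classify_distance <- function(d, table = distance_class_table()) {
  if (!inherits(table, "distance_class_table"))
    stop("`table` must be a distance_class_table")
  if (any(is.na(d)) || any(d < 0)) stop("distances must be non-negative")
  vals <- c(table$values, table$beyond)
  idx <- findInterval(d, table$breaks, left.open = TRUE)
  vals[idx + 1L]
}

#' Classify a modified-land proportion into a relative pressure value
#'
#' @param p Percentages in `[0, 100]` (vectorised).
#' @param table A [proportion_class_table()].
#' @return Integer pressure values on the table's scale (default 0-4).
#' @examples
#' classify_proportion(c(10, 20, 39.9, 40, 90))
#' @export
classify_proportion <- function(p, table = proportion_class_table()) {
  if (!inherits(table, "proportion_class_table"))
    stop("`table` must be a proportion_class_table")
  if (any(is.na(p)) || any(p < 0 | p > 100))
    stop("proportions must lie in [0, 100]")
  vals <- c(table$below, table$values)
  idx <- findInterval(p, table$breaks)
  vals[idx + 1L]
}

#' Integer percentage, rounded half away from zero
#'
#' Percent cover as printed in the area-accounting tables:
#' `round(100 * part / whole)` with halves rounded away from zero.
#'
#' @param part,whole Areas in the same unit (typically km^2); `whole > 0`.
#' @return Integer percent.
#' @examples
#' compute_percent(1851, 5267) # 35
#' @export
compute_percent <- function(part, whole) {
  if (any(whole <= 0)) stop("`whole` must be positive")
  if (any(part < 0)) stop("`part` must be non-negative")
  x <- 100 * part / whole
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
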