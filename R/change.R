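#' Per-class area tabulation of a classified map
#'
#' `area_c = count_c * pixel_size^2 / 1e6` square kilometres. Declared
#' classes absent from the map are reported with zero area.
#'
#' @param labels integer class map (matrix, classes `1..M`).
#' @param pixel_size metres per pixel edge (> 0).
#' @param class_names optional class legend (also fixes the class count).
#' @param date_tag free-text date label attached to the table.
#' @return tibble with columns `class_id`, `class`, `pixels`, `area_km2`,
#'   `date_tag`.
#' @examples
#' class_areas(matrix(c(1, 1, 2, 2), 2), pixel_size = 10)
#' @export
class_areas <- function(labels, pixel_size, class_names = NULL,
                        date_tag = "") {
  if (length(labels) == 0L) stop_dynspec("empty class map")
  if (pixel_size <= 0) stop_dynspec("`pixel_size` must be > 0")
  m <- max(length(class_names), max(labels))
  counts <- tabulate(as.vector(labels), nbins = m)
  tibble::tibble(
    class_id = seq_len(m),
    class = class_names %||% sprintf("class_%d", seq_len(m)),
    pixels = counts,
    area_km2 = counts * pixel_size^2 / 1e6,
    date_tag = date_tag)
}

#' Relative area change rate
#'
#' `(a2 - a1) / a1 * 100` percent, reported to two decimals by the table
#' writers (raw values are returned here). A zero baseline is flagged as
#' `NA` with a warning rather than an error.
#'
#' @param a1,a2 areas (same units) at the earlier and later date;
#'   vectorised.
#' @return percent change (numeric vector, `NA` where `a1 == 0`).
#' @examples
#' change_rate(908.91, 1225.16)  # 34.79
#' @export
change_rate <- function(a1, a2) {
  out <- ifelse(a1 > 0, (a2 - a1) / a1 * 100, NA_real_)
  if (any(a1 == 0)) warning("change rate undefined where baseline area is 0")
  out
}

#' Change report between two classified dates
#'
#' @param areas1,areas2 area tables from [class_areas()] (same classes).
#' @return tibble with per-class `area_1`, `area_2` (km2) and
#'   `change_rate` (%, rounded to 2 decimals; raw value in
#'   `change_rate_raw`).
#' @export
change_report <- function(areas1, areas2) {
  stopifnot(identical(areas1$class, areas2$class))
  raw <- suppressWarnings(change_rate(areas1$area_km2, areas2$area_km2))
  tibble::tibble(
    class_id = areas1$class_id, class = areas1$class,
    area_1 = areas1$area_km2, area_2 = areas2$area_km2,
    date_1 = areas1$date_tag, date_2 = areas2$date_tag,
    change_rate = round(raw, 2), change_rate_raw = raw)
}

#' Class-transition matrix between two classified maps
#'
#' `counts[c1, c2]` is the number of pixels labelled `c1` at date 1 and
#' `c2` at date 2; row sums equal the date-1 class counts.
#'
#' @param map1,map2 integer label matrices of identical shape.
#' @param n_classes class count `M`; defaults to the maximum label.
#' @param class_names optional dimnames.
#' @return `M x M` integer matrix of class `transition_matrix`, with a
#'   `change_mask` attribute (logical matrix marking pixels whose class
#'   changed).
#' @export
transition_matrix <- function(map1, map2, n_classes = NULL,
                              class_names = NULL) {
  if (!identical(dim(map1), dim(map2))) {
    stop_dynspec("maps differ in shape")
  }
  m <- n_classes %||% max(map1, map2)
  v1 <- as.vector(map1); v2 <- as.vector(map2)
  if (any(v1 < 1L | v1 > m | v2 < 1L | v2 > m)) {
    stop_dynspec("labels outside 1..", m)
  }
  tm <- unclass(table(factor(v1, levels = seq_len(m)),
                      factor(v2, levels = seq_len(m))))
  tm <- matrix(as.integer(tm), m, m)
  nm <- class_names %||% sprintf("class_%d", seq_len(m))
  dimnames(tm) <- list(date_1 = nm, date_2 = nm)
  attr(tm, "change_mask") <- matrix(v1 != v2, nrow(map1), ncol(map1))
  class(tm) <- c("transition_matrix", class(tm))
  tm
}
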