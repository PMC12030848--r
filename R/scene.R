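#' Multiband reflectance scene
#'
#' A `scene` bundles a band-major reflectance array with the pixel size and
#' band labels of the acquisition. Values are unitless surface reflectances;
#' the array is indexed `(band, row, col)` with row 1 the top image line.
#'
#' @param values numeric array of dimension `(bands, height, width)`, all
#'   values finite.
#' @param pixel_size edge length of a pixel in metres (> 0).
#' @param band_names optional character vector of band labels, one per band
#'   (defaults to `band_01`, `band_02`, ...).
#' @param date_tag free-text acquisition label (e.g. `"2019-12-12"`).
#' @param metadata opaque list preserved on write/read round trips
#'   (e.g. georeferencing carried along from an external source).
#'
#' @return An object of class `scene`.
#' @examples
#' sc <- scene(array(runif(4 * 8 * 8), c(4, 8, 8)), pixel_size = 10)
#' n_bands(sc)
#' @export
scene <- function(values, pixel_size = 1, band_names = NULL, date_tag = "",
                  metadata = list()) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_dynspec("`values` must be a 3-d array indexed (band, row, col)")
  }
  d <- dim(values)
  if (any(d < 1L)) stop_dynspec("all scene dimensions must be >= 1")
  if (!all(is.finite(values))) stop_dynspec("scene values must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop_dynspec("`pixel_size` must be a single positive number")
  }
  if (is.null(band_names)) {
    band_names <- sprintf("band_%02d", seq_len(d[1]))
  }
  if (length(band_names) != d[1]) {
    stop_dynspec("`band_names` must have one entry per band (", d[1], ")")
  }
  structure(
    list(values = values, pixel_size = pixel_size,
         band_names = as.character(band_names),
         date_tag = as.character(date_tag), metadata = metadata),
    class = "scene"
  )
}

#' @rdname scene
#' @param x a `scene`.
#' @export
n_bands <- function(x) dim(x$values)[1]

#' @export
dim.scene <- function(x) dim(x$values)

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scene> %d band(s), %d x %d px, pixel size %g m%s\n",
              d[1], d[2], d[3], x$pixel_size,
              if (nzchar(x$date_tag)) paste0(", ", x$date_tag) else ""))
  cat("bands:", paste(x$band_names, collapse = ", "), "\n")
  invisible(x)
}
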