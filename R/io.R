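#' Read and write multiband scenes
#'
#' Two on-disk containers are supported. `"rds"` serialises the full `scene`
#' object and round-trips values bit-exactly. `"tiff"` writes one 32-bit
#' float page per band; because float TIFF storage is only defined on
#' \[0, 1\], values are mapped through a recorded affine transform
#' (stored, with `pixel_size`, `band_names`, `date_tag` and any opaque
#' metadata, in a JSON sidecar `<path>.aux.json`), so values round-trip to
#' within float32 quantisation.
#'
#' @param x a [scene()].
#' @param path file path; the format is inferred from the extension
#'   (`.rds` or `.tif`/`.tiff`) when `format` is `NULL`.
#' @param format `"rds"` or `"tiff"`.
#' @return `read_scene()` returns a [scene()]; `write_scene()` returns
#'   `path` invisibly.
#' @examples
#' sc <- scene(array(runif(4 * 6 * 5), c(4, 6, 5)), pixel_size = 10)
#' p <- tempfile(fileext = ".rds")
#' write_scene(sc, p)
#' identical(read_scene(p)$values, sc$values)
#' @export
write_scene <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "scene"))
  format <- format %||% infer_format(path)
  if (format == "rds") {
    saveRDS(x, path)
  } else if (format == "tiff") {
    v <- x$values
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(v)[1]), function(b) (v[b, , , drop = TRUE] - lo) / scale)
    pages <- lapply(pages, function(m) matrix(m, dim(v)[2], dim(v)[3]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
    aux <- list(pixel_size = x$pixel_size, band_names = x$band_names,
                date_tag = x$date_tag, offset = lo, scale = scale,
                metadata = x$metadata)
    jsonlite::write_json(aux, paste0(path, ".aux.json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    stop_dynspec("unknown scene format: ", format)
  }
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path, format = NULL) {
  if (!file.exists(path)) stop_dynspec("scene file not found: ", path)
  format <- format %||% infer_format(path)
  if (format == "rds") {
    x <- tryCatch(readRDS(path), error = function(e) {
      stop_dynspec("failed to parse scene file ", path, ": ", conditionMessage(e))
    })
    if (!inherits(x, "scene")) stop_dynspec(path, " does not contain a scene")
    return(x)
  }
  if (format != "tiff") stop_dynspec("unknown scene format: ", format)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e) {
    stop_dynspec("failed to parse TIFF ", path, ": ", conditionMessage(e))
  })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop_dynspec("TIFF ", path, " contains no bands")
  aux_path <- paste0(path, ".aux.json")
  aux <- if (file.exists(aux_path)) {
    jsonlite::read_json(aux_path, simplifyVector = TRUE)
  } else {
    list()
  }
  offset <- aux$offset %||% 0
  scale <- aux$scale %||% 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  v <- array(0, c(length(pages), h, w))
  for (b in seq_along(pages)) {
    pg <- pages[[b]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # collapse accidental RGB pages
    v[b, , ] <- pg * scale + offset
  }
  scene(v, pixel_size = aux$pixel_size %||% 1,
        band_names = aux$band_names,
        date_tag = aux$date_tag %||% "",
        metadata = aux$metadata %||% list())
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    rds = "rds", tif = "tiff", tiff = "tiff",
    stop_dynspec("cannot infer scene format from extension '.", ext,
                 "'; pass `format`")
  )
}

#' Read and write region-of-interest sample points
#'
#' ROI files are plain text, one record per line: `class_id row col`,
#' whitespace- or comma-delimited, `#` starts a comment, blank lines are
#' skipped. Coordinates are 0-based with `row` counted from the top image
#' line. Duplicate coordinates are allowed (and reported by `print()`).
#'
#' @param path text file path.
#' @param class_names optional named character vector (or plain vector
#'   indexed by class id) carried as the id-to-name map.
#' @return A tibble of class `roi_set` with integer columns `class_id`,
#'   `row`, `col` and a `class_names` attribute.
#' @examples
#' p <- tempfile(fileext = ".txt")
#' writeLines(c("# demo", "1 5 7", "3,2,2"), p)
#' read_roi_text(p)
#' @export
read_roi_text <- function(path, class_names = NULL) {
  if (!file.exists(path)) stop_dynspec("ROI file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop_dynspec("ROI file ", path, " contains no records")
  recs <- matrix(NA_integer_, length(keep), 3L)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 3L || anyNA(vals) || any(vals != floor(vals))) {
      stop_dynspec("malformed ROI record at line ", ln, ": '", lines[ln], "'")
    }
    if (vals[1] < 1) stop_dynspec("class id must be >= 1 at line ", ln)
    if (any(vals[2:3] < 0)) stop_dynspec("negative coordinate at line ", ln)
    recs[i, ] <- as.integer(vals)
  }
  roi_set(tibble::tibble(class_id = recs[, 1], row = recs[, 2], col = recs[, 3]),
          class_names = class_names)
}

#' @rdname read_roi_text
#' @param roi an `roi_set` (or data frame with `class_id`, `row`, `col`).
#' @export
write_roi_text <- function(roi, path) {
  stopifnot(all(c("class_id", "row", "col") %in% names(roi)))
  writeLines(c("# class_id row col (0-based, row from top)",
               sprintf("%d %d %d", roi$class_id, roi$row, roi$col)), path)
  invisible(path)
}

#' @rdname read_roi_text
#' @param records data frame with integer columns `class_id`, `row`, `col`.
#' @export
roi_set <- function(records, class_names = NULL) {
  records <- tibble::as_tibble(records)[c("class_id", "row", "col")]
  if (nrow(records) == 0L) stop_dynspec("ROI set must contain >= 1 record")
  records$class_id <- as.integer(records$class_id)
  records$row <- as.integer(records$row)
  records$col <- as.integer(records$col)
  attr(records, "class_names") <- class_names
  class(records) <- c("roi_set", class(records))
  records
}
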