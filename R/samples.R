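#' Extract labelled pixel samples from a scene
#'
#' Pulls one sample per ROI record. With `patch = 1` (the deployed
#' configuration: pure pixel spectra) the result is a wide tibble with one
#' column per band; with an odd `patch > 1` each sample carries a
#' `(band, patch, patch)` array in a `patch` list-column.
#'
#' @param sc a [scene()].
#' @param roi an [roi_set()] (0-based coordinates, row from top).
#' @param patch odd integer window edge (default 1).
#' @param pad if `TRUE`, windows reaching past the border are zero-padded;
#'   if `FALSE` (default) out-of-reach coordinates are an error.
#' @param class_names optional id-to-name map; defaults to the map on `roi`
#'   or `class_1..class_M`.
#' @return A tibble of class `sample_set`: columns `class` (integer 1..M),
#'   `row`, `col`, `split` (initially `"unsplit"`), and either the band
#'   columns or a `patch` list-column. Attributes: `band_names`,
#'   `class_names`.
#' @examples
#' sc <- scene(array(runif(4 * 10 * 10), c(4, 10, 10)))
#' roi <- roi_set(data.frame(class_id = c(1, 2), row = c(3, 4), col = c(5, 6)))
#' extract_samples(sc, roi)
#' @export
extract_samples <- function(sc, roi, patch = 1L, pad = FALSE,
                            class_names = NULL) {
  stopifnot(inherits(sc, "scene"))
  patch <- as.integer(patch)
  if (patch < 1L || !is_odd(patch)) stop_dynspec("`patch` must be an odd integer >= 1")
  d <- dim(sc$values)
  h <- d[2]; w <- d[3]; nb <- d[1]
  half <- (patch - 1L) %/% 2L

  oob <- roi$row < 0L | roi$row >= h | roi$col < 0L | roi$col >= w
  if (any(oob)) {
    stop_dynspec("ROI coordinates outside the scene: records ",
                 paste(which(oob), collapse = ", "))
  }
  if (!pad && patch > 1L) {
    near <- roi$row < half | roi$row >= h - half |
      roi$col < half | roi$col >= w - half
    if (any(near)) {
      stop_dynspec("patch = ", patch, " reaches past the border for records ",
                   paste(which(near), collapse = ", "),
                   " (enable `pad` or drop them)")
    }
  }

  cls <- as.integer(roi$class_id)
  m <- max(cls)
  class_names <- class_names %||% attr(roi, "class_names") %||%
    sprintf("class_%d", seq_len(m))

  out <- tibble::tibble(class = cls, row = roi$row, col = roi$col,
                        split = "unsplit")
  if (patch == 1L) {
    spectra <- t(vapply(seq_len(nrow(roi)),
                        function(i) sc$values[, roi$row[i] + 1L, roi$col[i] + 1L],
                        numeric(nb)))
    colnames(spectra) <- sc$band_names
    out <- dplyr::bind_cols(out, tibble::as_tibble(spectra))
  } else {
    out$patch <- lapply(seq_len(nrow(roi)), function(i) {
      win <- array(0, c(nb, patch, patch))
      rows <- roi$row[i] + 1L + (-half:half)
      cols <- roi$col[i] + 1L + (-half:half)
      rk <- rows >= 1L & rows <= h
      ck <- cols >= 1L & cols <= w
      win[, which(rk), which(ck)] <- sc$values[, rows[rk], cols[ck], drop = FALSE]
      win
    })
  }
  attr(out, "band_names") <- sc$band_names
  attr(out, "class_names") <- class_names
  class(out) <- c("sample_set", class(out))
  out
}

#' Split samples into training and testing sets
#'
#' Tags every sample `"train"` or `"test"`; the split is disjoint and
#' exhaustive and identical for identical seeds. Stratified mode (default)
#' preserves per-class proportions to within rounding.
#'
#' @param samples a `sample_set` (or any tibble with a `class` column).
#' @param train_frac training fraction in (0, 1); the study-design default
#'   is 0.6 (a 6:4 train:test split).
#' @param seed integer RNG seed for the split.
#' @param stratified sample within classes (`TRUE`) or over all rows.
#' @return `samples` with its `split` column filled in.
#' @examples
#' s <- tibble::tibble(class = rep(1:2, each = 50), x = rnorm(100))
#' table(split_samples(s, 0.6, seed = 1)$split, s$class)
#' @export
split_samples <- function(samples, train_frac = 0.6, seed = 1L,
                          stratified = TRUE) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop_dynspec("`train_frac` must lie strictly between 0 and 1")
  }
  n <- nrow(samples)
  split <- rep("test", n)
  set.seed(as.integer(seed))
  if (stratified) {
    for (cl in sort(unique(samples$class))) {
      idx <- which(samples$class == cl)
      if (length(idx) < 2L) {
        stop_dynspec("class ", cl, " has fewer than 2 samples; ",
                     "stratified splitting needs both sides populated")
      }
      k <- round(train_frac * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      split[sample(idx, k)] <- "train"
    }
  } else {
    k <- min(max(round(train_frac * n), 1L), n - 1L)
    split[sample.int(n, k)] <- "train"
  }
  samples$split <- split
  samples
}

#' Extract the spectra matrix and labels from a sample set
#'
#' @param samples a `sample_set` with band columns (patch = 1).
#' @param split optional filter: `"train"`, `"test"` or `NULL` for all rows.
#' @return list with `x` (n x bands matrix), `y` (integer labels),
#'   `band_names`, `class_names`.
#' @export
sample_matrix <- function(samples, split = NULL) {
  if (!is.null(split)) samples <- samples[samples$split == split, , drop = FALSE]
  bn <- attr(samples, "band_names") %||%
    setdiff(names(samples), c("class", "row", "col", "split", "patch"))
  x <- as.matrix(samples[, bn, drop = FALSE])
  if (anyNA(x)) stop_dynspec("sample spectra contain NA values")
  list(x = x, y = as.integer(samples$class), band_names = bn,
       class_names = attr(samples, "class_names"))
}
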