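#' Mean cross-entropy loss
#'
#' `L = -(1/N) * sum_i log p_i(true class)`; probabilities are clamped at
#' `1e-12` before the log.
#'
#' @param p probability matrix `(N, M)`; rows must sum to 1 within `tol`.
#' @param y integer true labels in `1..M`.
#' @param tol row-normalisation tolerance (default `1e-6`).
#' @return scalar mean loss.
#' @examples
#' cross_entropy(matrix(rep(1 / 7, 7), 1), 1)  # log(7)
#' @export
cross_entropy <- function(p, y, tol = 1e-6) {
  p <- as.matrix(p)
  y <- as.integer(y)
  if (length(y) != nrow(p)) stop_dynspec("length(y) must equal nrow(p)")
  if (any(y < 1L | y > ncol(p))) stop_dynspec("labels must lie in 1..", ncol(p))
  if (any(abs(rowSums(p) - 1) > tol)) {
    stop_dynspec("probability rows do not sum to 1 within ", tol)
  }
  pt <- pmax(p[cbind(seq_along(y), y)], 1e-12)
  -mean(log(pt))
}

#' Confusion matrix
#'
#' Rows are the true class, columns the predicted class.
#'
#' @param y_true,y_pred integer labels in `1..n_classes`.
#' @param n_classes class count `M`; defaults to the maximum observed label.
#' @param class_names optional class labels used as dimnames.
#' @return `M x M` integer matrix of class `confusion_matrix`.
#' @examples
#' confusion_counts(c(1, 1, 2), c(1, 2, 2), 2)
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = NULL,
                             class_names = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop_dynspec("label vectors differ in length")
  m <- n_classes %||% max(y_true, y_pred)
  if (any(y_true < 1L | y_true > m | y_pred < 1L | y_pred > m)) {
    stop_dynspec("labels outside 1..", m)
  }
  cm <- matrix(0L, m, m)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  nm <- class_names %||% sprintf("class_%d", seq_len(m))
  dimnames(cm) <- list(true = nm, predicted = nm)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Overall accuracy
#'
#' `100 * trace / total` percent of the confusion matrix.
#'
#' @param cm confusion matrix (true rows, predicted columns).
#' @return overall accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop_dynspec("empty confusion matrix")
  100 * sum(diag(as.matrix(cm))) / total
}

#' Average (per-class) accuracy
#'
#' `mode = "mean_recall"` (default) averages the per-class recall
#' (diagonal over row sum) — the convention consistent with multi-class
#' accuracy tables where AA tracks OA. `mode = "literal_onevsrest"`
#' averages the binary one-vs-rest accuracies `(TP + TN) / N` per class,
#' which inflates multi-class AA because every class collects the true
#' negatives of all others; it is retained for fidelity to the binary
#' definition.
#'
#' @inheritParams overall_accuracy
#' @param mode `"mean_recall"` or `"literal_onevsrest"`.
#' @return average accuracy in percent.
#' @export
average_accuracy <- function(cm, mode = c("mean_recall", "literal_onevsrest")) {
  mode <- match.arg(mode)
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total == 0) stop_dynspec("empty confusion matrix")
  if (mode == "mean_recall") {
    rs <- rowSums(cm)
    empty <- which(rs == 0)
    if (length(empty) > 0) {
      stop_dynspec("no true samples for class(es) ",
                   paste(rownames(cm)[empty] %||% empty, collapse = ", "))
    }
    return(100 * mean(diag(cm) / rs))
  }
  acc <- vapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    (tp + tn) / total
  }, numeric(1))
  100 * mean(acc)
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement: `kappa = (P_l - P_x) / (1 - P_x)` with
#' `P_l = trace / total` the observed agreement and
#' `P_x = sum_c(row_c * col_c) / total^2` the chance agreement from the
#' marginals.
#'
#' @inheritParams overall_accuracy
#' @return kappa in `[-1, 1]`.
#' @examples
#' kappa_coefficient(matrix(c(25, 25, 25, 25), 2))  # 0: chance agreement
#' @export
kappa_coefficient <- function(cm) {
  cm <- as.matrix(unclass(cm))
  total <- sum(cm)
  if (total == 0) stop_dynspec("empty confusion matrix")
  pl <- sum(diag(cm)) / total
  px <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - px) < .Machine$double.eps) {
    stop_dynspec("kappa undefined: chance agreement P_x = 1 (degenerate matrix)")
  }
  (pl - px) / (1 - px)
}

#' Full accuracy report from a confusion matrix
#'
#' @inheritParams average_accuracy
#' @return An object of class `metrics_report`: list with the confusion
#'   matrix, `oa`, `aa`, `aa_mode`, `kappa` and a `per_class` tibble
#'   (class, n, accuracy in percent).
#' @export
metrics_report <- function(cm, mode = "mean_recall") {
  cmu <- as.matrix(unclass(cm))
  rs <- rowSums(cmu)
  per_class <- tibble::tibble(
    class = rownames(cmu) %||% sprintf("class_%d", seq_len(nrow(cmu))),
    n = as.integer(rs),
    accuracy = ifelse(rs > 0, 100 * diag(cmu) / rs, NA_real_))
  structure(
    list(confusion = cm, oa = overall_accuracy(cm),
         aa = average_accuracy(cm, mode), aa_mode = mode,
         kappa = kappa_coefficient(cm), per_class = per_class),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> OA %.2f%%  AA %.2f%% (%s)  Kappa %.4f\n",
              x$oa, x$aa, x$aa_mode, x$kappa))
  print(x$per_class)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' CSV mirrors the per-class table layout with an OA/AA/Kappa footer;
#' JSON carries the same fields structured.
#'
#' @param report a [metrics_report()].
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @export
write_metrics <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    body <- report$per_class
    footer <- tibble::tibble(
      class = c("OA", "AA", "Kappa"), n = NA_integer_,
      accuracy = c(report$oa, report$aa, report$kappa))
    utils::write.csv(rbind(body, footer), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(oa = report$oa, aa = report$aa, aa_mode = report$aa_mode,
           kappa = report$kappa,
           per_class = report$per_class,
           confusion = as.matrix(unclass(report$confusion))),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
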