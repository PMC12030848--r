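#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted classifier
#'
#' One row per parameter group with its array shape and size.
#'
#' @param x a `dynspec_fit`.
#' @param ... unused.
#' @return tibble with columns `component`, `parameter`, `shape`, `n`.
#' @method tidy dynspec_fit
#' @export
tidy.dynspec_fit <- function(x, ...) {
  p <- get_trainable(x$net)
  rows <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      nms <- names(node) %||% as.character(seq_along(node))
      nms[nms == ""] <- as.character(which(nms == ""))
      for (i in seq_along(node)) {
        walk(node[[i]], c(path, nms[i]))
      }
    } else {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        component = path[1],
        parameter = paste(path[-1], collapse = "."),
        shape = paste(dim(node) %||% length(node), collapse = "x"),
        n = length(node))
    }
  }
  walk(p, character(0))
  dplyr::bind_rows(rows)
}

#' @rdname tidy.dynspec_fit
#' @return `glance()` returns a one-row tibble: epochs trained, final
#'   training loss and accuracy, final learning rate, parameter count and
#'   the ablation switches.
#' @method glance dynspec_fit
#' @export
glance.dynspec_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_loss = h$loss[nrow(h)],
    final_train_accuracy = h$accuracy[nrow(h)],
    final_lr = h$lr[nrow(h)],
    n_parameters = n_params(get_trainable(x$net)),
    use_odc = x$config$use_odc, use_lsk = x$config$use_lsk,
    improved_lsk = x$config$improved_lsk)
}

#' Tidy an accuracy report
#'
#' @param x a [metrics_report()].
#' @param ... unused.
#' @return per-class tibble (`class`, `n`, `accuracy`).
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  x$per_class
}

#' @rdname tidy.metrics_report
#' @return `glance()` returns a one-row tibble with `oa`, `aa`, `kappa`
#'   and the sample count.
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(oa = x$oa, aa = x$aa, aa_mode = x$aa_mode, kappa = x$kappa,
                 n = sum(unclass(x$confusion)))
}

#' Training-history curves
#'
#' Loss and training accuracy against the epoch index.
#'
#' @param object a `dynspec_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot dynspec_fit
#' @export
autoplot.dynspec_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}

#' Confusion-matrix heatmap
#'
#' @param object a [metrics_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  cm <- as.matrix(unclass(object$confusion))
  df <- tibble::as_tibble(as.data.frame.table(cm, responseName = "count"))
  names(df)[1:2] <- c("true", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::labs(title = sprintf("OA %.2f%%, AA %.2f%%, Kappa %.4f",
                                  object$oa, object$aa, object$kappa)) +
    ggplot2::theme_minimal()
}

#' Difficulty-sweep curve
#'
#' Test overall accuracy against class-mean separation; the dashed line
#' marks the chance level of the sweep's class count.
#'
#' @param object a [difficulty_sweep()] tibble.
#' @param n_classes class count for the chance line (inferred from the
#'   kappa-free chance level if omitted).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot difficulty_sweep
#' @export
autoplot.difficulty_sweep <- function(object, n_classes = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$separation, y = .data$oa)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "class-mean separation", y = "overall accuracy (%)",
                  title = "Accuracy against spectral separation")
  if (!is.null(n_classes)) {
    p <- p + ggplot2::geom_hline(yintercept = 100 / n_classes,
                                 linetype = "dashed")
  }
  p
}

#' Single-band raster plot of a scene
#'
#' @param object a [scene()].
#' @param band band index to display.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot scene
#' @export
autoplot.scene <- function(object, band = 1L, ...) {
  v <- object$values[band, , ]
  df <- tidyr::expand_grid(row = seq_len(nrow(v)), col = seq_len(ncol(v)))
  df$value <- v[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$band_names[band], fill = "reflectance")
}

#' @importFrom rlang .data
NULL
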