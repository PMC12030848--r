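#' Training protocol configuration
#'
#' Defaults follow the study protocol: batch size 32, at most 100 epochs,
#' learning-rate decay 0.9 applied once per epoch, adaptive-moment (Adam)
#' optimisation from an initial rate of 1e-3.
#'
#' @param batch_size minibatch size (>= 1).
#' @param max_epochs maximum number of passes over the training set.
#' @param initial_lr initial learning rate.
#' @param lr_decay per-epoch multiplicative decay in (0, 1].
#' @param seed integer seed controlling initial weights and epoch shuffles.
#' @param patience optional early-stop patience: stop when the training
#'   loss has not improved for this many epochs (`NULL` disables).
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, max_epochs = 100L,
                         initial_lr = 1e-3, lr_decay = 0.9, seed = 1L,
                         patience = NULL) {
  if (batch_size < 1L) stop_dynspec("`batch_size` must be >= 1")
  if (lr_decay <= 0 || lr_decay > 1) stop_dynspec("`lr_decay` must lie in (0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 seed = as.integer(seed), patience = patience),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr(epoch) = initial_lr * lr_decay^(epoch - 1)`.
#'
#' @param tc a [train_config()].
#' @param epoch 1-based epoch index.
#' @return learning rate.
#' @export
lr_at_epoch <- function(tc, epoch) {
  tc$initial_lr * tc$lr_decay^(epoch - 1)
}

#' Fit the pixel classifier
#'
#' Trains the network on labelled pixel spectra by minibatch Adam on the
#' mean cross-entropy, shuffling each epoch with a seeded generator and
#' decaying the learning rate once per epoch. Fully deterministic for a
#' fixed seed on a single thread.
#'
#' @param samples a `sample_set` tibble (band columns + `class`); rows
#'   tagged `split == "train"` are used when a split is present, otherwise
#'   all rows.
#' @param config a [network_config()]; defaults to the standard
#'   architecture sized from the data.
#' @param tc a [train_config()].
#' @param standardize z-score each band using training-set statistics
#'   before the network (default `TRUE`); the statistics are stored on the
#'   fit and re-applied by `predict()`.
#' @return An object of class `dynspec_fit`: the trained network, a
#'   `history` tibble (epoch, loss, accuracy, lr) and the label/band
#'   metadata.
#' @examples
#' \donttest{
#' sim <- generate_scene(scene_spec(height = 48, width = 48, bands = 4,
#'                                  n_classes = 3, seed = 1))
#' roi <- generate_roi(sim$labels, n_per_class = 40, seed = 2)
#' s <- split_samples(extract_samples(sim$scene, roi), 0.6, seed = 3)
#' fit <- fit_network(s, network_config(4, 3, gru_hidden = 16,
#'                                      mlp_hidden = 32),
#'                    train_config(max_epochs = 3))
#' glance(fit)
#' }
#' @export
fit_network <- function(samples, config = NULL, tc = train_config(),
                        standardize = TRUE) {
  has_split <- "split" %in% names(samples) && any(samples$split == "train")
  sm <- sample_matrix(samples, split = if (has_split) "train" else NULL)
  x <- sm$x
  y <- sm$y
  if (nrow(x) == 0L) stop_dynspec("no training samples")
  scaling <- NULL
  if (standardize) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2L, stats::sd)
    sd_[sd_ == 0 | !is.finite(sd_)] <- 1
    scaling <- list(center = mu, scale = sd_)
    x <- sweep(sweep(x, 2L, mu), 2L, sd_, "/")
  }
  m <- max(y)
  config <- config %||% network_config(bands = ncol(x), n_classes = m)
  if (config$bands != ncol(x)) {
    stop_dynspec("samples have ", ncol(x), " bands; config expects ", config$bands)
  }
  if (m > config$n_classes) stop_dynspec("labels exceed configured class count")

  net <- build_network(config, seed = tc$seed)
  params <- get_trainable(net)
  opt <- adam_init(params)
  onehot <- diag(config$n_classes)
  history <- vector("list", tc$max_epochs)
  best_loss <- Inf; stale <- 0L
  set.seed(tc$seed + 17L)
  n <- nrow(x)
  for (epoch in seq_len(tc$max_epochs)) {
    lr <- lr_at_epoch(tc, epoch)
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- net_forward(net, xb, keep_cache = TRUE)
      pt <- pmax(fw$probs[cbind(seq_along(yb), yb)], 1e-12)
      loss <- -mean(log(pt))
      if (!is.finite(loss)) {
        stop_dynspec("training aborted: non-finite loss at epoch ", epoch,
                     " (learning rate ", signif(lr, 3), ")")
      }
      dlogits <- (fw$probs - onehot[yb, , drop = FALSE]) / length(yb)
      bw <- net_backward(net, fw$cache, dlogits)
      stepped <- adam_step(params, bw$grads, opt, lr)
      params <- stepped$params
      opt <- stepped$state
      net <- set_trainable(net, params)
      ep_loss <- ep_loss + loss * length(yb)
      ep_correct <- ep_correct +
        sum(max.col(fw$probs, ties.method = "first") == yb)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = ep_loss / n, accuracy = 100 * ep_correct / n,
      lr = lr)
    if (!is.null(tc$patience)) {
      if (history[[epoch]]$loss < best_loss - 1e-8) {
        best_loss <- history[[epoch]]$loss; stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= tc$patience) break
      }
    }
  }
  structure(
    list(net = net, config = config, train_config = tc, scaling = scaling,
         history = dplyr::bind_rows(history),
         band_names = sm$band_names,
         class_names = sm$class_names %||%
           sprintf("class_%d", seq_len(config$n_classes))),
    class = "dynspec_fit")
}

#' @export
print.dynspec_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<dynspec_fit> %d bands -> %d classes | odc=%s lsk=%s improved=%s\n",
    x$config$bands, x$config$n_classes, x$config$use_odc, x$config$use_lsk,
    x$config$improved_lsk))
  cat(sprintf("trained %d epoch(s); final loss %.4f, train accuracy %.2f%%\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  cat(sprintf("parameters: %d\n", n_params(get_trainable(x$net))))
  invisible(x)
}

#' Predict classes or probabilities for pixel spectra
#'
#' Argmax ties are broken toward the lowest class index.
#'
#' @param object a `dynspec_fit`.
#' @param newdata a `sample_set` tibble or a numeric matrix `(n, bands)`.
#' @param type `"class"` for hard labels, `"prob"` for the probability
#'   matrix.
#' @param ... unused.
#' @export
predict.dynspec_fit <- function(object, newdata, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else sample_matrix(newdata)$x
  if (!is.null(object$scaling)) {
    x <- sweep(sweep(x, 2L, object$scaling$center), 2L,
               object$scaling$scale, "/")
  }
  probs <- net_forward(object$net, x)$probs
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  max.col(probs, ties.method = "first")
}

#' Evaluate a fitted classifier on labelled samples
#'
#' Predicts by probability argmax (ties toward the lowest class index),
#' tabulates the confusion matrix, and reports overall accuracy, average
#' accuracy, kappa and per-class accuracies.
#'
#' @param fit a `dynspec_fit`.
#' @param samples labelled `sample_set`; rows tagged `split == "test"` are
#'   used when a split is present, otherwise all rows.
#' @param aa_mode passed to [average_accuracy()].
#' @return a [metrics_report()].
#' @export
evaluate_network <- function(fit, samples, aa_mode = "mean_recall") {
  has_split <- "split" %in% names(samples) && any(samples$split == "test")
  sm <- sample_matrix(samples, split = if (has_split) "test" else NULL)
  if (nrow(sm$x) == 0L) stop_dynspec("no evaluation samples")
  pred <- predict(fit, sm$x)
  cm <- confusion_counts(sm$y, pred, n_classes = fit$config$n_classes,
                         class_names = fit$class_names)
  metrics_report(cm, mode = aa_mode)
}
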