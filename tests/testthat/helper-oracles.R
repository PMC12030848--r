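# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain scalar loops and
# first-principles formulas.

# Dense 2-d convolution by quintuple loop; stride 1, zero "same" padding.
# x: (C_in, H, W); w: (C_out, C_in, kh, kw).
conv2d_loop <- function(x, w, bias = NULL, dilation = 1L) {
  ci <- dim(x)[1]; h <- dim(x)[2]; wd <- dim(x)[3]
  co <- dim(w)[1]; kh <- dim(w)[3]; kw <- dim(w)[4]
  ph <- dilation * (kh - 1L) / 2L
  pw <- dilation * (kw - 1L) / 2L
  out <- array(0, c(co, h, wd))
  for (o in seq_len(co)) {
    for (i in seq_len(h)) {
      for (j in seq_len(wd)) {
        acc <- if (is.null(bias)) 0 else bias[o]
        for (c in seq_len(ci)) {
          for (u in seq_len(kh)) {
            for (v in seq_len(kw)) {
              ii <- i + dilation * (u - 1L) - ph
              jj <- j + dilation * (v - 1L) - pw
              if (ii >= 1 && ii <= h && jj >= 1 && jj <= wd) {
                acc <- acc + w[o, c, u, v] * x[c, ii, jj]
              }
            }
          }
        }
        out[o, i, j] <- acc
      }
    }
  }
  out
}

# First-principles accuracy metrics from a confusion matrix (rows = truth).
metrics_ref <- function(cm) {
  cm <- as.matrix(unclass(cm))
  n <- sum(cm)
  oa <- 100 * sum(diag(cm)) / n
  recalls <- diag(cm) / rowSums(cm)
  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  kappa <- (sum(diag(cm)) / n - pe) / (1 - pe)
  list(oa = oa, aa = 100 * mean(recalls), kappa = kappa)
}

# Small labelled synthetic sample fixture shared across training tests.
make_toy_samples <- function(seed = 1, n_per_class = 60, bands = 4,
                             sep = 4) {
  set.seed(seed)
  x1 <- matrix(rnorm(n_per_class * bands, 0, 1), n_per_class, bands)
  x2 <- matrix(rnorm(n_per_class * bands, sep, 1), n_per_class, bands)
  x <- rbind(x1, x2)
  colnames(x) <- sprintf("band_%02d", seq_len(bands))
  out <- dplyr::bind_cols(
    tibble::tibble(class = rep(1:2, each = n_per_class),
                   row = 0L, col = 0L, split = "unsplit"),
    tibble::as_tibble(x))
  attr(out, "band_names") <- colnames(x)
  class(out) <- c("sample_set", class(out))
  out
}

small_config <- function(bands = 4, n_classes = 2, ...) {
  network_config(bands, n_classes, gru_hidden = 8L, mlp_hidden = 16L,
                 odconv = list(n_kernels = 2L), lsk = list(heads = 2L), ...)
}
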