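#' Omni-dimensional dynamic convolution state
#'
#' Holds `n` candidate convolution kernels together with the parameters of
#' the attention network that modulates them along four axes of the kernel
#' space: spatial position, input channel, output channel (filter) and
#' kernel index. The attention network is a global-average-pool followed by
#' a bottleneck projection (`c_in -> max(c_in / reduction, 1)`), a ReLU, and
#' four parallel linear heads; spatial/channel/filter heads are squashed by
#' a sigmoid and the kernel head by a temperature softmax, so the candidate
#' kernels always enter as a convex combination.
#'
#' @param c_in,c_out input and output channel counts.
#' @param k odd spatial kernel size (deployed configuration: 1).
#' @param n_kernels number of candidate kernels `n` (default 4).
#' @param reduction attention bottleneck ratio (default 4, floored at one
#'   hidden unit).
#' @param temperature softmax temperature for the kernel-axis attention.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `odconv_state`.
#' @examples
#' st <- odconv_state(4, 4, k = 1, n_kernels = 2, seed = 1)
#' st$n_kernels
#' @export
odconv_state <- function(c_in, c_out, k = 1L, n_kernels = 4L, reduction = 4L,
                         temperature = 1, seed = 1L) {
  k <- as.integer(k)
  if (!is_odd(k) || k < 1L) stop_dynspec("`k` must be an odd integer >= 1")
  if (n_kernels < 1L) stop_dynspec("`n_kernels` must be >= 1")
  set.seed(as.integer(seed))
  cr <- max(1L, c_in %/% as.integer(reduction))
  st <- list(
    kernels = init_weights(c(n_kernels, c_out, c_in, k, k), c_in * k * k),
    bias = rep(0, c_out),
    w_reduce = init_weights(c(c_in, cr), c_in), b_reduce = rep(0, cr),
    w_spatial = init_weights(c(cr, k * k), cr), b_spatial = rep(0, k * k),
    w_channel = init_weights(c(cr, c_in), cr), b_channel = rep(0, c_in),
    w_filter = init_weights(c(cr, c_out), cr), b_filter = rep(0, c_out),
    w_kernel = init_weights(c(cr, n_kernels), cr), b_kernel = rep(0, n_kernels)
  )
  st$c_in <- c_in; st$c_out <- c_out; st$k <- k
  st$n_kernels <- as.integer(n_kernels)
  st$temperature <- temperature
  class(st) <- "odconv_state"
  st
}

#' Per-item attention bundle for dynamic convolution
#'
#' Computes, for every batch item, the four attention vectors that modulate
#' the candidate kernels: `alpha_s` over the `k*k` spatial taps, `alpha_c`
#' over input channels, `alpha_f` over output channels (all sigmoid, hence
#' in (0, 1)) and `alpha_w` over the `n` candidate kernels (softmax, hence
#' non-negative and summing to 1).
#'
#' @param x input feature maps `(batch, c_in, H, W)`, or an `n x c_in`
#'   matrix of pixel spectra (interpreted as `H = W = 1`).
#' @param state an [odconv_state()].
#' @return An object of class `attention_bundle`: list of matrices
#'   `alpha_s` (batch x k^2), `alpha_c` (batch x c_in), `alpha_f`
#'   (batch x c_out), `alpha_w` (batch x n).
#' @export
compute_attentions <- function(x, state) {
  stopifnot(inherits(state, "odconv_state"))
  if (is.matrix(x)) x <- spectra_to_maps(x)
  d <- dim(x)
  if (d[2] != state$c_in) stop_dynspec("input has ", d[2], " channels; state expects ", state$c_in)
  if (d[3] * d[4] == 0L) stop_dynspec("empty spatial extent")
  # global average pool over (H, W)
  g <- matrix(0, d[1], d[2])
  for (b in seq_len(d[1])) g[b, ] <- apply(array(x[b, , , ], d[-1]), 1L, mean)
  z0 <- g %*% state$w_reduce + rep(state$b_reduce, each = d[1])
  z <- relu(z0)
  bundle <- attention_bundle(
    alpha_s = sigmoid(z %*% state$w_spatial + rep(state$b_spatial, each = d[1])),
    alpha_c = sigmoid(z %*% state$w_channel + rep(state$b_channel, each = d[1])),
    alpha_f = sigmoid(z %*% state$w_filter + rep(state$b_filter, each = d[1])),
    alpha_w = softmax_rows((z %*% state$w_kernel +
                              rep(state$b_kernel, each = d[1])) / state$temperature)
  )
  bundle
}

#' @rdname compute_attentions
#' @param alpha_s,alpha_c,alpha_f,alpha_w attention matrices (one row per
#'   batch item); use this constructor to force attentions in tests or
#'   ablations.
#' @export
attention_bundle <- function(alpha_s, alpha_c, alpha_f, alpha_w) {
  alpha_w <- as.matrix(alpha_w)
  if (any(abs(rowSums(alpha_w) - 1) > 1e-6)) {
    stop_dynspec("kernel attention rows must sum to 1")
  }
  structure(list(alpha_s = as.matrix(alpha_s), alpha_c = as.matrix(alpha_c),
                 alpha_f = as.matrix(alpha_f), alpha_w = alpha_w),
            class = "attention_bundle")
}

#' Dynamic convolution forward pass
#'
#' Builds, for every batch item, the effective kernel
#' `sum_n alpha_w[n] * (alpha_f x alpha_c x alpha_s) * W_n` — the four
#' attentions applied along the output-channel, input-channel and spatial
#' axes of each candidate kernel — and convolves the item with it (stride
#' 1, zero same-padding, so `k = 1` preserves the spatial extent).
#'
#' @inheritParams compute_attentions
#' @param bundle an `attention_bundle`; computed from `x` when `NULL`.
#' @return Feature maps `(batch, c_out, H, W)`; if `x` was given as a
#'   spectra matrix, an `n x c_out` matrix.
#' @examples
#' st <- odconv_state(3, 3, n_kernels = 2, seed = 7)
#' x <- matrix(rnorm(6), 2, 3)
#' y <- odconv_forward(x, st)
#' dim(y)
#' @export
odconv_forward <- function(x, state, bundle = NULL) {
  stopifnot(inherits(state, "odconv_state"))
  as_matrix <- is.matrix(x)
  if (as_matrix) x <- spectra_to_maps(x)
  d <- dim(x)
  if (d[2] != state$c_in) stop_dynspec("input has ", d[2], " channels; state expects ", state$c_in)
  bundle <- bundle %||% compute_attentions(x, state)
  k <- state$k
  out <- NULL
  for (b in seq_len(d[1])) {
    w_eff <- array(0, c(state$c_out, state$c_in, k, k))
    a_s <- array(bundle$alpha_s[b, ], c(k, k))
    for (n in seq_len(state$n_kernels)) {
      wn <- array(state$kernels[n, , , , ], c(state$c_out, state$c_in, k, k))
      mod <- outer(outer(bundle$alpha_f[b, ], bundle$alpha_c[b, ]), a_s)
      w_eff <- w_eff + bundle$alpha_w[b, n] * mod * wn
    }
    r <- conv2d_chw(array(x[b, , , ], d[-1]), w_eff, state$bias)
    if (is.null(out)) out <- array(0, c(d[1], dim(r)))
    out[b, , , ] <- r
  }
  if (as_matrix) maps_to_spectra(out) else out
}
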