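#' Classifier network configuration
#'
#' Configures the full pixel classifier: two parallel spectral feature
#' branches (dynamic convolution and improved selective-kernel attention),
#' fused and fed band-by-band through a stacked GRU whose final hidden
#' state is classified by an MLP head with softmax output. The three
#' ablation switches `use_odc`, `use_lsk`, `improved_lsk` span the module
#' on/off lattice; a disabled branch passes the raw input through.
#'
#' @param bands input band count (4 and 12 are the typical sensor layouts).
#' @param n_classes number of land-cover classes `M` (>= 2).
#' @param gru_hidden GRU state width (default 128; this is also the MLP
#'   input width).
#' @param gru_layers number of stacked GRU layers (default 2).
#' @param mlp_hidden MLP hidden width (default 256).
#' @param use_odc,use_lsk enable the dynamic-convolution / selective-kernel
#'   branch.
#' @param improved_lsk apply the multi-head refinement inside the LSK
#'   branch.
#' @param fusion `"add"` (elementwise, the default) or `"concat"`
#'   (channel concatenation, doubling the sequence length).
#' @param head_activation `"relu"` (default) or `"sigmoid"` nonlinearity in
#'   the MLP head.
#' @param odconv list of dynamic-convolution settings: `n_kernels`,
#'   `reduction`, `temperature`, `kernel_size`.
#' @param lsk list of selective-kernel settings: `heads`, `embed_dim`,
#'   `branch_kernels`, `dilations`, `attn_kernel`.
#' @return A list of class `network_config`.
#' @examples
#' cfg <- network_config(bands = 12, n_classes = 7)
#' cfg$gru_hidden
#' @export
network_config <- function(bands, n_classes, gru_hidden = 128L,
                           gru_layers = 2L, mlp_hidden = 256L,
                           use_odc = TRUE, use_lsk = TRUE,
                           improved_lsk = TRUE,
                           fusion = c("add", "concat"),
                           head_activation = c("relu", "sigmoid"),
                           odconv = list(), lsk = list()) {
  if (n_classes < 2L) stop_dynspec("`n_classes` must be >= 2")
  if (gru_layers < 1L) stop_dynspec("`gru_layers` must be >= 1")
  od <- utils::modifyList(
    list(n_kernels = 4L, reduction = 4L, temperature = 1, kernel_size = 1L),
    odconv)
  lk <- utils::modifyList(
    list(heads = 4L, embed_dim = NULL, branch_kernels = c(5L, 7L),
         dilations = c(1L, 3L), attn_kernel = 7L),
    lsk)
  structure(
    list(bands = as.integer(bands), n_classes = as.integer(n_classes),
         gru_hidden = as.integer(gru_hidden),
         gru_layers = as.integer(gru_layers),
         mlp_hidden = as.integer(mlp_hidden),
         use_odc = isTRUE(use_odc), use_lsk = isTRUE(use_lsk),
         improved_lsk = isTRUE(improved_lsk),
         fusion = match.arg(fusion),
         head_activation = match.arg(head_activation),
         odconv = od, lsk = lk),
    class = "network_config")
}

#' Build a network with freshly initialised weights
#'
#' All weight arrays use uniform fan-in initialisation with a seeded
#' generator; the same seed always yields the same network.
#'
#' @param config a [network_config()].
#' @param seed integer seed.
#' @return An object of class `dynspec_net` holding the branch states, GRU
#'   layer parameters and MLP head.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  seed <- as.integer(seed)
  net <- list(config = config)
  if (config$use_odc) {
    net$odc <- odconv_state(config$bands, config$bands,
                            k = config$odconv$kernel_size,
                            n_kernels = config$odconv$n_kernels,
                            reduction = config$odconv$reduction,
                            temperature = config$odconv$temperature,
                            seed = seed + 1L)
  }
  if (config$use_lsk) {
    net$lsk <- lsk_params(config$bands,
                          branch_kernels = config$lsk$branch_kernels,
                          dilations = config$lsk$dilations,
                          attn_kernel = config$lsk$attn_kernel,
                          heads = config$lsk$heads,
                          embed_dim = config$lsk$embed_dim,
                          seed = seed + 2L)
  }
  set.seed(seed + 3L)
  h <- config$gru_hidden
  net$gru <- vector("list", config$gru_layers)
  f_in <- 1L  # per-step feature width: one flattened spatial position
  for (l in seq_len(config$gru_layers)) {
    net$gru[[l]] <- gru_layer_init(f_in, h)
    f_in <- h
  }
  net$mlp <- list(
    w1 = init_weights(c(h, config$mlp_hidden), h),
    b1 = rep(0, config$mlp_hidden),
    w2 = init_weights(c(config$mlp_hidden, config$n_classes), config$mlp_hidden),
    b2 = rep(0, config$n_classes))
  class(net) <- "dynspec_net"
  net
}

gru_layer_init <- function(f_in, h) {
  list(wxz = init_weights(c(f_in, h), f_in), whz = init_weights(c(h, h), h),
       bz = rep(0, h),
       wxr = init_weights(c(f_in, h), f_in), whr = init_weights(c(h, h), h),
       br = rep(0, h),
       wxh = init_weights(c(f_in, h), f_in), whh = init_weights(c(h, h), h),
       bh = rep(0, h))
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Fuse the parallel branch features
#'
#' @param odc_feat,lsk_feat branch outputs: matrices `(batch, C)` or arrays
#'   `(batch, C, H, W)` of identical shape. A disabled branch is
#'   represented by the raw input (residual pass-through).
#' @param mode `"add"` for elementwise addition, `"concat"` for channel
#'   concatenation (doubling the channel count).
#' @return fused feature in the same layout.
#' @export
fuse_parallel <- function(odc_feat, lsk_feat, mode = c("add", "concat")) {
  mode <- match.arg(mode)
  if (mode == "add") {
    if (!identical(dim(odc_feat), dim(lsk_feat))) {
      stop_dynspec("branch shapes differ; additive fusion needs identical shapes")
    }
    return(odc_feat + lsk_feat)
  }
  if (is.matrix(odc_feat)) return(cbind(odc_feat, lsk_feat))
  d <- dim(odc_feat)
  out <- array(0, c(d[1], 2L * d[2], d[3], d[4]))
  out[, seq_len(d[2]), , ] <- odc_feat
  out[, d[2] + seq_len(d[2]), , ] <- lsk_feat
  out
}

#' Reshape fused feature maps into a band sequence
#'
#' The band axis becomes the recurrent sequence axis and the spatial
#' positions flatten into the per-step feature vector (length 1 in the
#' deployed pixel-spectrum configuration).
#'
#' @param fused array `(batch, C, H, W)`.
#' @return array `(batch, T = C, features = H * W)`.
#' @export
reshape_for_rnn <- function(fused) {
  d <- dim(fused)
  stopifnot(length(d) == 4L)
  array(fused, c(d[1], d[2], d[3] * d[4]))
}

#' Stacked GRU forward pass
#'
#' Standard gated recursion per layer: update gate
#' `z = sigmoid(x W_xz + h W_hz + b_z)`, reset gate
#' `r = sigmoid(x W_xr + h W_hr + b_r)`, candidate
#' `h~ = tanh(x W_xh + r * (h W_hh) + b_h)`, new state
#' `h' = z * h + (1 - z) * h~` (the update gate retains the previous
#' state). The initial state is zero; the final top-layer state is
#' returned.
#'
#' @param seq input array `(batch, T, features)` (see [reshape_for_rnn()]).
#' @param layers list of GRU layer parameter lists (as built by
#'   [build_network()], `net$gru`).
#' @return final hidden state matrix `(batch, gru_hidden)`.
#' @export
gru_forward <- function(seq, layers) {
  d <- dim(seq)
  xs <- lapply(seq_len(d[2]), function(t) matrix(seq[, t, ], d[1], d[3]))
  for (l in seq_along(layers)) {
    fw <- gru_layer_fwd(xs, layers[[l]])
    xs <- fw$h_seq
  }
  xs[[length(xs)]]
}

gru_layer_fwd <- function(xs, p) {
  n <- nrow(xs[[1]]); h_dim <- ncol(p$whz)
  h <- matrix(0, n, h_dim)
  steps <- vector("list", length(xs))
  h_seq <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    x <- xs[[t]]
    z <- sigmoid(x %*% p$wxz + h %*% p$whz + rep_row(p$bz, n))
    r <- sigmoid(x %*% p$wxr + h %*% p$whr + rep_row(p$br, n))
    q <- h %*% p$whh
    hc <- tanh(x %*% p$wxh + r * q + rep_row(p$bh, n))
    h_new <- z * h + (1 - z) * hc
    steps[[t]] <- list(x = x, h_prev = h, z = z, r = r, q = q, hc = hc)
    h <- h_new
    h_seq[[t]] <- h
  }
  list(h_seq = h_seq, h_final = h, steps = steps)
}

#' MLP classification head
#'
#' Affine `gru_hidden -> mlp_hidden`, nonlinearity (ReLU by default),
#' affine `mlp_hidden -> n_classes`.
#'
#' @param hidden matrix `(batch, gru_hidden)`.
#' @param mlp head parameter list (`net$mlp`).
#' @param activation `"relu"` or `"sigmoid"`.
#' @return logits matrix `(batch, n_classes)`.
#' @export
mlp_head <- function(hidden, mlp, activation = "relu") {
  if (ncol(hidden) != nrow(mlp$w1)) {
    stop_dynspec("hidden width ", ncol(hidden), " does not match head input ",
                 nrow(mlp$w1))
  }
  a1 <- hidden %*% mlp$w1 + rep_row(mlp$b1, nrow(hidden))
  z1 <- if (activation == "relu") relu(a1) else sigmoid(a1)
  z1 %*% mlp$w2 + rep_row(mlp$b2, nrow(hidden))
}

# ---------------------------------------------------------------------------
# Fast pixel-spectrum (patch = 1) forward pass with caches for backprop.
# At 1x1 spatial extent every convolution degenerates to channel mixing,
# so the whole network is matrix algebra over (batch x bands) spectra.
# Consistency with the general array path is asserted in the test suite.

odc_fast_fwd <- function(x, st) {
  n <- nrow(x)
  z0 <- x %*% st$w_reduce + rep_row(st$b_reduce, n)
  z <- relu(z0)
  ac <- sigmoid(z %*% st$w_channel + rep_row(st$b_channel, n))
  af <- sigmoid(z %*% st$w_filter + rep_row(st$b_filter, n))
  as_ <- sigmoid(z %*% st$w_spatial + rep_row(st$b_spatial, n))
  awl <- (z %*% st$w_kernel + rep_row(st$b_kernel, n)) / st$temperature
  aw <- softmax_rows(awl)
  wk <- lapply(seq_len(st$n_kernels),
               function(k) matrix(st$kernels[k, , , 1L, 1L], st$c_out, st$c_in))
  u <- x * ac
  vk <- lapply(wk, function(w) u %*% t(w))
  y0 <- matrix(0, n, st$c_out)
  for (k in seq_len(st$n_kernels)) y0 <- y0 + aw[, k] * vk[[k]]
  y <- as.vector(as_) * af * y0 + rep_row(st$bias, n)
  list(y = y, cache = list(x = x, z0 = z0, z = z, ac = ac, af = af, as_ = as_,
                           aw = aw, wk = wk, u = u, vk = vk, y0 = y0))
}

lsk_fast_fwd <- function(x, p, improved) {
  n <- nrow(x); ch <- p$channels
  if (improved) {
    e <- x %*% p$w_embed
    v <- e %*% p$w_v
    r <- v %*% p$w_out + rep_row(p$b_out, n)
    x1 <- x + r
  } else {
    e <- v <- NULL
    x1 <- x
  }
  c1 <- p$dw1[, (p$branch_kernels[1] + 1L) %/% 2L, (p$branch_kernels[1] + 1L) %/% 2L]
  c2 <- p$dw2[, (p$branch_kernels[2] + 1L) %/% 2L, (p$branch_kernels[2] + 1L) %/% 2L]
  d1 <- x1 * rep_row(c1, n) + rep_row(p$b_dw1, n)
  d2 <- d1 * rep_row(c2, n) + rep_row(p$b_dw2, n)
  u1 <- d1 %*% p$proj1 + rep_row(p$b_proj1, n)
  u2 <- d2 %*% p$proj2 + rep_row(p$b_proj2, n)
  ucat <- cbind(u1, u2)
  avg <- rowMeans(ucat)
  mx_idx <- max.col(ucat, ties.method = "first")
  mx <- ucat[cbind(seq_len(n), mx_idx)]
  kc <- (p$attn_kernel + 1L) %/% 2L
  wc <- matrix(p$attn_w[, , kc, kc], 2L, 2L)    # [out, in]
  raw <- cbind(avg, mx) %*% t(wc) + rep_row(p$attn_b, n)
  m <- sigmoid(raw)
  pre <- m[, 1L] * u1 + m[, 2L] * u2
  s <- pre %*% p$fuse_w + rep_row(p$b_fuse, n)
  list(y = s, cache = list(x = x, e = e, v = v, x1 = x1, c1 = c1, c2 = c2,
                           d1 = d1, d2 = d2, u1 = u1, u2 = u2, avg = avg,
                           mx = mx, mx_idx = mx_idx, wc = wc, raw = raw,
                           m = m, pre = pre))
}

net_forward <- function(net, x, keep_cache = FALSE) {
  cfg <- net$config
  x <- as.matrix(x)
  if (ncol(x) != cfg$bands) {
    stop_dynspec("input has ", ncol(x), " bands; network expects ", cfg$bands)
  }
  n <- nrow(x)
  odc_out <- if (cfg$use_odc) odc_fast_fwd(x, net$odc) else list(y = x)
  lsk_out <- if (cfg$use_lsk) lsk_fast_fwd(x, net$lsk, cfg$improved_lsk)
             else list(y = x)
  fused <- fuse_parallel(odc_out$y, lsk_out$y, cfg$fusion)
  t_steps <- ncol(fused)
  xs <- lapply(seq_len(t_steps), function(t) fused[, t, drop = FALSE])
  gru_caches <- vector("list", length(net$gru))
  for (l in seq_along(net$gru)) {
    fw <- gru_layer_fwd(xs, net$gru[[l]])
    gru_caches[[l]] <- fw
    xs <- fw$h_seq
  }
  h_final <- xs[[length(xs)]]
  a1 <- h_final %*% net$mlp$w1 + rep_row(net$mlp$b1, n)
  z1 <- if (cfg$head_activation == "relu") relu(a1) else sigmoid(a1)
  logits <- z1 %*% net$mlp$w2 + rep_row(net$mlp$b2, n)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- list(x = x, odc = odc_out, lsk = lsk_out, fused = fused,
                      gru = gru_caches, h_final = h_final, a1 = a1, z1 = z1)
  }
  out
}

#' Class probabilities from the full network
#'
#' Runs the complete pipeline on pixel spectra: parallel branch extraction,
#' fusion, band-sequence reshaping, stacked GRU, MLP head, softmax.
#'
#' @param net a [build_network()] object.
#' @param x matrix `(batch, bands)` of pixel spectra.
#' @return matrix `(batch, n_classes)` of class probabilities; rows sum
#'   to 1.
#' @examples
#' cfg <- network_config(4, 3, gru_hidden = 8, mlp_hidden = 16,
#'                       odconv = list(n_kernels = 2), lsk = list(heads = 2))
#' net <- build_network(cfg, seed = 1)
#' rowSums(forward_probs(net, matrix(runif(8), 2, 4)))
#' @export
forward_probs <- function(net, x) {
  net_forward(net, x)$probs
}
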