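#' Large-selective-kernel block parameters
#'
#' The block decomposes a large receptive field into two serial depthwise
#' branches — a 5x5 depthwise convolution, then a 7x7 depthwise convolution
#' with dilation 3 applied to the first branch's output — each followed by a
#' 1x1 channel projection. Channel-pooled spatial descriptors (mean and max)
#' are mapped by a small convolution to one raw attention map per branch,
#' squashed to sigmoid selection masks, and the masked branches are fused by
#' a final 1x1 convolution. The improved variant additionally refines the
#' block input with multi-head self-attention over spatial tokens before the
#' decomposition (a residual refinement).
#'
#' @param channels channel count `C` the block operates on.
#' @param branch_kernels depthwise kernel sizes for the two branches.
#' @param dilations dilation for each depthwise branch.
#' @param attn_kernel kernel size of the 2-to-N attention convolution.
#' @param heads number of attention heads in the refinement.
#' @param embed_dim token embedding width `d`; defaults to `channels`
#'   rounded up to a multiple of `heads`.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `lsk_params`.
#' @export
lsk_params <- function(channels, branch_kernels = c(5L, 7L),
                       dilations = c(1L, 3L), attn_kernel = 7L,
                       heads = 4L, embed_dim = NULL, seed = 1L) {
  stopifnot(length(branch_kernels) == 2L, length(dilations) == 2L)
  if (heads < 1L) stop_dynspec("`heads` must be >= 1")
  set.seed(as.integer(seed))
  d <- embed_dim %||% (ceiling(channels / heads) * heads)
  if (d %% heads != 0L) stop_dynspec("`embed_dim` must be divisible by `heads`")
  k1 <- branch_kernels[1]; k2 <- branch_kernels[2]
  ka <- attn_kernel
  p <- list(
    dw1 = init_weights(c(channels, k1, k1), k1 * k1), b_dw1 = rep(0, channels),
    dw2 = init_weights(c(channels, k2, k2), k2 * k2), b_dw2 = rep(0, channels),
    proj1 = init_weights(c(channels, channels), channels), b_proj1 = rep(0, channels),
    proj2 = init_weights(c(channels, channels), channels), b_proj2 = rep(0, channels),
    attn_w = init_weights(c(2L, 2L, ka, ka), 2 * ka * ka), attn_b = rep(0, 2L),
    fuse_w = init_weights(c(channels, channels), channels), b_fuse = rep(0, channels),
    w_embed = init_weights(c(channels, d), channels),
    w_q = init_weights(c(d, d), d), w_k = init_weights(c(d, d), d),
    w_v = init_weights(c(d, d), d),
    w_out = init_weights(c(d, channels), d), b_out = rep(0, channels)
  )
  p$channels <- channels
  p$branch_kernels <- as.integer(branch_kernels)
  p$dilations <- as.integer(dilations)
  p$attn_kernel <- as.integer(ka)
  p$heads <- as.integer(heads)
  p$embed_dim <- as.integer(d)
  class(p) <- "lsk_params"
  p
}

#' Decompose a feature map into large-kernel depthwise branches
#'
#' @param x feature maps `(batch, C, H, W)`.
#' @param params an [lsk_params()].
#' @return list with `branches` (list of two `(batch, C, H, W)` arrays,
#'   after the 1x1 projections) and `concat` (`(batch, 2C, H, W)`).
#' @export
decompose_large_kernel <- function(x, params) {
  d <- dim(x)
  if (d[2] != params$channels) stop_dynspec("channel mismatch: ", d[2], " vs ", params$channels)
  d1 <- depthwise_conv2d_batch(x, params$dw1, params$b_dw1, params$dilations[1])
  d2 <- depthwise_conv2d_batch(d1, params$dw2, params$b_dw2, params$dilations[2])
  u1 <- conv1x1_batch(d1, params$proj1, params$b_proj1)
  u2 <- conv1x1_batch(d2, params$proj2, params$b_proj2)
  concat <- array(0, c(d[1], 2L * d[2], d[3], d[4]))
  concat[, seq_len(d[2]), , ] <- u1
  concat[, d[2] + seq_len(d[2]), , ] <- u2
  list(branches = list(u1, u2), concat = concat)
}

# 1x1 convolution expressed as a channel-mixing matrix (C_out x C_in rows
# indexed [out, in] stored as w[in, out] for matrix multiply convenience).
conv1x1_batch <- function(x, w, bias = NULL) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(2L, 1L, 3L, 4L)), d[2], d[1] * d[3] * d[4])
  ym <- t(w) %*% xm
  if (!is.null(bias)) ym <- ym + bias
  aperm(array(ym, c(ncol(w), d[1], d[3], d[4])), c(2L, 1L, 3L, 4L))
}

#' Channel-pooled spatial descriptors
#'
#' Mean and max over the channel axis, keeping a singleton channel.
#'
#' @param u feature maps `(batch, C, H, W)` (typically the branch
#'   concatenation).
#' @return list with `avg` and `max`, both `(batch, 1, H, W)`.
#' @export
pool_descriptors <- function(u) {
  d <- dim(u)
  if (d[2] < 1L) stop_dynspec("empty channel axis")
  avg <- array(apply(u, c(1L, 3L, 4L), mean), c(d[1], 1L, d[3], d[4]))
  mx <- array(apply(u, c(1L, 3L, 4L), max), c(d[1], 1L, d[3], d[4]))
  list(avg = avg, max = mx)
}

#' Raw spatial attention maps from pooled descriptors
#'
#' Concatenates the two descriptors channel-wise and applies a padded
#' 2-to-N convolution (N = branch count).
#'
#' @param desc descriptor list from [pool_descriptors()].
#' @param params an [lsk_params()].
#' @return raw attentions `(batch, N, H, W)`.
#' @export
spatial_attention_maps <- function(desc, params) {
  d <- dim(desc$avg)
  x <- array(0, c(d[1], 2L, d[3], d[4]))
  x[, 1L, , ] <- desc$avg
  x[, 2L, , ] <- desc$max
  conv2d_batch(x, params$attn_w, params$attn_b)
}

#' Sigmoid selection masks
#'
#' @param raw raw attention maps `(batch, N, H, W)`.
#' @return masks of the same shape, every value strictly in (0, 1).
#' @export
selection_masks <- function(raw) {
  sigmoid(raw)
}

#' Fuse masked branches
#'
#' Computes `S = F(sum_i mask_i * U_i)` where the per-branch masks broadcast
#' over channels and `F` is a 1x1 convolution restoring `C` channels.
#'
#' @param branches list of `(batch, C, H, W)` branch arrays.
#' @param masks `(batch, N, H, W)` selection masks.
#' @param params an [lsk_params()].
#' @return fused feature `(batch, C, H, W)`.
#' @export
fuse_selected <- function(branches, masks, params) {
  nb <- length(branches)
  if (dim(masks)[2] != nb) {
    stop_dynspec("mask count (", dim(masks)[2], ") != branch count (", nb, ")")
  }
  d <- dim(branches[[1]])
  pre <- array(0, d)
  for (i in seq_len(nb)) {
    mi <- array(masks[, i, , ], c(d[1], d[3], d[4]))
    mfull <- aperm(array(mi, c(d[1], d[3], d[4], d[2])), c(1L, 4L, 2L, 3L))
    pre <- pre + branches[[i]] * mfull
  }
  conv1x1_batch(pre, params$fuse_w, params$b_fuse)
}

#' Multi-head self-attention refinement
#'
#' Flattens the spatial positions to a token sequence, embeds channels to
#' width `d`, applies scaled-dot-product multi-head self-attention over the
#' tokens, projects back to `C` channels and adds the result to the input
#' (residual refinement).
#'
#' @param x feature maps `(batch, C, H, W)`.
#' @param params an [lsk_params()].
#' @param heads overrides the head count in `params` when given.
#' @return refined feature maps, same shape as `x`.
#' @export
multihead_refine <- function(x, params, heads = NULL) {
  heads <- heads %||% params$heads
  if (heads < 1L) stop_dynspec("`heads` must be >= 1")
  d <- dim(x)
  dd <- params$embed_dim
  if (dd %% heads != 0L) stop_dynspec("embed_dim not divisible by heads")
  dh <- dd %/% heads
  out <- array(0, d)
  for (b in seq_len(d[1])) {
    xt <- t(matrix(array(x[b, , , ], d[-1]), d[2], d[3] * d[4]))  # tokens x C
    e <- xt %*% params$w_embed                                    # tokens x d
    q <- e %*% params$w_q; k <- e %*% params$w_k; v <- e %*% params$w_v
    ctx <- matrix(0, nrow(e), dd)
    for (h in seq_len(heads)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      a <- softmax_rows(q[, cols, drop = FALSE] %*%
                          t(k[, cols, drop = FALSE]) / sqrt(dh))
      ctx[, cols] <- a %*% v[, cols, drop = FALSE]
    }
    r <- ctx %*% params$w_out + rep(params$b_out, each = nrow(e))  # tokens x C
    out[b, , , ] <- array(t(r), c(d[2], d[3], d[4]))
  }
  x + out
}

#' Full (improved) large-selective-kernel block
#'
#' Pipeline: optional multi-head refinement of the input, depthwise
#' decomposition, channel pooling, 2-to-N attention convolution, sigmoid
#' selection masks, mask-weighted fusion. With `improved = FALSE` the
#' refinement stage is skipped entirely (the plain-LSK ablation arm).
#'
#' @inheritParams multihead_refine
#' @param improved apply the multi-head refinement stage?
#' @return fused feature `(batch, C, H, W)` with attribute
#'   `refine_applied` recording whether the refinement ran.
#' @examples
#' p <- lsk_params(3, heads = 1, seed = 2)
#' x <- array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4))
#' dim(lsk_block(x, p))
#' @export
lsk_block <- function(x, params, improved = TRUE) {
  x1 <- if (improved) multihead_refine(x, params) else x
  dec <- decompose_large_kernel(x1, params)
  desc <- pool_descriptors(dec$concat)
  raw <- spatial_attention_maps(desc, params)
  masks <- selection_masks(raw)
  s <- fuse_selected(dec$branches, masks, params)
  attr(s, "refine_applied") <- isTRUE(improved)
  s
}
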