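# Analytic gradients for the deployed pixel-spectrum (patch = 1)
# configuration. Structure mirrors the forward caches in network.R; the
# whole chain is validated against central-difference numerical gradients
# in the test suite.

ODC_TRAINABLE <- c("kernels", "bias", "w_reduce", "b_reduce", "w_spatial",
                   "b_spatial", "w_channel", "b_channel", "w_filter",
                   "b_filter", "w_kernel", "b_kernel")
LSK_TRAINABLE <- c("dw1", "b_dw1", "dw2", "b_dw2", "proj1", "b_proj1",
                   "proj2", "b_proj2", "attn_w", "attn_b", "fuse_w",
                   "b_fuse", "w_embed", "w_q", "w_k", "w_v", "w_out",
                   "b_out")
GRU_TRAINABLE <- c("wxz", "whz", "bz", "wxr", "whr", "br", "wxh", "whh", "bh")
MLP_TRAINABLE <- c("w1", "b1", "w2", "b2")

# Extract the nested list of trainable arrays for the active configuration.
get_trainable <- function(net) {
  out <- list()
  if (net$config$use_odc) out$odc <- net$odc[ODC_TRAINABLE]
  if (net$config$use_lsk) out$lsk <- net$lsk[LSK_TRAINABLE]
  out$gru <- lapply(net$gru, function(l) l[GRU_TRAINABLE])
  out$mlp <- net$mlp[MLP_TRAINABLE]
  out
}

set_trainable <- function(net, params) {
  if (!is.null(params$odc)) net$odc[ODC_TRAINABLE] <- params$odc
  if (!is.null(params$lsk)) net$lsk[LSK_TRAINABLE] <- params$lsk
  for (l in seq_along(net$gru)) net$gru[[l]][GRU_TRAINABLE] <- params$gru[[l]]
  net$mlp[MLP_TRAINABLE] <- params$mlp
  net
}

odc_fast_bwd <- function(dy, st, cache) {
  n <- nrow(dy)
  x <- cache$x; z0 <- cache$z0; z <- cache$z
  ac <- cache$ac; af <- cache$af; as_ <- cache$as_; aw <- cache$aw
  u <- cache$u; vk <- cache$vk; y0 <- cache$y0

  db_out <- colSums(dy)
  as_v <- as.vector(as_)
  daf <- as_v * dy * y0
  dy0 <- as_v * af * dy
  das <- rowSums(dy * af * y0)

  nk <- st$n_kernels
  daw <- matrix(0, n, nk)
  du <- matrix(0, n, st$c_in)
  dkern <- array(0, dim(st$kernels))
  for (k in seq_len(nk)) {
    daw[, k] <- rowSums(dy0 * vk[[k]])
    dvk <- dy0 * aw[, k]
    dkern[k, , , 1L, 1L] <- t(dvk) %*% u
    du <- du + dvk %*% cache$wk[[k]]
  }
  dx_conv <- du * ac
  dac <- du * x

  dacl <- dac * ac * (1 - ac)
  dafl <- daf * af * (1 - af)
  dasl <- (das * as_v * (1 - as_v))
  dawl <- (daw - rowSums(daw * aw)) * aw / st$temperature

  dz <- dacl %*% t(st$w_channel) + dafl %*% t(st$w_filter) +
    matrix(dasl, n, 1L) %*% t(st$w_spatial) + dawl %*% t(st$w_kernel)
  dz0 <- dz * (z0 > 0)
  dx <- dx_conv + dz0 %*% t(st$w_reduce)

  grads <- list(
    kernels = dkern, bias = db_out,
    w_reduce = t(x) %*% dz0, b_reduce = colSums(dz0),
    w_spatial = t(z) %*% matrix(dasl, n, 1L), b_spatial = sum(dasl),
    w_channel = t(z) %*% dacl, b_channel = colSums(dacl),
    w_filter = t(z) %*% dafl, b_filter = colSums(dafl),
    w_kernel = t(z) %*% dawl, b_kernel = colSums(dawl))
  list(grads = grads, dx = dx)
}

lsk_fast_bwd <- function(ds, p, cache, improved) {
  n <- nrow(ds); ch <- p$channels
  u1 <- cache$u1; u2 <- cache$u2; m <- cache$m

  db_fuse <- colSums(ds)
  dfuse_w <- t(cache$pre) %*% ds
  dpre <- ds %*% t(p$fuse_w)

  dm <- cbind(rowSums(dpre * u1), rowSums(dpre * u2))
  du1 <- m[, 1L] * dpre
  du2 <- m[, 2L] * dpre

  draw <- dm * m * (1 - m)
  dattn_b <- colSums(draw)
  dwc <- t(draw) %*% cbind(cache$avg, cache$mx)
  davgmx <- draw %*% cache$wc
  # avg/max pooling over the 2C concatenated channels
  ducat <- matrix(davgmx[, 1L] / (2 * ch), n, 2L * ch)
  ducat[cbind(seq_len(n), cache$mx_idx)] <-
    ducat[cbind(seq_len(n), cache$mx_idx)] + davgmx[, 2L]
  du1 <- du1 + ducat[, seq_len(ch), drop = FALSE]
  du2 <- du2 + ducat[, ch + seq_len(ch), drop = FALSE]

  dproj1 <- t(cache$d1) %*% du1; db_proj1 <- colSums(du1)
  dproj2 <- t(cache$d2) %*% du2; db_proj2 <- colSums(du2)
  dd2 <- du2 %*% t(p$proj2)
  dd1 <- du1 %*% t(p$proj1) + dd2 * rep_row(cache$c2, n)
  dc2 <- colSums(dd2 * cache$d1); db_dw2 <- colSums(dd2)
  dx1 <- dd1 * rep_row(cache$c1, n)
  dc1 <- colSums(dd1 * cache$x1); db_dw1 <- colSums(dd1)

  ddw1 <- array(0, dim(p$dw1))
  ddw2 <- array(0, dim(p$dw2))
  k1c <- (p$branch_kernels[1] + 1L) %/% 2L
  k2c <- (p$branch_kernels[2] + 1L) %/% 2L
  ddw1[, k1c, k1c] <- dc1
  ddw2[, k2c, k2c] <- dc2
  dattn_w <- array(0, dim(p$attn_w))
  kc <- (p$attn_kernel + 1L) %/% 2L
  dattn_w[, , kc, kc] <- dwc

  grads <- list(dw1 = ddw1, b_dw1 = db_dw1, dw2 = ddw2, b_dw2 = db_dw2,
                proj1 = dproj1, b_proj1 = db_proj1,
                proj2 = dproj2, b_proj2 = db_proj2,
                attn_w = dattn_w, attn_b = dattn_b,
                fuse_w = dfuse_w, b_fuse = db_fuse,
                w_embed = array(0, dim(p$w_embed)),
                w_q = array(0, dim(p$w_q)), w_k = array(0, dim(p$w_k)),
                w_v = array(0, dim(p$w_v)),
                w_out = array(0, dim(p$w_out)), b_out = rep(0, ch))
  if (improved) {
    dr <- dx1                     # x1 = x + r
    grads$w_out <- t(cache$v) %*% dr
    grads$b_out <- colSums(dr)
    dv <- dr %*% t(p$w_out)
    grads$w_v <- t(cache$e) %*% dv
    de <- dv %*% t(p$w_v)
    grads$w_embed <- t(cache$x) %*% de
    dx <- dx1 + de %*% t(p$w_embed)
  } else {
    dx <- dx1
  }
  list(grads = grads, dx = dx)
}

gru_layer_bwd <- function(p, fw, dh_seq) {
  steps <- fw$steps
  t_len <- length(steps)
  n <- nrow(dh_seq[[t_len]])
  g <- lapply(p[GRU_TRAINABLE], function(a) array(0, dim(a) %||% length(a)))
  g <- stats::setNames(g, GRU_TRAINABLE)
  dx_seq <- vector("list", t_len)
  dh_carry <- matrix(0, n, ncol(p$whz))
  for (t in rev(seq_len(t_len))) {
    st <- steps[[t]]
    dh <- dh_carry + (dh_seq[[t]] %||% 0)
    dz <- dh * (st$h_prev - st$hc)
    dhc <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    dhc_pre <- dhc * (1 - st$hc^2)
    g$wxh <- g$wxh + t(st$x) %*% dhc_pre
    g$bh <- g$bh + colSums(dhc_pre)
    dr <- dhc_pre * st$q
    dq <- dhc_pre * st$r
    g$whh <- g$whh + t(st$h_prev) %*% dq
    dh_prev <- dh_prev + dq %*% t(p$whh)
    dz_pre <- dz * st$z * (1 - st$z)
    dr_pre <- dr * st$r * (1 - st$r)
    g$wxz <- g$wxz + t(st$x) %*% dz_pre
    g$whz <- g$whz + t(st$h_prev) %*% dz_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$wxr <- g$wxr + t(st$x) %*% dr_pre
    g$whr <- g$whr + t(st$h_prev) %*% dr_pre
    g$br <- g$br + colSums(dr_pre)
    dh_prev <- dh_prev + dz_pre %*% t(p$whz) + dr_pre %*% t(p$whr)
    dx_seq[[t]] <- dhc_pre %*% t(p$wxh) + dz_pre %*% t(p$wxz) +
      dr_pre %*% t(p$wxr)
    dh_carry <- dh_prev
  }
  list(grads = g, dx_seq = dx_seq)
}

# Full backward pass; dlogits is the gradient of the scalar loss w.r.t.
# the logits (for mean cross-entropy: (probs - onehot) / n).
net_backward <- function(net, cache, dlogits) {
  cfg <- net$config
  n <- nrow(dlogits)
  grads <- list()

  # MLP head
  dz1 <- dlogits %*% t(net$mlp$w2)
  da1 <- if (cfg$head_activation == "relu") dz1 * (cache$a1 > 0)
         else dz1 * cache$z1 * (1 - cache$z1)
  grads$mlp <- list(
    w1 = t(cache$h_final) %*% da1, b1 = colSums(da1),
    w2 = t(cache$z1) %*% dlogits, b2 = colSums(dlogits))
  dh_final <- da1 %*% t(net$mlp$w1)

  # stacked GRU (top layer gets loss gradient at the final step only;
  # lower layers receive the per-step input gradients of the layer above)
  n_layers <- length(net$gru)
  t_len <- length(cache$gru[[1]]$steps)
  grads$gru <- vector("list", n_layers)
  dh_seq <- vector("list", t_len)
  dh_seq[[t_len]] <- dh_final
  for (t in seq_len(t_len - 1L)) dh_seq[[t]] <- matrix(0, n, ncol(dh_final))
  for (l in rev(seq_len(n_layers))) {
    bw <- gru_layer_bwd(net$gru[[l]], cache$gru[[l]], dh_seq)
    grads$gru[[l]] <- bw$grads
    dh_seq <- bw$dx_seq
  }
  dfused <- do.call(cbind, dh_seq)    # (n x T) per-step scalars

  # fusion
  if (cfg$fusion == "add") {
    dodc <- dfused; dlsk <- dfused
  } else {
    dodc <- dfused[, seq_len(cfg$bands), drop = FALSE]
    dlsk <- dfused[, cfg$bands + seq_len(cfg$bands), drop = FALSE]
  }

  dx <- matrix(0, n, cfg$bands)
  if (cfg$use_odc) {
    bo <- odc_fast_bwd(dodc, net$odc, cache$odc$cache)
    grads$odc <- bo$grads
    dx <- dx + bo$dx
  } else {
    dx <- dx + dodc
  }
  if (cfg$use_lsk) {
    bl <- lsk_fast_bwd(dlsk, net$lsk, cache$lsk$cache, cfg$improved_lsk)
    grads$lsk <- bl$grads
    dx <- dx + bl$dx
  } else {
    dx <- dx + dlsk
  }
  # order grads as get_trainable() does
  out <- list()
  if (cfg$use_odc) out$odc <- grads$odc
  if (cfg$use_lsk) out$lsk <- grads$lsk
  out$gru <- grads$gru
  out$mlp <- grads$mlp
  list(grads = out, dx = dx)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = map_params(params, function(a) a * 0),
       v = map_params(params, function(a) a * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_params(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map2_params(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- map2_params(params, upd, function(p, u) p - lr * u)
  list(params = params, state = state)
}
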