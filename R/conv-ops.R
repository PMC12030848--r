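# 2-d convolution primitives on (channel, height, width) arrays.
# Stride is always 1 and zero "same" padding is applied, so odd kernels
# preserve the spatial extent. These run on the small feature maps of the
# attention blocks; clarity is preferred over raw speed.

# x: (C_in, H, W); w: (C_out, C_in, kh, kw); dilation applies to both axes.
conv2d_chw <- function(x, w, bias = NULL, dilation = 1L) {
  dx <- dim(x); dw <- dim(w)
  stopifnot(length(dx) == 3L, length(dw) == 4L, dx[1] == dw[2])
  c_out <- dw[1]; kh <- dw[3]; kw <- dw[4]
  h <- dx[2]; wd <- dx[3]
  ph <- dilation * (kh - 1L) %/% 2L
  pw <- dilation * (kw - 1L) %/% 2L
  xp <- array(0, c(dx[1], h + 2L * ph, wd + 2L * pw))
  xp[, ph + seq_len(h), pw + seq_len(wd)] <- x
  out <- matrix(0, c_out, h * wd)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      xs <- xp[, (u - 1L) * dilation + seq_len(h),
               (v - 1L) * dilation + seq_len(wd), drop = FALSE]
      out <- out + matrix(w[, , u, v], c_out, dx[1]) %*%
        matrix(xs, dx[1], h * wd)
    }
  }
  if (!is.null(bias)) out <- out + bias
  array(out, c(c_out, h, wd))
}

# Depthwise variant: w is (C, kh, kw), each channel convolved with its own
# single-channel kernel.
depthwise_conv2d_chw <- function(x, w, bias = NULL, dilation = 1L) {
  dx <- dim(x); dw <- dim(w)
  stopifnot(length(dx) == 3L, length(dw) == 3L, dx[1] == dw[1])
  kh <- dw[2]; kw <- dw[3]
  h <- dx[2]; wd <- dx[3]
  ph <- dilation * (kh - 1L) %/% 2L
  pw <- dilation * (kw - 1L) %/% 2L
  xp <- array(0, c(dx[1], h + 2L * ph, wd + 2L * pw))
  xp[, ph + seq_len(h), pw + seq_len(wd)] <- x
  out <- array(0, dx)
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      xs <- xp[, (u - 1L) * dilation + seq_len(h),
               (v - 1L) * dilation + seq_len(wd), drop = FALSE]
      out <- out + as.vector(w[, u, v]) * xs
    }
  }
  if (!is.null(bias)) out <- out + as.vector(bias)
  out
}

# Batched wrappers over (B, C, H, W) arrays.
conv2d_batch <- function(x, w, bias = NULL, dilation = 1L) {
  db <- dim(x)
  out <- NULL
  for (b in seq_len(db[1])) {
    r <- conv2d_chw(array(x[b, , , ], db[-1]), w, bias, dilation)
    if (is.null(out)) out <- array(0, c(db[1], dim(r)))
    out[b, , , ] <- r
  }
  out
}

depthwise_conv2d_batch <- function(x, w, bias = NULL, dilation = 1L) {
  db <- dim(x)
  out <- array(0, db)
  for (b in seq_len(db[1])) {
    out[b, , , ] <- depthwise_conv2d_chw(array(x[b, , , ], db[-1]), w,
                                         bias, dilation)
  }
  out
}

# Coerce an n x C matrix of pixel spectra to the (B, C, 1, 1) layout the
# spatial modules expect, and back.
spectra_to_maps <- function(x) {
  x <- as.matrix(x)
  array(x, c(nrow(x), ncol(x), 1L, 1L))
}

maps_to_spectra <- function(x) {
  d <- dim(x)
  stopifnot(d[3] == 1L, d[4] == 1L)
  matrix(x, d[1], d[2])
}
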