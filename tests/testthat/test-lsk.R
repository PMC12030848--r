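test_that("branch decomposition preserves shape and recovers identity kernels", {
  p <- lsk_params(3, heads = 1, seed = 1)
  set.seed(2)
  for (hw in list(c(1, 1), c(5, 8))) {
    x <- array(rnorm(2 * 3 * hw[1] * hw[2]), c(2, 3, hw[1], hw[2]))
    dec <- decompose_large_kernel(x, p)
    expect_equal(dim(dec$branches[[1]]), dim(x))
    expect_equal(dim(dec$branches[[2]]), dim(x))
    expect_equal(dim(dec$concat), c(2, 6, hw[1], hw[2]))
  }

  # delta depthwise kernel + identity 1x1 projection leaves branch 1 = x
  pid <- p
  pid$dw1[] <- 0; pid$dw1[, 3, 3] <- 1; pid$b_dw1[] <- 0
  pid$proj1 <- diag(3); pid$b_proj1[] <- 0
  x <- array(rnorm(1 * 3 * 6 * 6), c(1, 3, 6, 6))
  dec <- decompose_large_kernel(x, pid)
  expect_equal(dec$branches[[1]], x, tolerance = 1e-12)

  # zero weights and biases give zero branches
  pz <- p
  for (nm in c("dw1", "b_dw1", "dw2", "b_dw2", "proj1", "b_proj1",
               "proj2", "b_proj2")) pz[[nm]][] <- 0
  dec0 <- decompose_large_kernel(x, pz)
  expect_equal(max(abs(dec0$concat)), 0)
})

test_that("channel pooling computes mean and max descriptors", {
  u <- array(2.5, c(1, 4, 3, 3))
  d <- pool_descriptors(u)
  expect_equal(as.vector(d$avg), rep(2.5, 9))
  expect_equal(as.vector(d$max), rep(2.5, 9))

  u2 <- array(0, c(1, 2, 1, 1)); u2[1, , 1, 1] <- c(1, 3)
  d2 <- pool_descriptors(u2)
  expect_equal(as.vector(d2$avg), 2)
  expect_equal(as.vector(d2$max), 3)

  set.seed(3)
  u3 <- array(rnorm(2 * 5 * 4 * 4), c(2, 5, 4, 4))
  d3 <- pool_descriptors(u3)
  expect_true(all(d3$max >= d3$avg))
})

test_that("attention maps have branch-count channels and obey hand arithmetic", {
  p <- lsk_params(3, heads = 1, seed = 4)
  desc <- list(avg = array(0, c(2, 1, 4, 4)), max = array(0, c(2, 1, 4, 4)))
  pz <- p; pz$attn_w[] <- 0; pz$attn_b[] <- 0
  raw0 <- spatial_attention_maps(desc, pz)
  expect_equal(dim(raw0), c(2, 2, 4, 4))
  expect_equal(max(abs(raw0)), 0)

  # single pixel: only the kernel centre sees data -> 2x2 matrix product
  ph <- p
  ph$attn_w[] <- 0
  ph$attn_w[, , 4, 4] <- matrix(c(1, -1, 2, 0.5), 2, 2)  # [out, in]
  ph$attn_b <- c(0.1, -0.2)
  d1 <- list(avg = array(3, c(1, 1, 1, 1)), max = array(5, c(1, 1, 1, 1)))
  raw <- spatial_attention_maps(d1, ph)
  expect_equal(as.vector(raw),
               c(1 * 3 + 2 * 5 + 0.1, -1 * 3 + 0.5 * 5 - 0.2),
               tolerance = 1e-12)
})

test_that("selection masks are sigmoid: half at zero, bounded, monotone", {
  raw <- array(c(0, -2, 2, 20, -20, 0.3), c(1, 2, 3, 1))
  m <- selection_masks(raw)
  expect_equal(m[1, 1, 1, 1], 0.5)
  expect_true(all(m > 0 & m < 1))
  ord <- order(as.vector(raw))
  expect_equal(order(as.vector(m)), ord)
})

test_that("mask-weighted fusion matches a nested-loop reference", {
  p <- lsk_params(4, heads = 2, seed = 5)
  set.seed(6)
  x <- array(rnorm(2 * 4 * 5 * 5), c(2, 4, 5, 5))
  dec <- decompose_large_kernel(x, p)
  masks <- selection_masks(spatial_attention_maps(pool_descriptors(dec$concat), p))
  got <- fuse_selected(dec$branches, masks, p)

  for (b in 1:2) {
    pre <- array(0, c(4, 5, 5))
    for (c in 1:4) for (i in 1:5) for (j in 1:5) {
      pre[c, i, j] <- masks[b, 1, i, j] * dec$branches[[1]][b, c, i, j] +
        masks[b, 2, i, j] * dec$branches[[2]][b, c, i, j]
    }
    ref <- array(0, c(4, 5, 5))
    for (o in 1:4) for (i in 1:5) for (j in 1:5) {
      ref[o, i, j] <- sum(p$fuse_w[, o] * pre[, i, j]) + p$b_fuse[o]
    }
    expect_lt(max(abs(got[b, , , ] - ref)), 1e-5)
  }

  # identical branches distribute: pre-F tensor = (m1 + m2) * U
  u <- dec$branches[[1]]
  got2 <- fuse_selected(list(u, u), masks, p)
  msum <- masks[, 1, , ] + masks[, 2, , ]
  pre2 <- u * aperm(array(msum, c(2, 5, 5, 4)), c(1, 4, 2, 3))
  ref2 <- got2 * 0
  for (b in 1:2) {
    ref2[b, , , ] <- conv2d_loop(array(pre2[b, , , ], c(4, 5, 5)),
                                 array(aperm(array(p$fuse_w, c(4, 4, 1, 1)),
                                             c(2, 1, 3, 4)), c(4, 4, 1, 1)),
                                 bias = p$b_fuse)
  }
  expect_equal(got2, ref2, tolerance = 1e-8)
  expect_error(fuse_selected(dec$branches[1], masks, p), "mask count")
})

test_that("multi-head refinement: single token adds pure value projection", {
  p <- lsk_params(4, heads = 2, embed_dim = 4, seed = 7)
  set.seed(8)
  x <- array(rnorm(2 * 4), c(2, 4, 1, 1))
  got <- multihead_refine(x, p)
  # with one token every attention weight is 1, so the context is just the
  # value projection of the embedded token
  for (b in 1:2) {
    xv <- x[b, , 1, 1]
    r <- (xv %*% p$w_embed %*% p$w_v %*% p$w_out)[1, ] + p$b_out
    expect_equal(got[b, , 1, 1], xv + r, tolerance = 1e-10)
  }
  expect_error(multihead_refine(x, p, heads = 0), "heads")
})

test_that("two-token single-head attention matches hand arithmetic", {
  p <- lsk_params(2, heads = 1, embed_dim = 2, seed = 9)
  p$w_embed <- diag(2)
  p$w_q <- diag(2); p$w_k <- diag(2); p$w_v <- diag(2)
  p$w_out <- diag(2); p$b_out <- c(0, 0)
  x <- array(0, c(1, 2, 2, 1))
  x[1, , 1, 1] <- c(1, 0)
  x[1, , 2, 1] <- c(0, 1)
  got <- multihead_refine(x, p)
  # tokens t1 = (1,0), t2 = (0,1); q = k = v = tokens
  # scores/sqrt(2): [ .7071 0; 0 .7071 ] -> softmax rows give
  # w_self = e^(1/sqrt 2) / (e^(1/sqrt 2) + 1)
  ws <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  ctx1 <- ws * c(1, 0) + (1 - ws) * c(0, 1)
  ctx2 <- (1 - ws) * c(1, 0) + ws * c(0, 1)
  expect_equal(got[1, , 1, 1], c(1, 0) + ctx1, tolerance = 1e-10)
  expect_equal(got[1, , 2, 1], c(0, 1) + ctx2, tolerance = 1e-10)
})

test_that("the full block preserves shape and isolates the refinement stage", {
  p <- lsk_params(4, heads = 2, seed = 10)
  set.seed(11)
  for (hw in list(c(1, 1), c(8, 8))) {
    x <- array(rnorm(2 * 4 * hw[1] * hw[2]), c(2, 4, hw[1], hw[2]))
    y_imp <- lsk_block(x, p, improved = TRUE)
    y_pln <- lsk_block(x, p, improved = FALSE)
    expect_equal(dim(y_imp), dim(x))
    expect_equal(dim(y_pln), dim(x))
    expect_true(attr(y_imp, "refine_applied"))
    expect_false(attr(y_pln, "refine_applied"))

    # deterministic
    y2 <- lsk_block(x, p, improved = TRUE)
    expect_identical(as.vector(y_imp), as.vector(y2))

    # zeroing the refinement output projection collapses improved to plain
    pz <- p; pz$w_out[] <- 0; pz$b_out[] <- 0
    expect_equal(as.vector(lsk_block(x, pz, improved = TRUE)),
                 as.vector(lsk_block(x, pz, improved = FALSE)),
                 tolerance = 1e-12)
  }

  # masks never saturate for finite inputs
  xb <- array(rnorm(1 * 4 * 6 * 6, 0, 10), c(1, 4, 6, 6))
  dec <- decompose_large_kernel(xb, p)
  m <- selection_masks(spatial_attention_maps(pool_descriptors(dec$concat), p))
  expect_true(all(m > 0 & m < 1))
})
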