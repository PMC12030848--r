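test_that("parallel fusion obeys ablation and shape contracts", {
  a <- matrix(1:6, 2, 3); b <- matrix(0, 2, 3)
  expect_equal(fuse_parallel(a, b, "add"), a)
  expect_equal(dim(fuse_parallel(a, a, "concat")), c(2, 6))
  expect_error(fuse_parallel(a, matrix(0, 2, 4), "add"), "shapes")

  # network with lsk disabled: fused input to the GRU is odc(x) + x
  cfg <- small_config(use_lsk = FALSE)
  net <- build_network(cfg, seed = 1)
  set.seed(2)
  x <- matrix(rnorm(8), 2, 4)
  fw <- dynspec:::net_forward(net, x, keep_cache = TRUE)
  expect_equal(fw$cache$fused, odconv_forward(x, net$odc) + x,
               tolerance = 1e-12)
})

test_that("band reshaping moves bands to the sequence axis losslessly", {
  x <- array(seq_len(2 * 12 * 1 * 1), c(2, 12, 1, 1))
  s <- reshape_for_rnn(x)
  expect_equal(dim(s), c(2, 12, 1))
  x2 <- array(seq_len(1 * 4 * 3 * 3), c(1, 4, 3, 3))
  s2 <- reshape_for_rnn(x2)
  expect_equal(dim(s2), c(1, 4, 9))
  expect_equal(s2[1, 2, ], as.vector(x2[1, 2, , ]))
  expect_setequal(as.vector(s2), as.vector(x2))
})

test_that("GRU recursion: zero fixed point, manual oracle, state bounds", {
  layers <- list(dynspec:::gru_layer_init(1, 4), dynspec:::gru_layer_init(4, 4))
  seq0 <- array(0, c(3, 5, 1))
  for (l in seq_along(layers)) {
    layers[[l]]$bz[] <- 0; layers[[l]]$br[] <- 0; layers[[l]]$bh[] <- 0
  }
  expect_equal(gru_forward(seq0, layers), matrix(0, 3, 4))

  # single step, single unit, hand-set scalar weights
  p <- list(wxz = matrix(0.5), whz = matrix(0.2), bz = 0.1,
            wxr = matrix(-0.3), whr = matrix(0.4), br = 0.0,
            wxh = matrix(1.0), whh = matrix(0.7), bh = -0.2)
  x <- 0.8
  z <- 1 / (1 + exp(-(0.5 * x + 0.1)))
  r <- 1 / (1 + exp(-(-0.3 * x)))
  hc <- tanh(1.0 * x + r * 0 - 0.2)
  h_expect <- z * 0 + (1 - z) * hc
  got <- gru_forward(array(x, c(1, 1, 1)), list(p))
  expect_equal(got[1, 1], h_expect, tolerance = 1e-12)

  # states bounded in (-1, 1) from a zero initial state
  set.seed(3)
  layers2 <- list(dynspec:::gru_layer_init(1, 8), dynspec:::gru_layer_init(8, 8))
  s <- array(rnorm(4 * 12 * 1, 0, 10), c(4, 12, 1))
  h <- gru_forward(s, layers2)
  expect_true(all(h > -1 & h < 1))
})

test_that("MLP head arithmetic and shape contracts", {
  mlp <- list(w1 = matrix(0, 2, 3), b1 = rep(0, 3),
              w2 = matrix(0, 3, 2), b2 = rep(0, 2))
  expect_equal(mlp_head(matrix(0, 4, 2), mlp), matrix(0, 4, 2))
  expect_error(mlp_head(matrix(0, 4, 5), mlp), "width")

  # hand-set 2 -> 3 -> 2 toy case
  mlp2 <- list(w1 = matrix(c(1, 0, -1, 1, 2, 0), 2, 3), b1 = c(0, 0.5, -1),
               w2 = matrix(c(1, 1, 0, 0, -1, 2), 3, 2), b2 = c(0.1, 0))
  h <- matrix(c(2, -1), 1, 2)
  a1 <- as.vector(h %*% mlp2$w1) + mlp2$b1
  z1 <- pmax(a1, 0)
  ref <- as.vector(z1 %*% mlp2$w2) + mlp2$b2
  expect_equal(as.vector(mlp_head(h, mlp2)), ref, tolerance = 1e-12)

  for (m in c(2L, 7L)) {
    cfg <- small_config(n_classes = m)
    net <- build_network(cfg, seed = 4)
    p <- forward_probs(net, matrix(rnorm(8), 2, 4))
    expect_equal(ncol(p), m)
  }
})

test_that("forward pass yields normalised, deterministic, batch-consistent probabilities", {
  cfg <- small_config(n_classes = 3)
  net <- build_network(cfg, seed = 5)
  set.seed(6)
  x <- matrix(rnorm(40, 0, 2), 10, 4)
  p1 <- forward_probs(net, x)
  expect_equal(rowSums(p1), rep(1, 10), tolerance = 1e-6)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, forward_probs(net, x))

  # batch-consistent: one at a time equals batched
  singly <- t(vapply(seq_len(10), function(i) {
    forward_probs(net, x[i, , drop = FALSE])[1, ]
  }, numeric(3)))
  expect_equal(singly, p1, tolerance = 1e-10)

  # large random sweep stays normalised
  xb <- matrix(rnorm(1000 * 4), 1000, 4)
  pb <- forward_probs(net, xb)
  expect_equal(rowSums(pb), rep(1, 1000), tolerance = 1e-6)
})

test_that("fast pixel path agrees with the general spatial modules", {
  cfg <- small_config(n_classes = 3)
  net <- build_network(cfg, seed = 7)
  set.seed(8)
  x <- matrix(rnorm(12), 3, 4)
  fw <- dynspec:::net_forward(net, x, keep_cache = TRUE)
  x4 <- array(x, c(3, 4, 1, 1))
  odc_gen <- odconv_forward(x4, net$odc)
  lsk_gen <- lsk_block(x4, net$lsk, improved = TRUE)
  expect_equal(fw$cache$odc$y, matrix(odc_gen, 3, 4), tolerance = 1e-10)
  expect_equal(fw$cache$lsk$y, matrix(lsk_gen, 3, 4), tolerance = 1e-10)
})

test_that("parameter count matches an independent per-layer tally", {
  cfg <- network_config(bands = 12, n_classes = 7)
  net <- build_network(cfg, seed = 9)
  counted <- dynspec:::n_params(dynspec:::get_trainable(net))

  C <- 12; M <- 7; H <- 128; Hm <- 256; K <- 4
  cr <- max(1, C %/% 4)
  d <- ceiling(C / 4) * 4
  odc <- K * C * C + C +            # candidate kernels (k = 1) + bias
    C * cr + cr +                   # bottleneck
    cr * 1 + 1 +                    # spatial head (k^2 = 1)
    cr * C + C +                    # input-channel head
    cr * C + C +                    # output-channel head
    cr * K + K                      # kernel head
  lsk <- C * 25 + C + C * 49 + C +  # depthwise 5x5 and 7x7 + biases
    C * C + C + C * C + C +         # branch projections
    2 * 2 * 49 + 2 +                # 2->N attention conv (7x7)
    C * C + C +                     # fusion 1x1
    C * d + 3 * d * d + d * C + C   # refinement: embed, q/k/v, out
  gru <- (1 * H + H * H + H) * 3 +  # layer 1
    (H * H + H * H + H) * 3         # layer 2
  mlp <- H * Hm + Hm + Hm * M + M
  expect_equal(counted, odc + lsk + gru + mlp)
})

test_that("every ablation combination builds and runs forward", {
  combos <- list(c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE),
                 c(FALSE, TRUE, FALSE), c(FALSE, TRUE, TRUE),
                 c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
  set.seed(10)
  x <- matrix(rnorm(8), 2, 4)
  for (cb in combos) {
    cfg <- small_config(n_classes = 3, use_odc = cb[1], use_lsk = cb[2],
                        improved_lsk = cb[3])
    net <- build_network(cfg, seed = 11)
    p <- forward_probs(net, x)
    expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  }
})

test_that("analytic gradients match central differences through the whole net", {
  cfg <- small_config(n_classes = 3)
  net <- build_network(cfg, seed = 12)
  set.seed(13)
  x <- matrix(runif(12, -1, 1), 3, 4)
  y <- c(1L, 2L, 3L)
  params <- dynspec:::get_trainable(net)
  pv <- dynspec:::flatten_params(params)
  unflatten <- function(v) {
    k <- 0
    walk <- function(node) {
      if (is.list(node)) return(lapply(node, walk))
      nn <- length(node); node[] <- v[k + seq_len(nn)]; k <<- k + nn; node
    }
    walk(params)
  }
  loss_at <- function(v) {
    pr <- forward_probs(dynspec:::set_trainable(net, unflatten(v)), x)
    -mean(log(pr[cbind(seq_along(y), y)]))
  }
  fw <- dynspec:::net_forward(net, x, keep_cache = TRUE)
  bw <- dynspec:::net_backward(net, fw$cache, (fw$probs - diag(3)[y, ]) / 3)
  ga <- dynspec:::flatten_params(bw$grads)
  expect_length(ga, length(pv))
  set.seed(14)
  pick <- sample(length(pv), 60)
  num <- vapply(pick, function(i) {
    up <- pv; up[i] <- up[i] + 1e-5
    dn <- pv; dn[i] <- dn[i] - 1e-5
    (loss_at(up) - loss_at(dn)) / 2e-5
  }, numeric(1))
  rel <- abs(num - ga[pick]) / pmax(abs(num) + abs(ga[pick]), 1e-4)
  expect_lt(max(rel), 1e-4)
})
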