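# Encoder-decoder architecture: block contracts, shape arithmetic, SE
# behaviour, gradient correctness and single-sample learnability.

small_cfg <- function() {
  network_config(16, n_pool = 2, channel_schedule = c(4, 8, 8),
                 se_reduction = 2)
}

test_that("conv blocks preserve spatial size, set depth, and are non-negative", {
  p <- fazseg:::with_seed(3, fazseg:::init_conv_block(2L, 5L, 3L))
  x <- matrix(rnorm(64 * 2), 64, 2)
  out <- fazseg:::conv_block_fwd(x, p, 8, 8, 3, training = TRUE)$out
  expect_equal(dim(out), c(64L, 5L))
  expect_true(all(out >= 0))
  zero <- fazseg:::conv_block_fwd(matrix(0, 64, 2), p, 8, 8, 3,
                                  training = FALSE)$out
  expect_true(all(zero == 0))  # zero input, zero bias, fresh BN stats
})

test_that("SE block is pure per-channel scaling with weights in (0,1)", {
  set.seed(4)
  p <- fazseg:::init_se(6L, 2L)
  x <- matrix(rnorm(100 * 6), 100, 6)
  r <- fazseg:::se_fwd(x, p, training = FALSE)
  expect_true(all(r$scale > 0 & r$scale < 1))
  for (c in 1:6) {
    nz <- abs(x[, c]) > 1e-8
    expect_equal(r$out[nz, c] / x[nz, c],
                 rep(r$scale[c], sum(nz)))
  }
  # zero dense weights: every scale is sigmoid(0) = 0.5, output = x/2
  p0 <- lapply(p, function(w) w * 0)
  r0 <- fazseg:::se_fwd(x, p0, training = FALSE)
  expect_equal(r0$out, x / 2)
})

test_that("max pooling halves the grid and matches a window-loop oracle", {
  set.seed(5)
  h <- 6; w <- 4
  x <- matrix(rnorm(h * w * 3), h * w, 3)
  mp <- fazseg:::cpp_maxpool2(x, h, w)
  expect_equal(dim(mp$out), c(h * w / 4L, 3L))
  for (c in 1:3) {
    grid <- matrix(x[, c], h, w)
    pooled <- matrix(mp$out[, c], h / 2, w / 2)
    for (i in seq_len(h / 2)) for (j in seq_len(w / 2)) {
      expect_equal(pooled[i, j],
                   max(grid[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]))
    }
  }
  flat <- matrix(3.5, 16, 1)
  expect_true(all(fazseg:::cpp_maxpool2(flat, 4, 4)$out == 3.5))
})

test_that("bilinear upsampling doubles the grid and preserves constants", {
  up <- fazseg:::cpp_upsample2(matrix(2.25, 12, 1), 4, 3)
  expect_equal(dim(up), c(48L, 1L))
  expect_true(all(abs(up - 2.25) < 1e-12))
})

test_that("forward pass maps input size to output size with values in (0,1)", {
  cfg <- small_cfg()
  p <- init_network(cfg, seed = 1)
  img <- matrix(runif(16 * 16), 16, 16)
  prob <- predict_probmap(p, cfg, img)
  expect_equal(dim(prob), c(16L, 16L))
  expect_true(all(prob > 0 & prob < 1))
  expect_error(predict_probmap(p, cfg, matrix(0, 8, 8)), "16 x 16")
})

test_that("decoder concatenation fuses upsampled and skip channels", {
  cfg <- small_cfg()
  p <- init_network(cfg, seed = 1)
  x <- matrix(runif(256), 256, 1)
  fw <- fazseg:::network_forward(p, x, cfg, training = TRUE)
  s <- cfg$channel_schedule
  # U1 fuses the bottleneck (s[3]) with the deepest skip (s[3])
  expect_equal(fw$cache$up[[1]]$d_up, s[3])
  expect_equal(fw$cache$up[[1]]$d_skip, s[3])
  # U2 fuses U1's output (s[2]) with the shallow skip (s[2])
  expect_equal(fw$cache$up[[2]]$d_up, s[2])
  expect_equal(fw$cache$up[[2]]$d_skip, s[2])
})

test_that("shape trace reproduces the reference 704-pixel geometry", {
  tr <- shape_trace(network_config(704))
  expect_equal(tr$h[tr$block == "P5"], 22)
  expect_equal(tr$w[tr$block == "P5"], 22)
  expect_equal(tr$h[tr$block == "U5"], 704)
  expect_equal(tr$h[tr$block %in% paste0("P", 1:5)],
               c(352, 176, 88, 44, 22))
  tr128 <- shape_trace(network_config(128,
                                      channel_schedule = c(8, 16, 32, 32, 32, 32),
                                      se_reduction = 4))
  expect_equal(tr128$h[tr128$block == "P5"], 4)
  expect_equal(tr128$h[tr128$block == "R1"], 128)
})

test_that("invalid architecture configurations are rejected", {
  expect_error(network_config(100), "divisible")
  expect_error(network_config(128, channel_schedule = c(8, 16)), "length")
  expect_error(network_config(128, channel_schedule = c(8, 16, 32, 32, 32, 32),
                              se_reduction = 16), ">=")
})

test_that("analytic gradients match central finite differences", {
  cfg <- network_config(8, n_pool = 1, channel_schedule = c(4, 4),
                        se_reduction = 2)
  p <- init_network(cfg, seed = 2)
  set.seed(42)
  x <- matrix(runif(64), 64, 1)
  y <- as.numeric(runif(64) > 0.5)
  loss_of <- function(params) {
    fw <- fazseg:::network_forward(params, x, cfg, training = TRUE)
    fazseg:::bce_with_logits(fw$logits, y)$loss
  }
  fw <- fazseg:::network_forward(p, x, cfg, training = TRUE)
  lo <- fazseg:::bce_with_logits(fw$logits, y)
  gr <- fazseg:::network_backward(matrix(lo$dz, ncol = 1), fw$cache,
                                  fw$params, cfg)
  assign_path <- function(p, pa, v) {
    if (length(pa) == 1) { p[[pa[[1]]]] <- v; return(p) }
    p[[pa[[1]]]] <- assign_path(p[[pa[[1]]]], pa[-1], v); p
  }
  eps <- 1e-6
  paths <- list(
    list("stem1", "c1", "W"), list("stem1", "bn1", "gamma"),
    list("stem2", "bn2", "beta"), list("pool", 1L, "conv", "c2", "W"),
    list("pool", 1L, "se", "W1"), list("up", 1L, "conv", "c1", "W"),
    list("up", 1L, "se", "W2"), list("head", "W"), list("head", "b"))
  for (pa in paths) {
    leaf <- p; for (k in pa) leaf <- leaf[[k]]
    gl <- gr; for (k in pa) gl <- gl[[k]]
    for (j in sample(length(leaf), min(3, length(leaf)))) {
      lp <- leaf; lp[j] <- lp[j] + eps
      lm <- leaf; lm[j] <- lm[j] - eps
      num <- (loss_of(assign_path(p, pa, lp)) -
                loss_of(assign_path(p, pa, lm))) / (2 * eps)
      expect_lt(abs(num - gl[j]) / max(1e-8, abs(num) + abs(gl[j])), 1e-4)
    }
  }
})

test_that("the scaled network can overfit a single sample", {
  cfg <- network_config(128, channel_schedule = c(8, 16, 32, 32, 32, 32),
                        se_reduction = 4)
  p <- init_network(cfg, seed = 3)
  coh <- generate_cohort(1, 0, seed = 12, size = c(128, 128))
  s <- fazseg:::prepare_sample(coh$samples[[1]], 128)
  x <- matrix(as.numeric(s$image), 128 * 128, 1)
  y <- as.numeric(s$gt)
  adam <- fazseg:::adam_init()
  final_dsc <- 0
  for (step in 1:300) {
    fw <- fazseg:::network_forward(p, x, cfg, training = TRUE)
    p <- fw$params
    lo <- fazseg:::dice_with_logits(fw$logits, y)
    if (!is.finite(lo$loss)) stop("non-finite training loss")
    g <- fazseg:::network_backward(matrix(lo$dz, ncol = 1), fw$cache, p, cfg)
    upd <- fazseg:::adam_update(p, g, adam, lr = 3e-2)
    p <- upd$params; adam <- upd$state
    if (step %% 10 == 0) {
      pred <- matrix(as.integer(fazseg:::sigmoid(fw$logits) >= 0.5), 128, 128)
      final_dsc <- fazseg:::dsc_masks(pred, s$gt)
      if (final_dsc > 0.99) break
    }
  }
  expect_gt(final_dsc, 0.99)
})
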