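#' Architecture configuration for the segmentation network
#'
#' The network is a U-Net-style encoder-decoder with squeeze-and-excitation
#' (SE) channel attention: two stem Conv-BN-ReLU blocks (C1-C2), `n_pool`
#' pooling blocks (Conv-BN-ReLU + SE + 2x2 max-pool, P1..P5 by default),
#' `n_pool` upsampling blocks (bilinear 2x upsample + skip concatenation +
#' Conv-BN-ReLU + SE, U1..U5) and a 1x1-conv + sigmoid reconstruction head
#' (R1). At the default full scale a 704 x 704 input reaches a 22 x 22
#' bottleneck and is reconstructed back to 704 x 704.
#'
#' @param input_size Square input side; must be divisible by `2^n_pool`.
#' @param n_pool Number of pooling stages (default 5).
#' @param channel_schedule Integer vector of length `n_pool + 1`: feature
#'   dimensions of the stem and of each pooling block. Defaults to
#'   `c(32, 64, 128, 256, 512, 512)` at full scale.
#' @param se_reduction SE bottleneck reduction ratio (default 16); every
#'   entry of `channel_schedule` must be >= `se_reduction` or the SE hidden
#'   width collapses below one unit.
#' @param kernel_size Odd convolution kernel side (default 3).
#' @return A `faz_net_config` object.
#' @export
#' @examples
#' network_config(128, channel_schedule = c(8, 16, 32, 32, 32, 32),
#'                se_reduction = 4)
network_config <- function(input_size = 704, n_pool = 5,
                           channel_schedule = c(32, 64, 128, 256, 512, 512),
                           se_reduction = 16, kernel_size = 3) {
  if (input_size %% (2^n_pool) != 0) {
    abort(sprintf("`input_size` (%d) must be divisible by 2^n_pool (%d).",
                  input_size, 2^n_pool))
  }
  if (length(channel_schedule) != n_pool + 1) {
    abort("`channel_schedule` must have length `n_pool + 1`.")
  }
  if (kernel_size %% 2 != 1) abort("`kernel_size` must be odd.")
  if (any(channel_schedule < se_reduction)) {
    abort("Every channel count must be >= `se_reduction`.")
  }
  structure(
    list(input_size = as.integer(input_size), n_pool = as.integer(n_pool),
         channel_schedule = as.integer(channel_schedule),
         se_reduction = as.integer(se_reduction),
         kernel_size = as.integer(kernel_size)),
    class = "faz_net_config"
  )
}

#' @export
print.faz_net_config <- function(x, ...) {
  cat(sprintf(
    "<faz_net_config> input %dx%d, %d pooling stages, channels [%s], SE 1/%d, %dx%d kernels\n",
    x$input_size, x$input_size, x$n_pool,
    paste(x$channel_schedule, collapse = ", "), x$se_reduction,
    x$kernel_size, x$kernel_size))
  invisible(x)
}

#' Initialise network parameters
#'
#' He-uniform initialisation for convolution and dense weights, unit scale /
#' zero shift for batch normalisation; fully determined by `seed`.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return Nested parameter list (class `faz_net_params`).
#' @export
init_network <- function(config, seed = 1L) {
  s <- config$channel_schedule
  k <- config$kernel_size
  np <- config$n_pool
  with_seed(seed, {
    params <- list(
      stem1 = init_conv_block(1L, s[1], k),
      stem2 = init_conv_block(s[1], s[1], k),
      pool = lapply(seq_len(np), function(i) {
        cin <- s[i]
        list(conv = init_conv_block(cin, s[i + 1], k),
             se = init_se(s[i + 1], config$se_reduction))
      }),
      up = lapply(seq_len(np), function(i) {
        j <- np + 1 - i
        cin_up <- if (i == 1) s[np + 1] else s[j + 1]
        cin <- cin_up + s[j + 1]
        list(conv = init_conv_block(cin, s[j], k),
             se = init_se(s[j], config$se_reduction))
      }),
      head = list(W = he_uniform(s[1], 1L, s[1]), b = 0)
    )
    structure(params, class = "faz_net_params")
  })
}

# Full forward pass. `x` is an npix x 1 matrix of normalised intensities.
# Returns logits (npix x 1), caches (training only) and params with updated
# batch-norm running statistics.
network_forward <- function(params, x, config, training = FALSE,
                            batch_stats = TRUE) {
  k <- config$kernel_size
  np <- config$n_pool
  h <- config$input_size; w <- config$input_size
  cache <- list()

  st1 <- conv_block_fwd(x, params$stem1, h, w, k, training, batch_stats)
  params$stem1 <- st1$params
  st2 <- conv_block_fwd(st1$out, params$stem2, h, w, k, training, batch_stats)
  params$stem2 <- st2$params
  cache$stem1 <- st1$cache; cache$stem2 <- st2$cache

  out <- st2$out
  skips <- vector("list", np)
  dims <- matrix(0L, np, 2)
  cache$pool <- vector("list", np)
  for (i in seq_len(np)) {
    cb <- conv_block_fwd(out, params$pool[[i]]$conv, h, w, k, training,
                         batch_stats)
    params$pool[[i]]$conv <- cb$params
    se <- se_fwd(cb$out, params$pool[[i]]$se, training)
    mp <- cpp_maxpool2(se$out, h, w)
    skips[[i]] <- se$out
    dims[i, ] <- c(h, w)
    cache$pool[[i]] <- if (training) {
      list(conv = cb$cache, se = se$cache, argmax = mp$argmax,
           h = h, w = w)
    }
    out <- mp$out
    h <- h %/% 2L; w <- w %/% 2L
  }

  cache$up <- vector("list", np)
  for (i in seq_len(np)) {
    j <- np + 1 - i
    upx <- cpp_upsample2(out, h, w)
    h <- 2L * h; w <- 2L * w
    stopifnot(h == dims[j, 1], w == dims[j, 2])
    cat_in <- cbind(upx, skips[[j]])
    cb <- conv_block_fwd(cat_in, params$up[[i]]$conv, h, w, k, training,
                         batch_stats)
    params$up[[i]]$conv <- cb$params
    se <- se_fwd(cb$out, params$up[[i]]$se, training)
    cache$up[[i]] <- if (training) {
      list(conv = cb$cache, se = se$cache, h = h, w = w,
           d_up = ncol(upx), d_skip = ncol(skips[[j]]))
    }
    out <- se$out
  }

  logits <- out %*% params$head$W + params$head$b
  cache$head_x <- if (training) out
  list(logits = logits, cache = cache, params = params)
}

# Backward pass from d(loss)/d(logits); returns gradients mirroring the
# trainable parameter structure, plus skip-gradient bookkeeping.
network_backward <- function(dlogits, cache, params, config) {
  np <- config$n_pool
  grads <- list()
  grads$head <- list(W = crossprod(cache$head_x, dlogits),
                     b = sum(dlogits))
  d <- dlogits %*% t(params$head$W)

  dskips <- vector("list", np)
  grads$up <- vector("list", np)
  for (i in rev(seq_len(np))) {
    j <- np + 1 - i
    cc <- cache$up[[i]]
    se <- se_bwd(d, cc$se, params$up[[i]]$se)
    cb <- conv_block_bwd(se$dx, cc$conv, params$up[[i]]$conv)
    grads$up[[i]] <- list(conv = cb$grads, se = se$grads)
    d_up <- cb$dx[, seq_len(cc$d_up), drop = FALSE]
    dskips[[j]] <- cb$dx[, cc$d_up + seq_len(cc$d_skip), drop = FALSE]
    d <- cpp_upsample2_backward(d_up, cc$h %/% 2L, cc$w %/% 2L)
  }

  grads$pool <- vector("list", np)
  for (i in rev(seq_len(np))) {
    cc <- cache$pool[[i]]
    dskip <- cpp_maxpool2_backward(d, cc$argmax, cc$h * cc$w) + dskips[[i]]
    se <- se_bwd(dskip, cc$se, params$pool[[i]]$se)
    cb <- conv_block_bwd(se$dx, cc$conv, params$pool[[i]]$conv)
    grads$pool[[i]] <- list(conv = cb$grads, se = se$grads)
    d <- cb$dx
  }

  st2 <- conv_block_bwd(d, cache$stem2, params$stem2)
  st1 <- conv_block_bwd(st2$dx, cache$stem1, params$stem1)
  grads$stem2 <- st2$grads
  grads$stem1 <- st1$grads
  grads
}

#' Predict a probability map for one image
#'
#' Runs the network in inference mode and returns the per-pixel sFAZ
#' probability. By default batch normalisation uses the moments of the
#' image being predicted: the training loop normalises with per-batch
#' moments (per-image at batch size 1), so this evaluates exactly the
#' function that was optimised. `bn = "running"` instead applies the
#' running statistics accumulated during training.
#'
#' @param params Trained parameters from [init_network()]/[train_model()].
#' @param config The matching [network_config()].
#' @param bn Batch-normalisation statistics at inference: `"batch"`
#'   (default, per-image moments) or `"running"`.
#' @param image Normalised square intensity matrix (values in \[0, 1\]) of
#'   side `config$input_size`.
#' @return Matrix of probabilities strictly in (0, 1), same size as input.
#' @export
predict_probmap <- function(params, config, image,
                            bn = c("batch", "running")) {
  bn <- match.arg(bn)
  side <- config$input_size
  if (!identical(dim(image), c(side, side))) {
    abort(sprintf("Image must be %d x %d for this config.", side, side))
  }
  x <- matrix(as.numeric(image), side * side, 1)
  fw <- network_forward(params, x, config, training = FALSE,
                        batch_stats = (bn == "batch"))
  matrix(sigmoid(fw$logits), side, side)
}

#' Symbolic shape trace of the architecture
#'
#' Computes the output dimensions (h, w, d) of every block without
#' allocating any parameters, consistent with the forward pass: the encoder
#' halves the spatial side `n_pool` times down to the bottleneck and the
#' decoder doubles it back.
#'
#' @param config A [network_config()].
#' @return A tibble with columns `block`, `h`, `w`, `d`.
#' @export
#' @examples
#' shape_trace(network_config(704))
shape_trace <- function(config) {
  s <- config$channel_schedule
  np <- config$n_pool
  side <- config$input_size
  rows <- list(list(block = "input", h = side, w = side, d = 1L),
               list(block = "C1", h = side, w = side, d = s[1]),
               list(block = "C2", h = side, w = side, d = s[1]))
  h <- side
  for (i in seq_len(np)) {
    h <- h %/% 2L
    rows[[length(rows) + 1]] <-
      list(block = paste0("P", i), h = h, w = h, d = s[i + 1])
  }
  for (i in seq_len(np)) {
    h <- h * 2L
    rows[[length(rows) + 1]] <-
      list(block = paste0("U", i), h = h, w = h, d = s[np + 1 - i])
  }
  rows[[length(rows) + 1]] <- list(block = "R1", h = side, w = side, d = 1L)
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

# Recursive Adam update; `state` carries first/second moment estimates and
# the step counter. Only leaves present in `grads` are updated, so BN
# running statistics are untouched.
adam_init <- function() list(t = 0)

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(g)) {
      m <- m %||% vector("list", length(g))
      v <- v %||% vector("list", length(g))
      names(m) <- names(g); names(v) <- names(g)
      for (nm in names(g)) {
        res <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- res$p; m[[nm]] <- res$m; v[[nm]] <- res$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- if (is.null(m)) (1 - beta1) * g else beta1 * m + (1 - beta1) * g
    v <- if (is.null(v)) (1 - beta2) * g * g else beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}
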