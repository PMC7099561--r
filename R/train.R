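#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with an initial learning
#' rate of 1e-4, halved whenever the training loss fails to improve within a
#' trailing 30-epoch window, and a model checkpoint taken whenever the
#' test-set correct rate (mean pixel accuracy) strictly increases.
#'
#' @param initial_lr Initial Adam learning rate (default `1e-4`).
#' @param patience_epochs Plateau window length in epochs (default 30).
#' @param lr_factor Multiplicative decay on plateau (default 0.5).
#' @param max_epochs Maximum training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param loss `"bce"` (pixelwise binary cross-entropy, default) or
#'   `"dice"` (soft Dice).
#' @param seed Integer seed controlling shuffling, augmentation draws and
#'   parameter initialisation.
#' @param stop_dsc Optional early-stop target: halt once the test-set mean
#'   DSC reaches this value (`NULL` = never).
#' @return A `faz_train_config` object.
#' @export
train_config <- function(initial_lr = 1e-4, patience_epochs = 30,
                         lr_factor = 0.5, max_epochs = 300,
                         batch_size = 4, loss = c("bce", "dice"),
                         seed = 1L, stop_dsc = NULL) {
  loss <- match.arg(loss)
  if (lr_factor <= 0 || lr_factor >= 1) abort("`lr_factor` must be in (0, 1).")
  if (patience_epochs < 1) abort("`patience_epochs` must be >= 1.")
  structure(
    list(initial_lr = initial_lr, patience_epochs = as.integer(patience_epochs),
         lr_factor = lr_factor, max_epochs = as.integer(max_epochs),
         batch_size = as.integer(batch_size), loss = loss,
         seed = as.integer(seed), stop_dsc = stop_dsc),
    class = "faz_train_config"
  )
}

new_train_state <- function(config) {
  list(epoch = 0L, current_lr = config$initial_lr,
       loss_history = numeric(), best_test_score = -Inf,
       checkpoints_saved = 0L, last_reduce = 0L)
}

#' Participant-based stratified cross-validation splits
#'
#' Partitions subjects into `k` folds of near-equal size (sizes differ by at
#' most one), stratified on myopia class so each fold's high-myopia count is
#' within one of its proportional share. All nine B/C renderings of a
#' subject always land on the same side of every split, preventing leakage.
#'
#' @param subjects Data frame with columns `subject_id` and `myopia_class`
#'   (e.g. the `subjects` element of a [generate_cohort()]).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; splits are deterministic given it.
#' @return List of `k` folds: `list(fold_id, test_subjects, train_subjects)`.
#' @export
#' @examples
#' coh <- generate_cohort(5, 2, seed = 1, size = c(64, 64))
#' make_cv_splits(coh$subjects, k = 5, seed = 1)[[1]]$test_subjects
make_cv_splits <- function(subjects, k = 5, seed = 1L) {
  n <- nrow(subjects)
  if (k > n) abort("`k` cannot exceed the number of subjects.")
  high <- subjects$subject_id[subjects$myopia_class == "high"]
  low <- subjects$subject_id[subjects$myopia_class != "high"]
  nh <- length(high)
  tot <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  hc <- rep(nh %/% k, k) + (seq_len(k) <= nh %% k)
  # pair the larger high-counts with the smaller totals last, so that the
  # implied low-myopia counts stay non-negative
  hc <- sort(hc, decreasing = TRUE)
  tot <- sort(tot, decreasing = TRUE)
  lc <- tot - hc
  if (any(lc < 0) || any(lc > length(low))) {
    abort("Stratified split infeasible for these class counts.")
  }
  with_seed(seed, {
    high <- sample(high)
    low <- sample(low)
    hi_idx <- c(0, cumsum(hc))
    lo_idx <- c(0, cumsum(lc))
    lapply(seq_len(k), function(f) {
      test <- c(high[seq2(hi_idx[f] + 1, hi_idx[f + 1])],
                low[seq2(lo_idx[f] + 1, lo_idx[f + 1])])
      list(fold_id = f,
           test_subjects = sort(test),
           train_subjects = sort(setdiff(subjects$subject_id, test)))
    })
  })
}

seq2 <- function(from, to) if (from > to) integer() else seq(from, to)

#' Plateau-based learning-rate step
#'
#' Applies the schedule: the learning rate is multiplied by `lr_factor`
#' when the minimum loss over the trailing `patience_epochs` window fails
#' to beat the best loss achieved before that window. After a reduction the
#' window must fully refill before another reduction can trigger.
#'
#' @param state Training state (list with `loss_history`, `current_lr`,
#'   `last_reduce`, `epoch`).
#' @param config A [train_config()].
#' @return The updated state; the possibly-reduced rate is
#'   `state$current_lr`.
#' @export
lr_schedule_step <- function(state, config) {
  hist <- state$loss_history
  n <- length(hist)
  if (n == 0) abort("Empty loss history.")
  p <- config$patience_epochs
  if (n <= p || (n - state$last_reduce) < p) return(state)
  window <- hist[(n - p + 1):n]
  best_before <- min(hist[1:(n - p)])
  if (min(window) >= best_before) {
    state$current_lr <- state$current_lr * config$lr_factor
    state$last_reduce <- n
  }
  state
}

#' Best-on-test checkpointing
#'
#' Persists the model exactly when the test-set correct rate strictly
#' improves on the best seen so far.
#'
#' @param state Training state.
#' @param test_score Finite test-set score for the current epoch.
#' @param params Current network parameters.
#' @param path Optional file path; when given, an improved model is written
#'   there with `saveRDS()` (an I/O failure raises an error distinct from a
#'   no-save decision).
#' @return `list(state, saved)` where `saved` says whether a checkpoint was
#'   taken this epoch.
#' @export
maybe_checkpoint <- function(state, test_score, params, path = NULL) {
  if (!is.finite(test_score)) abort("`test_score` must be finite.")
  if (test_score <= state$best_test_score) {
    return(list(state = state, saved = FALSE))
  }
  state$best_test_score <- test_score
  state$checkpoints_saved <- state$checkpoints_saved + 1L
  if (!is.null(path)) {
    ok <- tryCatch({ saveRDS(params, path); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      abort(sprintf("Checkpoint I/O failed at '%s': %s", path,
                    conditionMessage(ok)))
    }
  }
  list(state = state, saved = TRUE)
}

prepare_sample <- function(sample, side) {
  img <- sample$image
  gt <- sample$gt
  if (!identical(dim(img), c(side, side))) {
    img <- resize_to_standard(img, side, kind = "image")
    gt <- resize_to_standard(gt, side, kind = "mask")
  }
  list(image = normalize_minmax(img), gt = gt,
       subject_id = sample$subject_id,
       group_id = sample$bc$group_id)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (nm in names(b)) a[[nm]] <- add_grads(a[[nm]], b[[nm]])
    return(a)
  }
  a + b
}

scale_grads <- function(g, f) {
  if (is.list(g)) return(lapply(g, scale_grads, f = f))
  g * f
}

dsc_masks <- function(pred, gt) {
  tp <- sum(pred == 1L & gt == 1L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  if (fp + 2 * tp + fn == 0) return(1)
  2 * tp / (fp + 2 * tp + fn)
}

#' Train the segmentation network
#'
#' Runs the full epoch loop on preprocessed (resized, min-max normalised)
#' samples with on-the-fly rigid augmentation: per epoch, shuffled
#' gradient-accumulation batches are fed to Adam, the mean loss is recorded,
#' the plateau learning-rate schedule is applied, the test-set correct rate
#' (mean pixel accuracy) is computed, and the model is checkpointed on
#' strict improvement. Training and test subject sets must be disjoint
#' (participant-based evaluation).
#'
#' @param config A [train_config()].
#' @param net_config A [network_config()].
#' @param train_samples,test_samples Lists of samples
#'   (`list(image, gt, subject_id, bc)`), e.g. from [generate_cohort()].
#' @param checkpoint_path Optional `.rds` path for the best model.
#' @return A `faz_fit` object: `params` (best checkpointed parameters),
#'   `state`, `history` tibble (epoch, lr, train_loss, test_correct_rate,
#'   test_dsc, checkpointed), `net_config`, `config`.
#' @export
train_model <- function(config, net_config, train_samples, test_samples,
                        checkpoint_path = NULL) {
  tr_subj <- unique(vapply(train_samples, `[[`, character(1), "subject_id"))
  te_subj <- unique(vapply(test_samples, `[[`, character(1), "subject_id"))
  leak <- intersect(tr_subj, te_subj)
  if (length(leak)) {
    abort(sprintf("Subject leakage between train and test sets: %s",
                  paste(leak, collapse = ", ")))
  }
  side <- net_config$input_size
  train_prep <- lapply(train_samples, prepare_sample, side = side)
  test_prep <- lapply(test_samples, prepare_sample, side = side)
  loss_fn <- switch(config$loss, bce = bce_with_logits,
                    dice = dice_with_logits)

  params <- init_network(net_config, seed = config$seed)
  best_params <- params
  state <- new_train_state(config)
  adam <- adam_init()
  history <- list()
  transforms <- rigid_transforms()

  with_seed(derive_seed(config$seed, "trainloop"), {
    for (epoch in seq_len(config$max_epochs)) {
      order <- sample(length(train_prep))
      losses <- numeric(0)
      g_acc <- NULL
      n_acc <- 0L
      for (ii in order) {
        s <- train_prep[[ii]]
        tr <- sample(transforms, 1)
        img <- apply_rigid(s$image, tr)
        gt <- apply_rigid(s$gt, tr)
        x <- matrix(as.numeric(img), side * side, 1)
        y <- as.numeric(gt)
        fw <- network_forward(params, x, net_config, training = TRUE)
        params <- fw$params
        lo <- loss_fn(fw$logits, y)
        if (!is.finite(lo$loss)) abort("Non-finite training loss.")
        losses <- c(losses, lo$loss)
        g <- network_backward(matrix(lo$dz, ncol = 1), fw$cache, params,
                              net_config)
        g_acc <- add_grads(g_acc, g)
        n_acc <- n_acc + 1L
        if (n_acc >= config$batch_size || ii == order[length(order)]) {
          upd <- adam_update(params, scale_grads(g_acc, 1 / n_acc), adam,
                             lr = state$current_lr)
          params <- upd$params
          adam <- upd$state
          g_acc <- NULL
          n_acc <- 0L
        }
      }
      state$epoch <- epoch
      state$loss_history <- c(state$loss_history, mean(losses))
      state <- lr_schedule_step(state, config)

      accs <- dscs <- numeric(length(test_prep))
      for (j in seq_along(test_prep)) {
        s <- test_prep[[j]]
        prob <- predict_probmap(params, net_config, s$image)
        pred <- matrix(as.integer(prob >= 0.5), side, side)
        accs[j] <- mean(pred == s$gt)
        dscs[j] <- dsc_masks(pred, s$gt)
      }
      test_correct <- mean(accs)
      test_dsc <- mean(dscs)
      ck <- maybe_checkpoint(state, test_correct, params, checkpoint_path)
      state <- ck$state
      if (ck$saved) best_params <- params
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = state$current_lr, train_loss = mean(losses),
        test_correct_rate = test_correct, test_dsc = test_dsc,
        checkpointed = ck$saved)
      if (!is.null(config$stop_dsc) && test_dsc >= config$stop_dsc) break
    }
  })

  structure(
    list(params = best_params, state = state,
         history = if (length(history)) dplyr::bind_rows(history)
                   else tibble::tibble(epoch = integer(), lr = numeric(),
                                       train_loss = numeric(),
                                       test_correct_rate = numeric(),
                                       test_dsc = numeric(),
                                       checkpointed = logical()),
         net_config = net_config, config = config),
    class = "faz_fit"
  )
}

#' @export
print.faz_fit <- function(x, ...) {
  cat(sprintf(
    "<faz_fit> %d epochs, best test correct rate %.4f, %d checkpoints\n",
    x$state$epoch, x$state$best_test_score, x$state$checkpoints_saved))
  invisible(x)
}

#' @rdname train_model
#' @param x A `faz_fit` object.
#' @param ... Unused.
#' @export
tidy.faz_fit <- function(x, ...) x$history

#' @rdname train_model
#' @export
glance.faz_fit <- function(x, ...) {
  tibble::tibble(
    epochs = x$state$epoch,
    best_test_correct_rate = x$state$best_test_score,
    best_test_dsc = if (nrow(x$history)) max(x$history$test_dsc) else NA_real_,
    final_lr = x$state$current_lr,
    checkpoints_saved = x$state$checkpoints_saved
  )
}

#' @rdname train_model
#' @param object A `faz_fit` object.
#' @export
autoplot.faz_fit <- function(object, ...) {
  h <- object$history
  long <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, value = h$train_loss, what = "train loss"),
    tibble::tibble(epoch = h$epoch, value = h$test_dsc, what = "test DSC"))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
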