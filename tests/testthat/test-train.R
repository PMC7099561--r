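# Cross-validation splitting, learning-rate schedule, checkpointing and
# the training loop on a miniature cohort.

test_that("5-fold stratified splits partition 45 subjects 9 per fold", {
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:45),
    myopia_class = rep(c("high", "low"), c(12, 33)))
  splits <- make_cv_splits(subjects, k = 5, seed = 3)
  sizes <- vapply(splits, function(s) length(s$test_subjects), numeric(1))
  expect_true(all(sizes == 9))
  highs <- vapply(splits, function(s) {
    sum(s$test_subjects %in% subjects$subject_id[1:12])
  }, numeric(1))
  expect_true(all(highs %in% 2:3))
  all_test <- unlist(lapply(splits, `[[`, "test_subjects"))
  expect_setequal(all_test, subjects$subject_id)
  expect_equal(anyDuplicated(all_test), 0L)
  for (s in splits) {
    expect_length(intersect(s$test_subjects, s$train_subjects), 0)
  }
  expect_identical(splits, make_cv_splits(subjects, k = 5, seed = 3))
  expect_error(make_cv_splits(subjects[1:3, ], k = 5), "exceed")
})

test_that("learning rate halves on a plateau and only then", {
  cfg <- train_config(initial_lr = 1e-4, patience_epochs = 30)
  st <- fazseg:::new_train_state(cfg)
  # a best of 0.4 followed by 30 flat epochs at 0.5
  st$loss_history <- c(0.45, 0.4, rep(0.5, 30))
  st <- lr_schedule_step(st, cfg)
  expect_equal(st$current_lr, 5e-5)
  # strictly decreasing loss never triggers a reduction
  st2 <- fazseg:::new_train_state(cfg)
  st2$loss_history <- seq(1, 0.1, length.out = 50)
  expect_equal(lr_schedule_step(st2, cfg)$current_lr, 1e-4)
  # two consecutive plateau windows quarter the rate
  st3 <- fazseg:::new_train_state(cfg)
  st3$loss_history <- c(0.4)
  for (i in 1:60) {
    st3$loss_history <- c(st3$loss_history, 0.5)
    st3 <- lr_schedule_step(st3, cfg)
  }
  expect_equal(st3$current_lr, 2.5e-5)
  st4 <- fazseg:::new_train_state(cfg)
  expect_error(lr_schedule_step(st4, cfg), "Empty")
})

test_that("checkpoints are taken exactly on strict improvements", {
  cfg <- train_config()
  st <- fazseg:::new_train_state(cfg)
  n_saved <- 0
  for (score in c(0.5, 0.6, 0.55, 0.7)) {
    r <- maybe_checkpoint(st, score, params = list(), path = NULL)
    st <- r$state
    n_saved <- n_saved + r$saved
  }
  expect_equal(n_saved, 3)
  expect_equal(st$checkpoints_saved, 3L)
  expect_equal(st$best_test_score, 0.7)
  # an equal score does not save (strict inequality)
  expect_false(maybe_checkpoint(st, 0.7, list())$saved)
  # monotone-decreasing scores after the first: one checkpoint
  st2 <- fazseg:::new_train_state(cfg)
  n2 <- 0
  for (score in c(0.8, 0.7, 0.6)) {
    r <- maybe_checkpoint(st2, score, list()); st2 <- r$state
    n2 <- n2 + r$saved
  }
  expect_equal(n2, 1)
  expect_error(maybe_checkpoint(st, NaN, list()), "finite")
  # checkpoint files are actually written on improvement
  f <- tempfile(fileext = ".rds")
  r <- maybe_checkpoint(fazseg:::new_train_state(cfg), 0.9,
                        list(a = 1), path = f)
  expect_true(file.exists(f))
  expect_equal(readRDS(f)$a, 1)
})

test_that("training rejects subject leakage and honours zero epochs", {
  coh <- tiny_cohort()
  subj <- vapply(coh$samples, `[[`, character(1), "subject_id")
  s1 <- coh$samples[subj == unique(subj)[1]]
  s2 <- coh$samples[subj == unique(subj)[2]]
  nc <- network_config(64, channel_schedule = c(4, 4, 4, 4, 4, 4),
                       se_reduction = 2)
  expect_error(
    train_model(train_config(max_epochs = 1), nc, s1, s1),
    "leakage")
  fit0 <- train_model(train_config(max_epochs = 0, seed = 5), nc, s1, s2)
  expect_equal(fit0$state$checkpoints_saved, 0L)
  expect_equal(nrow(fit0$history), 0L)
  # untrained parameters equal a fresh initialisation under the same seed
  expect_equal(fit0$params, init_network(nc, seed = 5), ignore_attr = TRUE)
})

test_that("a short training run keeps its invariants", {
  coh <- tiny_cohort()
  subj <- vapply(coh$samples, `[[`, character(1), "subject_id")
  s1 <- coh$samples[subj == unique(subj)[1]]
  s2 <- coh$samples[subj == unique(subj)[2]]
  nc <- network_config(64, channel_schedule = c(4, 8, 8, 8, 8, 8),
                       se_reduction = 2)
  fit <- train_model(
    train_config(initial_lr = 3e-3, max_epochs = 3, batch_size = 2,
                 loss = "dice", seed = 2),
    nc, s1, s2)
  h <- fit$history
  expect_equal(nrow(h), 3)
  expect_true(all(is.finite(h$train_loss)))
  # lr is initial * 0.5^m for integer m and non-increasing
  m <- log(fit$config$initial_lr / h$lr) / log(2)
  expect_true(all(abs(m - round(m)) < 1e-12))
  expect_true(all(diff(h$lr) <= 0))
  # best test score is the running max of the per-epoch scores
  expect_equal(fit$state$best_test_score, max(h$test_correct_rate))
  expect_equal(sum(h$checkpointed),
               sum(h$test_correct_rate == cummax(h$test_correct_rate) &
                     !duplicated(cummax(h$test_correct_rate))))
  # broom-style accessors
  expect_identical(tidy(fit), h)
  expect_equal(glance(fit)$epochs, 3L)
})
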