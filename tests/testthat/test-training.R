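# Loss functions, callback semantics and the training loop contract.

test_that("softmax normalizes, is shift-invariant and matches closed forms", {
  expect_equal(softmax(rep(0, 5)), rep(0.2, 5))
  z <- c(3.2, -1, 0.4, 7, 2)
  expect_equal(softmax(z), softmax(z + 123.4), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-12)
  # (1,0,0,0,0): first entry e/(e+4), rest 1/(e+4)
  p <- softmax(c(1, 0, 0, 0, 0))
  expect_equal(p[1], exp(1) / (exp(1) + 4), tolerance = 1e-12)
  expect_equal(p[2], 1 / (exp(1) + 4), tolerance = 1e-12)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("cross-entropy matches analytic values", {
  expect_equal(cross_entropy_loss(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0)
  expect_equal(cross_entropy_loss(rep(0.2, 5), c(0, 0, 1, 0, 0)), log(5),
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), c(1, 0)), log(2),
               tolerance = 1e-12)
  # permuting classes jointly leaves the loss unchanged
  p <- c(0.1, 0.6, 0.3)
  expect_equal(cross_entropy_loss(p, c(0, 1, 0)),
               cross_entropy_loss(p[c(2, 1, 3)], c(1, 0, 0)))
  # integer-label interface, batch mean
  pm <- rbind(c(0.5, 0.25, 0.25), c(0.1, 0.8, 0.1))
  expect_equal(cross_entropy_loss(pm, c(0L, 1L)),
               mean(-log(c(0.5, 0.8))))
})

test_that("plateau callback halves the learning rate after 5 stagnant epochs", {
  cfg <- train_config()
  st <- train_state(cfg)
  st <- reduce_lr_on_plateau(st, 0.70, cfg)  # first value is an improvement
  for (i in 1:4) st <- reduce_lr_on_plateau(st, 0.70, cfg)
  expect_equal(st$lr, 0.001)                 # 4 stagnant epochs: unchanged
  st <- reduce_lr_on_plateau(st, 0.70, cfg)  # 5th stagnant epoch
  expect_equal(st$lr, 0.0005)
  # 5 more stagnant epochs: second halving (no lower floor)
  for (i in 1:5) st <- reduce_lr_on_plateau(st, 0.70, cfg)
  expect_equal(st$lr, 0.00025)
})

test_that("improvement resets the plateau counter; min_delta is strict", {
  cfg <- train_config()
  st <- train_state(cfg)
  st <- reduce_lr_on_plateau(st, 0.70, cfg)
  for (i in 1:4) st <- reduce_lr_on_plateau(st, 0.70, cfg)
  st <- reduce_lr_on_plateau(st, 0.75, cfg)  # improvement at epoch 5
  expect_equal(st$lr, 0.001)
  expect_equal(st$plateau_wait, 0L)
  # a sub-min_delta "improvement" counts as stagnant
  st2 <- train_state(cfg)
  st2 <- reduce_lr_on_plateau(st2, 0.70, cfg)
  for (i in 1:5) st2 <- reduce_lr_on_plateau(st2, 0.70 + 1e-5, cfg)
  expect_equal(st2$lr, 0.0005)
})

test_that("early stopping snapshots, stops after 30, and restores bitwise", {
  cfg <- train_config(checkpoint_path = tempfile(fileext = ".rds"))
  st <- train_state(cfg)
  w_best <- list(a = matrix(rnorm(4), 2))
  st <- early_stop_and_checkpoint(st, 0.9, w_best, cfg)
  expect_identical(st$best_weights, w_best)
  expect_identical(readRDS(cfg$checkpoint_path), w_best)
  w_worse <- list(a = matrix(0, 2, 2))
  for (i in 1:29) st <- early_stop_and_checkpoint(st, 0.85, w_worse, cfg)
  expect_false(st$stopped)
  st <- early_stop_and_checkpoint(st, 0.85, w_worse, cfg)  # 30th
  expect_true(st$stopped)
  expect_identical(st$best_weights, w_best)  # snapshot untouched, bitwise
  # a strictly improving run never raises the stop flag
  st2 <- train_state(cfg)
  for (i in 1:40)
    st2 <- early_stop_and_checkpoint(st2, 0.5 + i / 100, list(a = i), cfg)
  expect_false(st2$stopped)
})

test_that("training is deterministic and records a full history", {
  ps <- small_patch_set(per_class = 4L, out_size = 16L)
  cfg <- network_config(input_size = 16L, stage_channels = c(4L, 8L),
                        num_classes = 5L, hidden_units = 8L)
  run <- function() {
    m <- build_rccgnet(cfg, seed = 31)
    train_model(m, ps, ps, train_config(max_epochs = 2L, seed = 13L))
  }
  f1 <- run()
  f2 <- run()
  expect_identical(f1$state$history$loss[1], f2$state$history$loss[1])
  expect_identical(f1$state$history, f2$state$history)
  expect_equal(nrow(f1$state$history), 2L)
  expect_true(all(diff(f1$state$history$lr) <= 0))
})

test_that("the reported best value equals the history maximum", {
  ps <- small_patch_set(per_class = 4L, out_size = 16L)
  cfg <- network_config(input_size = 16L, stage_channels = c(4L),
                        num_classes = 5L, hidden_units = 8L)
  m <- build_rccgnet(cfg, seed = 5)
  fit <- train_model(m, ps, ps, train_config(max_epochs = 3L, seed = 1L))
  expect_equal(fit$state$best_value,
               max(fit$state$history$val_accuracy))
})

test_that("empty splits are rejected", {
  ps <- small_patch_set(per_class = 4L, out_size = 16L)
  empty <- patch_set(array(0, c(16, 16, 3, 1)), 0L)
  empty$x <- empty$x[, , , 0, drop = FALSE]
  empty$y <- integer(0)
  m <- build_rccgnet(network_config(input_size = 16L,
                                    stage_channels = c(4L),
                                    hidden_units = 4L), seed = 1)
  expect_error(train_model(m, empty, ps), "non-empty")
})
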