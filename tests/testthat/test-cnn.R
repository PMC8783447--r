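# Toy patches that are trivially separable by mean intensity: fast to
# train, so the training loop's bookkeeping can be tested exactly.
toy_patch_set <- function(n_per_class, sd = 5, seed = 1) {
  with_seed <- function(s, e) { set.seed(s); e }
  with_seed(seed, {
    n <- 2 * n_per_class
    X <- array(rnorm(50 * 50 * n, 0, sd), c(50, 50, n))
    X[, , seq_len(n_per_class)] <- X[, , seq_len(n_per_class)] + 10
    X[, , n_per_class + seq_len(n_per_class)] <-
      X[, , n_per_class + seq_len(n_per_class)] + 100
    patch_set(X, rep(1:2, each = n_per_class), c("dark", "bright"))
  })
}

test_that("architectures match the published layer layouts", {
  sel <- build_cnn("selection")
  sta <- build_cnn("state")
  expect_identical(sel$conv_filters, c(16L, 32L, 64L))
  expect_identical(sel$fc_output, 4L)
  expect_identical(sta$conv_filters, c(8L, 16L, 32L))
  expect_identical(sta$fc_output, 2L)
  for (spec in list(sel, sta)) {
    L <- spec$layers
    expect_identical(sum(L$type == "conv"), 3L)
    expect_identical(sum(L$type == "maxpool"), 2L)
    expect_identical(sum(L$type == "batchnorm"), 3L)
    expect_true(all(L$kernel[L$type == "conv"] == 3))
    expect_true(all(L$padding[L$type == "conv"] == "same"))
    expect_true(all(L$pool_size[L$type == "maxpool"] == 2))
    expect_true(all(L$stride[L$type == "maxpool"] == 2))
    expect_identical(L$type[nrow(L)], "softmax")
    expect_identical(spec$input_shape, c(50L, 50L, 1L))
    expect_identical(spec$normalization, "zerocenter")
    # spatial path 50 -> 25 -> 12 before the fully connected layer
    expect_identical(L$output_size[L$type == "maxpool"], c(25L, 12L))
  }
  expect_error(build_cnn("other"))
})

test_that("training defaults match the reference recipe", {
  cfg <- train_config()
  expect_equal(cfg$initial_lr, 0.01)
  expect_equal(cfg$max_epochs, 4)
  expect_equal(cfg$validation_frequency, 30)
})

test_that("a separable toy problem trains to 100% validation accuracy", {
  tr <- toy_patch_set(90, seed = 2)
  va <- toy_patch_set(30, seed = 3)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 32), seed = 5)
  final <- fit$history[nrow(fit$history), ]
  expect_equal(final$val_acc, 1)
  # every training patch classifies to its own label
  pred <- classify(fit, tr$patches)
  expect_identical(pred$class, tr$class_names[tr$labels])
})

test_that("validation runs every 30 iterations plus a final evaluation", {
  tr <- toy_patch_set(250, seed = 7) # 500 patches, batch 32 -> 16 it/epoch
  va <- toy_patch_set(20, seed = 8)
  cfg <- train_config(batch_size = 32, max_epochs = 4) # 64 iterations
  fit <- train_cnn(build_cnn("state"), tr, va, cfg, seed = 9)
  expect_identical(fit$history$iteration, c(30L, 60L, 64L))
  expect_identical(fit$history$final, c(FALSE, FALSE, TRUE))
  expect_identical(nrow(fit$history), 3L) # floor(64/30) + final
})

test_that("softmax probabilities sum to 1 and batch equals per-patch", {
  tr <- toy_patch_set(40, seed = 10)
  va <- toy_patch_set(10, seed = 11)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 16, max_epochs = 1), seed = 12)
  X <- va$patches
  batch <- classify(fit, X)
  psums <- rowSums(as.matrix(batch[c("p_dark", "p_bright")]))
  expect_equal(psums, rep(1, nrow(batch)), tolerance = 1e-6)
  for (i in c(1, 7, 20)) {
    single <- classify(fit, X[, , i])
    expect_identical(single$class, batch$class[i])
    expect_equal(single$p_bright, batch$p_bright[i], tolerance = 1e-12)
  }
  expect_error(classify(fit, matrix(0, 40, 40)), "50 x 50")
})

test_that("training is deterministic for a fixed seed", {
  tr <- toy_patch_set(60, seed = 14)
  va <- toy_patch_set(20, seed = 15)
  cfg <- train_config(batch_size = 32, max_epochs = 2)
  f1 <- train_cnn(build_cnn("state"), tr, va, cfg, seed = 77)
  f2 <- train_cnn(build_cnn("state"), tr, va, cfg, seed = 77)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$Wfc, f2$params$Wfc)
})

test_that("inference applies the training-set mean image, not per patch", {
  tr <- toy_patch_set(40, seed = 16)
  va <- toy_patch_set(10, seed = 17)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 16, max_epochs = 1), seed = 18)
  expect_equal(fit$mean_image, apply(tr$patches, c(1, 2), mean))
  # a constant offset moves the zero-centered input, so predictions come
  # from (patch - training mean): verify classify() subtracts exactly that
  x <- va$patches[, , 1]
  p1 <- classify(fit, x)
  manual <- guvstack:::.cpp_cnn_predict(
    array(x - fit$mean_image, c(50, 50, 1)), fit$params)
  expect_equal(unname(unlist(p1[c("p_dark", "p_bright")])),
               as.numeric(manual), tolerance = 1e-12)
})

test_that("single-class training sets and class mismatches are rejected", {
  tr <- toy_patch_set(20, seed = 19)
  va <- toy_patch_set(5, seed = 20)
  bad <- patch_set(tr$patches, rep(1L, length(tr)), tr$class_names)
  expect_error(train_cnn(build_cnn("state"), bad, va), "2 classes")
  expect_error(train_cnn(build_cnn("selection"), tr, va), "fc_output")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  tr <- toy_patch_set(30, seed = 21)
  va <- toy_patch_set(10, seed = 22)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 16, max_epochs = 1), seed = 23)
  path <- tempfile(fileext = ".rds")
  save_cnn(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$kind, "state")
  expect_identical(unlist(side$class_names), c("dark", "bright"))
  back <- load_cnn(path)
  expect_equal(back$params$Wfc, fit$params$Wfc)
  unlink(c(path, paste0(path, ".json")))
})

test_that("MSE loss option also learns the separable problem", {
  tr <- toy_patch_set(60, seed = 24)
  va <- toy_patch_set(20, seed = 25)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 32, loss = "mse"), seed = 26)
  expect_gte(fit$history$val_acc[nrow(fit$history)], 0.95)
})

test_that("tidy and glance summarize a fitted classifier", {
  tr <- toy_patch_set(40, seed = 27)
  va <- toy_patch_set(10, seed = 28)
  fit <- train_cnn(build_cnn("state"), tr, va,
                   train_config(batch_size = 16, max_epochs = 1), seed = 29)
  h <- tidy(fit)
  expect_true(all(c("iteration", "val_acc", "val_loss") %in% names(h)))
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_classes, 2L)
  expect_gt(g$n_parameters, 10000)
})
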