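#' Build a CNN architecture specification
#'
#' Two compact architectures are used, identical in topology and differing
#' only in capacity:
#'
#' * `"selection"` (4-class vesicle-selection filter): conv layers with 16,
#'   32 and 64 filters, fully connected output of size 4.
#' * `"state"` (2-class phase-state classifier): conv layers with 8, 16 and
#'   32 filters, fully connected output of size 2.
#'
#' Both take 50 x 50 x 1 inputs with zero-center normalization (the
#' training-set mean image is subtracted); each convolution is 3 x 3 with
#' 'same' padding followed by batch normalization and ReLU; 2 x 2 max
#' pooling with stride 2 follows the first and second conv blocks (spatial
#' path 50 -> 25 -> 12); the fully connected layer feeds a softmax.
#'
#' @param kind `"selection"` or `"state"`.
#' @return A `cnn_spec`: list with `kind`, `input_shape`, `normalization`,
#'   `conv_filters`, `fc_output` and a `layers` tibble (one row per layer
#'   with kernel/pool geometry) for auditing.
#' @export
build_cnn <- function(kind = c("selection", "state")) {
  kind <- match.arg(kind)
  filters <- if (kind == "selection") c(16L, 32L, 64L) else c(8L, 16L, 32L)
  fc_output <- if (kind == "selection") 4L else 2L
  sizes <- c(50L, 25L, 12L)
  layers <- tibble::tibble(
    layer = c("input",
              "conv1", "batchnorm1", "relu1", "maxpool1",
              "conv2", "batchnorm2", "relu2", "maxpool2",
              "conv3", "batchnorm3", "relu3",
              "fc", "softmax"),
    type = c("imageInput", "conv", "batchnorm", "relu", "maxpool",
             "conv", "batchnorm", "relu", "maxpool",
             "conv", "batchnorm", "relu", "fc", "softmax"),
    filters = c(NA, filters[1], NA, NA, NA, filters[2], NA, NA, NA,
                filters[3], NA, NA, NA, NA),
    kernel = c(NA, 3L, NA, NA, NA, 3L, NA, NA, NA, 3L, NA, NA, NA, NA),
    padding = c(NA, "same", NA, NA, NA, "same", NA, NA, NA, "same",
                NA, NA, NA, NA),
    pool_size = c(NA, NA, NA, NA, 2L, NA, NA, NA, 2L, NA, NA, NA, NA, NA),
    stride = c(NA, NA, NA, NA, 2L, NA, NA, NA, 2L, NA, NA, NA, NA, NA),
    output_size = c(sizes[1], sizes[1], sizes[1], sizes[1], sizes[2],
                    sizes[2], sizes[2], sizes[2], sizes[3],
                    sizes[3], sizes[3], sizes[3], fc_output, fc_output))
  structure(list(kind = kind, input_shape = c(50L, 50L, 1L),
                 normalization = "zerocenter", conv_filters = filters,
                 fc_output = fc_output, layers = layers),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> %s: conv %s, fc %d, 50x50x1 zerocenter input\n",
              x$kind, paste(x$conv_filters, collapse = "/"), x$fc_output))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the reference training recipe for both networks:
#' stochastic gradient descent with momentum (SGDM), initial learning rate
#' 0.01, at most 4 epochs, validation every 30 iterations. Momentum 0.9,
#' batch size 128 and L2 decay 1e-4 are conventional SGDM settings.
#'
#' @param initial_lr initial learning rate.
#' @param max_epochs full passes over the training set.
#' @param validation_frequency iterations between validation evaluations.
#' @param momentum SGDM momentum coefficient.
#' @param batch_size mini-batch size.
#' @param l2 L2 weight-decay coefficient (weights only).
#' @param bn_momentum running-statistics update rate of the batch-norm
#'   layers.
#' @param loss `"crossentropy"` (default) or `"mse"` (mean squared error on
#'   the softmax outputs).
#' @param shuffle reshuffle the training set every epoch.
#' @param verbose print a line per validation.
#' @return list of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, max_epochs = 4,
                         validation_frequency = 30, momentum = 0.9,
                         batch_size = 128, l2 = 1e-4, bn_momentum = 0.1,
                         loss = c("crossentropy", "mse"), shuffle = TRUE,
                         verbose = FALSE) {
  loss <- match.arg(loss)
  structure(as.list(environment()), class = "train_config")
}

glorot <- function(nr, nc, fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

init_params <- function(spec) {
  f <- spec$conv_filters; nc <- spec$fc_output
  fin <- c(9 * 1, 9 * f[1], 9 * f[2])
  fout <- 9 * f
  list(
    W1 = glorot(f[1], 9, fin[1], fout[1]), b1 = numeric(f[1]),
    g1 = rep(1, f[1]), beta1 = numeric(f[1]),
    rm1 = numeric(f[1]), rv1 = rep(1, f[1]),
    W2 = glorot(f[2], 9 * f[1], fin[2], fout[2]), b2 = numeric(f[2]),
    g2 = rep(1, f[2]), beta2 = numeric(f[2]),
    rm2 = numeric(f[2]), rv2 = rep(1, f[2]),
    W3 = glorot(f[3], 9 * f[2], fin[3], fout[3]), b3 = numeric(f[3]),
    g3 = rep(1, f[3]), beta3 = numeric(f[3]),
    rm3 = numeric(f[3]), rv3 = rep(1, f[3]),
    Wfc = glorot(nc, 144 * f[3], 144 * f[3], nc), bfc = numeric(nc))
}

zero_like <- function(params) {
  v <- lapply(params[c("W1", "b1", "g1", "beta1", "W2", "b2", "g2", "beta2",
                       "W3", "b3", "g3", "beta3", "Wfc", "bfc")],
              function(x) x * 0)
  v
}

#' Train a CNN classifier on a labeled patch set
#'
#' Mini-batch SGDM training of a [build_cnn()] architecture. Patches are
#' zero-centered by subtracting the training-set mean image (the same mean
#' is stored in the classifier and applied at inference). The validation
#' set is evaluated every `validation_frequency` iterations and once more
#' after training; before that final evaluation the batch-norm statistics
#' are finalized over the whole training set with the trained weights (the
#' running statistics accumulated during SGD lag the weights they would
#' otherwise be used with). Training is single-threaded and fully
#' reproducible for a fixed `seed` (weight initialization and epoch
#' shuffling both draw from the seeded RNG).
#'
#' @param spec a `cnn_spec` from [build_cnn()].
#' @param train_set,val_set [patch_set()] objects with identical
#'   `class_names`; the training set must contain at least 2 classes.
#' @param config a [train_config()].
#' @param seed integer seed, or `NULL`.
#' @return A `guv_cnn` classifier: list with `spec`, `params`,
#'   `class_names`, `mean_image`, `history` tibble (iteration, epoch,
#'   train_loss, train_acc, val_loss, val_acc, final), `config`.
#' @export
train_cnn <- function(spec, train_set, val_set, config = train_config(),
                      seed = NULL) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(train_set, "patch_set"),
            inherits(val_set, "patch_set"),
            inherits(config, "train_config"))
  if (!identical(train_set$class_names, val_set$class_names))
    stop("train and validation sets must share class_names")
  if (length(unique(train_set$labels)) < 2)
    stop("training set must contain at least 2 classes")
  if (length(train_set$class_names) != spec$fc_output)
    stop("class count does not match the network's fc_output")
  with_seed(seed, {
    mean_image <- apply(train_set$patches, c(1, 2), mean)
    Xtr <- sweep(train_set$patches, c(1, 2), mean_image, "-")
    Xva <- sweep(val_set$patches, c(1, 2), mean_image, "-")
    ytr <- train_set$labels - 1L
    yva <- val_set$labels - 1L
    params <- init_params(spec)
    vel <- zero_like(params)
    n <- dim(Xtr)[3]
    bs <- config$batch_size
    iters_per_epoch <- ceiling(n / bs)
    total_iters <- iters_per_epoch * config$max_epochs
    loss_type <- if (config$loss == "crossentropy") 0L else 1L
    hist <- list()
    it <- 0L
    validate <- function(final = FALSE, tr_loss = NA, tr_acc = NA) {
      pv <- .cpp_cnn_predict(Xva, params)
      pred <- max.col(t(pv)) - 1L
      val_acc <- mean(pred == yva)
      val_loss <- if (loss_type == 0L) {
        -mean(log(pmax(pv[cbind(yva + 1L, seq_along(yva))], 1e-12)))
      } else {
        tv <- matrix(0, nrow(pv), ncol(pv))
        tv[cbind(yva + 1L, seq_along(yva))] <- 1
        mean(colSums((pv - tv)^2) / nrow(pv))
      }
      if (config$verbose)
        message(sprintf("iter %d: val_acc %.4f val_loss %.4f", it,
                        val_acc, val_loss))
      hist[[length(hist) + 1]] <<- tibble::tibble(
        iteration = it, epoch = ceiling(it / iters_per_epoch),
        train_loss = tr_loss, train_acc = tr_acc,
        val_loss = val_loss, val_acc = val_acc, final = final)
    }
    last <- list(loss = NA_real_, acc = NA_real_)
    for (ep in seq_len(config$max_epochs)) {
      ord <- if (config$shuffle) sample.int(n) else seq_len(n)
      for (b in seq_len(iters_per_epoch)) {
        idx <- ord[((b - 1) * bs + 1):min(b * bs, n)]
        res <- .cpp_cnn_train_batch(Xtr[, , idx, drop = FALSE],
                                    ytr[idx], params, vel,
                                    config$initial_lr, config$momentum,
                                    config$l2, config$bn_momentum, loss_type)
        params <- res$params
        # running BN stats live inside params; velocities separate
        vel <- res$vel
        it <- it + 1L
        if (it %% config$validation_frequency == 0 && it < total_iters)
          validate(tr_loss = res$loss, tr_acc = res$acc)
        last <- res
      }
    }
    # finalize batch-norm statistics on the full training set with the
    # trained weights (running statistics collected during SGD lag the
    # weights they end up used with), then take the final validation
    params <- .cpp_cnn_finalize_bn(Xtr, params, bs)
    validate(final = TRUE, tr_loss = last$loss, tr_acc = last$acc)
    structure(list(spec = spec, params = params,
                   class_names = train_set$class_names,
                   mean_image = mean_image,
                   history = dplyr::bind_rows(hist), config = config),
              class = "guv_cnn")
  })
}

#' @export
print.guv_cnn <- function(x, ...) {
  fin <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<guv_cnn> %s (%s): %d classes, final validation accuracy %.2f%%\n",
    x$spec$kind, paste(x$spec$conv_filters, collapse = "/"),
    length(x$class_names), 100 * fin$val_acc))
  invisible(x)
}

#' Classify 50x50 patches
#'
#' @param classifier a `guv_cnn` from [train_cnn()].
#' @param patches a 50x50 matrix or a `50 x 50 x n` array.
#' @return A tibble with one row per patch: `class`, `prob` (probability of
#'   the assigned class) and one `p_<class>` column per class; softmax
#'   probabilities sum to 1.
#' @export
classify <- function(classifier, patches) {
  stopifnot(inherits(classifier, "guv_cnn"))
  if (is.matrix(patches)) patches <- array(patches, c(dim(patches), 1))
  if (dim(patches)[1] != 50 || dim(patches)[2] != 50)
    stop("patches must be 50 x 50")
  X <- sweep(patches, c(1, 2), classifier$mean_image, "-")
  pv <- .cpp_cnn_predict(X, classifier$params) # nc x n
  cls <- classifier$class_names[max.col(t(pv))]
  out <- tibble::tibble(class = cls, prob = apply(pv, 2, max))
  probs <- tibble::as_tibble(as.data.frame(t(pv)))
  names(probs) <- paste0("p_", classifier$class_names)
  dplyr::bind_cols(out, probs)
}

#' @export
predict.guv_cnn <- function(object, patches, ...) {
  classify(object, patches)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a classifier
#'
#' @param x a `guv_cnn`.
#' @param ... unused.
#' @return The history tibble (one row per validation evaluation).
#' @method tidy guv_cnn
#' @export
tidy.guv_cnn <- function(x, ...) x$history

#' One-row training summary of a classifier
#'
#' @param x a `guv_cnn`.
#' @param ... unused.
#' @return tibble with `kind`, `n_classes`, `n_parameters`, `iterations`,
#'   `final_val_acc`, `final_val_loss`.
#' @method glance guv_cnn
#' @export
glance.guv_cnn <- function(x, ...) {
  fin <- x$history[nrow(x$history), ]
  npar <- sum(vapply(x$params[c("W1", "b1", "g1", "beta1", "W2", "b2", "g2",
                                "beta2", "W3", "b3", "g3", "beta3", "Wfc",
                                "bfc")], length, numeric(1)))
  tibble::tibble(kind = x$spec$kind, n_classes = length(x$class_names),
                 n_parameters = npar, iterations = fin$iteration,
                 final_val_acc = fin$val_acc, final_val_loss = fin$val_loss)
}

#' Save / load a trained classifier
#'
#' The weights are stored as an RDS checkpoint with a JSON sidecar carrying
#' the class names, architecture summary and normalization-statistics
#' checksum, so a checkpoint can be identified without loading it.
#'
#' @param classifier a `guv_cnn`.
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly (for `save_cnn`); the classifier (for
#'   `load_cnn`).
#' @export
save_cnn <- function(classifier, path) {
  stopifnot(inherits(classifier, "guv_cnn"))
  saveRDS(classifier, path)
  sidecar <- list(
    kind = classifier$spec$kind,
    class_names = classifier$class_names,
    conv_filters = classifier$spec$conv_filters,
    fc_output = classifier$spec$fc_output,
    mean_image_sum = sum(classifier$mean_image),
    final_val_acc = classifier$history$val_acc[nrow(classifier$history)])
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "guv_cnn")) stop("not a guv_cnn checkpoint: ", path)
  x
}

#' CNN-based vesicle-selection filter
#'
#' Replaces the computational edge-contrast filter (programs 2 and 3): each
#' detected section circle is cropped to a 50x50 patch and classified by
#' the 4-class selection network; only sections classified C1 (typical
#' unilamellar vesicle) pass. Entity acceptance downstream still follows
#' the stack-assembly rules on the passing sections.
#'
#' @param stack detection-channel [guv_stack()].
#' @param detections tibble with `z_index`, `cx`, `cy`, `r`.
#' @param classifier a 4-class `guv_cnn`.
#' @param margin patch margin (multiple of r).
#' @return `detections` with `class`, `class_prob` and `pass` columns.
#' @export
cnn_selection_filter <- function(stack, detections, classifier,
                                 margin = 1.2) {
  stopifnot(inherits(classifier, "guv_cnn"))
  if (length(classifier$class_names) != 4)
    stop("selection classifier must have 4 classes")
  if (nrow(detections) == 0)
    return(dplyr::mutate(detections, class = character(),
                         class_prob = numeric(), pass = logical()))
  X <- array(0, c(50, 50, nrow(detections)))
  for (i in seq_len(nrow(detections))) {
    X[, , i] <- prepare_patch(stack$sections[[detections$z_index[i] + 1L]],
                              detections[i, ], margin = margin)
  }
  res <- classify(classifier, X)
  dplyr::mutate(detections, class = res$class, class_prob = res$prob,
                pass = res$class == classifier$class_names[1])
}
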