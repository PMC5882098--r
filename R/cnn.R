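# The small fully-convolutional classifier.
#
# The network is a stack of [conv -> batch norm -> ReLU -> optional 2x2 max
# pool] stages followed by a 1-output-pixel convolutional head to 2 classes
# and a softmax.  All convolutions are "valid" (no padding) and bias-free
# where followed by batch normalization.  Because there is no dense layer the
# trained network can be applied to an arbitrarily large region of interest,
# yielding a dense failing-class probability map at the network's natural
# stride (the product of its pooling factors).

#' Architecture specification
#'
#' The default layout is the reference network: input 64 x 64 x 3 ->
#' \[3x3 conv 16, BN, ReLU, pool\] -> \[3x3 conv 16, BN, ReLU, pool\] ->
#' \[3x3 conv 24, BN, ReLU, pool\] -> \[3x3 conv 30, BN, ReLU\] ->
#' 4x4 conv to 2 channels (+ bias) -> softmax.  It has 13,806 learnable
#' parameters (approximately 13.5k) and maps one 64-px input to exactly one
#' output pixel, so the dense-map stride is 8.
#'
#' @param input_px input patch side (default 64).
#' @param input_channels input channels (default 3, RGB).
#' @param stages list of stages, each `list(kernel, out_channels, bn, relu,
#'   pool)`.
#' @param head_kernel kernel side of the 2-class convolutional head.
#' @param n_classes number of output classes (default 2).
#' @return object of class `hf_cnn_arch`.
#' @export
cnn_architecture <- function(input_px = 64, input_channels = 3,
                             stages = list(
                               list(kernel = 3, out_channels = 16, bn = TRUE, relu = TRUE, pool = TRUE),
                               list(kernel = 3, out_channels = 16, bn = TRUE, relu = TRUE, pool = TRUE),
                               list(kernel = 3, out_channels = 24, bn = TRUE, relu = TRUE, pool = TRUE),
                               list(kernel = 3, out_channels = 30, bn = TRUE, relu = TRUE, pool = FALSE)),
                             head_kernel = 4, n_classes = 2) {
  sm <- t(vapply(stages, function(s)
    c(s$kernel, s$out_channels, as.integer(isTRUE(s$bn)),
      as.integer(isTRUE(s$relu)), as.integer(isTRUE(s$pool))), numeric(5)))
  storage.mode(sm) <- "integer"
  arch <- structure(list(input_px = as.integer(input_px),
                         input_channels = as.integer(input_channels),
                         stage_matrix = sm,
                         head_kernel = as.integer(head_kernel),
                         n_classes = as.integer(n_classes)),
                    class = "hf_cnn_arch")
  # validate spatial dimensions on the nominal input
  h <- input_px
  for (i in seq_len(nrow(sm))) {
    h <- h - sm[i, 1] + 1
    if (sm[i, 5] == 1L) h <- h %/% 2L
    if (h < 1)
      stop_invalid_architecture(sprintf(
        "stage %d produces non-positive spatial size on a %d-px input", i, input_px))
  }
  if (h - head_kernel + 1 < 1)
    stop_invalid_architecture("head kernel larger than the remaining spatial size")
  arch
}

# spatial output side and stride for an input of side s
arch_output_side <- function(arch, s) {
  sm <- arch$stage_matrix
  for (i in seq_len(nrow(sm))) {
    s <- s - sm[i, 1] + 1
    if (sm[i, 5] == 1L) s <- s %/% 2L
    if (s < 1) return(0L)
  }
  s - arch$head_kernel + 1L
}

arch_stride <- function(arch) prod(ifelse(arch$stage_matrix[, 5] == 1L, 2L, 1L))

# closed-form learnable parameter count
arch_param_count <- function(arch) {
  sm <- arch$stage_matrix
  cin <- arch$input_channels
  total <- 0
  for (i in seq_len(nrow(sm))) {
    k <- sm[i, 1]; cout <- sm[i, 2]
    total <- total + k^2 * cin * cout +
      if (sm[i, 3] == 1L) 2 * cout else cout  # BN scale/shift or conv bias
    cin <- cout
  }
  total + arch$head_kernel^2 * cin * arch$n_classes + arch$n_classes
}

#' Build (initialize) the classifier
#'
#' Weights use seeded He-normal initialization (sd = sqrt(2 / fan-in));
#' batch-norm scales start at 1, shifts at 0, running statistics at (0, 1).
#'
#' @param arch an [cnn_architecture()] object.
#' @param rng_seed integer seed for the weight draw.
#' @return object of class `hf_cnn` (untrained).
#' @export
build_cnn <- function(arch = cnn_architecture(), rng_seed = 1L) {
  if (!inherits(arch, "hf_cnn_arch"))
    stop_invalid_argument("`arch` must be created by cnn_architecture()")
  sm <- arch$stage_matrix
  params <- list(); velocity <- list()
  withr::with_seed(as.integer(rng_seed), {
    cin <- arch$input_channels
    for (i in seq_len(nrow(sm))) {
      k <- sm[i, 1]; cout <- sm[i, 2]
      fan_in <- k^2 * cin
      W <- matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)), cout, fan_in)
      params[[paste0("W", i)]] <- W
      velocity[[paste0("W", i)]] <- W * 0
      if (sm[i, 3] == 1L) {
        params[[paste0("gamma", i)]] <- rep(1, cout)
        params[[paste0("beta", i)]] <- rep(0, cout)
        params[[paste0("rmean", i)]] <- rep(0, cout)
        params[[paste0("rvar", i)]] <- rep(1, cout)
        velocity[[paste0("gamma", i)]] <- rep(0, cout)
        velocity[[paste0("beta", i)]] <- rep(0, cout)
      } else {
        params[[paste0("b", i)]] <- rep(0, cout)
        velocity[[paste0("b", i)]] <- rep(0, cout)
      }
      cin <- cout
    }
    fan_in <- arch$head_kernel^2 * cin
    params$Wh <- matrix(stats::rnorm(arch$n_classes * fan_in, sd = sqrt(1 / fan_in)),
                        arch$n_classes, fan_in)
    params$bh <- rep(0, arch$n_classes)
    velocity$Wh <- params$Wh * 0
    velocity$bh <- rep(0, arch$n_classes)
  })
  structure(list(arch = arch, params = params, velocity = velocity,
                 trained = FALSE, log = NULL, seed = as.integer(rng_seed)),
            class = "hf_cnn")
}

#' Count learnable parameters
#'
#' Convolution weights and biases plus batch-norm scale/shift; batch-norm
#' running statistics are excluded.
#'
#' @param model an `hf_cnn` (or a bare parameter list).
#' @return integer count.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "hf_cnn")) model$params else model
  nm <- names(params)
  learn <- nm[!grepl("^r(mean|var)", nm)]
  sum(vapply(params[learn], length, 1))
}

#' Training configuration
#'
#' @param epochs training epochs (default 30).
#' @param batch_size mini-batch size (default 64).
#' @param optimizer only `"sgd"` is provided.
#' @param learning_rate,momentum,weight_decay SGD hyper-parameters
#'   (defaults 0.01, 0.9, 5e-4).
#' @param lr_step epoch after which the learning rate is multiplied by
#'   `lr_gamma` (default 20, gamma 0.1).
#' @param lr_gamma step-decay factor.
#' @param rng_seed seed for mini-batch shuffling.
#' @return object of class `hf_train_config`.
#' @export
training_config <- function(epochs = 30, batch_size = 64,
                            optimizer = c("sgd"), learning_rate = 0.01,
                            momentum = 0.9, weight_decay = 5e-4,
                            lr_step = 20, lr_gamma = 0.1, rng_seed = 1L) {
  epochs <- check_count(epochs, "epochs")
  batch_size <- check_count(batch_size, "batch_size")
  optimizer <- match.arg(optimizer)
  structure(list(epochs = epochs, batch_size = batch_size,
                 optimizer = optimizer, learning_rate = learning_rate,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_step = lr_step, lr_gamma = lr_gamma,
                 rng_seed = as.integer(rng_seed)),
            class = "hf_train_config")
}

# forward inference on a raw patch/image array, in batches; returns the
# failing-class probability matrix (one column of map values per sample)
cnn_infer <- function(model, raw_array) {
  d <- dim(raw_array)
  out <- cnn_forward_cpp(model$arch[c("stage_matrix", "input_channels",
                                      "head_kernel", "n_classes")],
                         model$params, raw_array, as.integer(d))
  list(probs = out$probs, oh = out$oh, ow = out$ow)
}

patch_class_index <- function(labels) {
  # class index 0 = failing (global convention: output channel 1 is failing)
  bin <- label_to_binary(labels)
  as.integer(ifelse(bin, 0L, 1L))
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy with SGD + momentum under the supplied
#' configuration.  When a validation set is given, the weights from the epoch
#' with the best validation patch accuracy are retained; otherwise the final
#' weights are kept.  A trailing mini-batch of fewer than two patches is
#' dropped (batch statistics are undefined for it).
#'
#' @param model an `hf_cnn` from [build_cnn()].
#' @param train_patches an `hf_patches` set with both classes present.
#' @param val_patches optional `hf_patches` validation set.
#' @param config an [training_config()].
#' @return the trained `hf_cnn`, with a per-epoch log (`$log`: epoch, lr,
#'   loss, train_acc, val_acc).
#' @export
train_cnn <- function(model, train_patches, val_patches = NULL,
                      config = training_config()) {
  if (!inherits(model, "hf_cnn")) stop_invalid_argument("`model` must be an hf_cnn")
  if (!inherits(train_patches, "hf_patches"))
    stop_invalid_argument("`train_patches` must be an hf_patches")
  if (train_patches$patch_px != model$arch$input_px)
    stop_invalid_argument(sprintf("patches are %d px but the network expects %d px",
                                  train_patches$patch_px, model$arch$input_px))
  y <- patch_class_index(train_patches$meta$label)
  if (length(unique(y)) < 2L)
    stop_invalid_data("training set must contain both classes")
  if (!is.null(val_patches) && val_patches$patch_px != model$arch$input_px)
    stop_invalid_argument("validation patch size mismatch")
  n <- n_patches(train_patches)
  arch_slice <- model$arch[c("stage_matrix", "input_channels", "head_kernel",
                             "n_classes")]
  log <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                    train_acc = numeric(0), val_acc = numeric(0))
  best <- list(acc = -Inf, params = NULL)
  withr::with_seed(config$rng_seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        ifelse(epoch > config$lr_step, config$lr_gamma, 1)
      ord <- sample.int(n) - 1L
      res <- cnn_train_epoch_cpp(arch_slice, model$params, model$velocity,
                                 train_patches$pixels,
                                 as.integer(dim(train_patches$pixels)),
                                 y, ord, lr, config$momentum,
                                 config$weight_decay, config$batch_size, 0.1)
      model$params <- res$params
      model$velocity <- res$velocity
      val_acc <- NA_real_
      if (!is.null(val_patches)) {
        vp <- predict(model, val_patches)
        vy <- label_to_binary(val_patches$meta$label)
        val_acc <- mean((vp > 0.5) == vy)
        if (val_acc > best$acc) best <- list(acc = val_acc, params = model$params)
      }
      log <- rbind(log, data.frame(epoch = epoch, lr = lr, loss = res$loss,
                                   train_acc = res$acc, val_acc = val_acc))
    }
  })
  if (!is.null(val_patches) && !is.null(best$params)) model$params <- best$params
  model$trained <- TRUE
  model$log <- log
  model
}

#' Predict failing-class probabilities
#'
#' For an `hf_patches` set, returns one probability per patch (applying the
#' network in inference mode, batch-norm running statistics).  For an
#' `hf_roi`, returns the dense probability map (see
#' [predict_probability_map()]).
#'
#' @param object a trained `hf_cnn`.
#' @param newdata an `hf_patches` or `hf_roi`.
#' @param batch inference batch size for patches.
#' @param ... unused.
#' @return numeric vector of probabilities, or an `hf_probmap`.
#' @export
predict.hf_cnn <- function(object, newdata, batch = 512L, ...) {
  if (inherits(newdata, "hf_roi"))
    return(predict_probability_map(object, newdata))
  if (!inherits(newdata, "hf_patches"))
    stop_invalid_argument("`newdata` must be hf_patches or hf_roi")
  n <- n_patches(newdata)
  p <- newdata$patch_px
  if (arch_output_side(object$arch, p) != 1L)
    stop_invalid_argument("patch size does not map to a single output pixel")
  probs <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    end <- min(n, start + batch - 1L)
    sub <- newdata$pixels[, , , start:end, drop = FALSE]
    out <- cnn_infer(object, sub)
    probs[start:end] <- out$probs[1L, ]  # channel 1 = failing
  }
  probs
}

#' Dense probability map over a region of interest
#'
#' Applies the fully-convolutional network across the whole ROI, yielding at
#' each map location the same probability the network would produce on the
#' corresponding input-sized crop (stride = the network's pooling factor).
#'
#' @param model a trained `hf_cnn`.
#' @param roi an `hf_roi` with side at least the network input size.
#' @return object of class `hf_probmap`: `values` (matrix of failing
#'   probabilities), `downsample_factor`, `roi_id`.
#' @export
predict_probability_map <- function(model, roi) {
  if (!inherits(model, "hf_cnn")) stop_invalid_argument("`model` must be an hf_cnn")
  if (!inherits(roi, "hf_roi")) stop_invalid_argument("`roi` must be an hf_roi")
  if (roi$side_px < model$arch$input_px)
    stop_invalid_argument("ROI is smaller than the network's receptive field")
  raw_arr <- array(as.raw(roi$pixels), dim = c(dim(roi$pixels), 1L))
  out <- cnn_infer(model, raw_arr)
  vals <- matrix(out$probs[1L, ], out$oh, out$ow)
  structure(list(values = vals, downsample_factor = arch_stride(model$arch),
                 roi_id = roi$roi_id),
            class = "hf_probmap")
}

#' Image-level probability from a probability map
#'
#' The arithmetic mean of all map values ("the pixels in a single image were
#' averaged").
#'
#' @param map an `hf_probmap` (or a bare numeric matrix).
#' @return single probability.
#' @export
image_probability <- function(map) {
  vals <- if (inherits(map, "hf_probmap")) map$values else map
  if (length(vals) == 0) stop_degenerate_input("empty probability map")
  mean(vals)
}

#' @export
print.hf_cnn <- function(x, ...) {
  sm <- x$arch$stage_matrix
  cat(sprintf("<hf_cnn> %d-px input, %d stages, %d parameters, stride %d%s\n",
              x$arch$input_px, nrow(sm), count_parameters(x), arch_stride(x$arch),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

#' @export
summary.hf_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$log)) {
    cat("training log (last 5 epochs):\n")
    print(utils::tail(object$log, 5))
  }
  invisible(object)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint embeds the architecture, parameters and training log in a
#' single versioned file.
#'
#' @param model an `hf_cnn`.
#' @param path file path.
#' @return `save_cnn` the path invisibly; `load_cnn` the restored `hf_cnn`.
#' @export
save_cnn <- function(model, path) {
  if (!inherits(model, "hf_cnn")) stop_invalid_argument("`model` must be an hf_cnn")
  obj <- model
  obj$checkpoint_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "hf_cnn")) stop_invalid_state("file is not an hf_cnn checkpoint")
  obj
}

#' Export a probability map as 32-bit float TIFF
#'
#' @param map an `hf_probmap`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_probability_map <- function(map, path) {
  tiff::writeTIFF(map$values, path, bits.per.sample = 32L)
  invisible(path)
}
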