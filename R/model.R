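# Model configuration, construction, training (Adam with per-epoch decay)
# and prediction for both architectures.

#' Model and training configuration
#'
#' Defaults follow the full-scale architecture: 3 encoder and 3 decoder
#' layers, hidden size 32, 2 attention heads, dropout 0.5, Adam with
#' learning rate 0.001 decayed by 0.97 per epoch, batch size 256.
#' `patch_size` controls the image tokenization (8x8 patches on a 64x64
#' image give 64 tokens).
#'
#' @param n_classes Number of output classes.
#' @param arch `"transformer"` or `"cnn"` (4-conv ablation network).
#' @param n_encoder_layers,n_decoder_layers Transformer stack depths.
#' @param hidden_size Model width; must be divisible by `n_heads`.
#' @param n_heads Attention heads.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param patch_size Patch side length; must divide the image size.
#' @param ff_mult Feed-forward width multiplier (width = `ff_mult *
#'   hidden_size`).
#' @param lr Adam learning rate.
#' @param lr_decay Multiplicative per-epoch learning-rate decay.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes, arch = c("transformer", "cnn"),
                         n_encoder_layers = 3L, n_decoder_layers = 3L,
                         hidden_size = 32L, n_heads = 2L, dropout = 0.5,
                         patch_size = 8L, ff_mult = 4L,
                         lr = 0.001, lr_decay = 0.97, batch_size = 256L,
                         epochs = 10L, seed = 1L) {
  arch <- match.arg(arch)
  if (!is_count(n_classes) || n_classes < 2)
    stop2("`n_classes` must be an integer >= 2")
  if (hidden_size %% n_heads != 0)
    stop2("`hidden_size` must be divisible by `n_heads`")
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop2("`dropout` must be in [0, 1)")
  if (!is_count(epochs) || epochs < 0)
    stop2("`epochs` must be a non-negative integer")
  structure(list(n_classes = as.integer(n_classes), arch = arch,
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 hidden_size = as.integer(hidden_size),
                 n_heads = as.integer(n_heads), dropout = dropout,
                 patch_size = as.integer(patch_size),
                 ff_mult = as.integer(ff_mult),
                 lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) classifier
#'
#' Parameter initialization is deterministic given `config$seed`.
#'
#' @param config A [model_config()].
#' @param image_size Input image side length; must be divisible by
#'   `patch_size` (transformer) or by 16 (cnn, four 2x2 pools).
#' @param class_names Optional class-name vector of length `n_classes`.
#' @return An object of class `s2i_model`.
#' @export
build_model <- function(config, image_size, class_names = NULL) {
  stopifnot(inherits(config, "model_config"))
  image_size <- as.integer(image_size)
  if (is.null(class_names))
    class_names <- as.character(seq_len(config$n_classes))
  if (length(class_names) != config$n_classes)
    stop2("`class_names` must have length n_classes")
  if (config$arch == "transformer") {
    if (image_size %% config$patch_size != 0)
      stop2("image_size must be divisible by patch_size")
    st <- tr_struct(image_size, config$patch_size)
    params <- with_seed(config$seed, tr_init_params(config, st))
  } else {
    st <- cnn_struct(image_size)
    params <- with_seed(config$seed, cnn_init_params(config, st))
  }
  structure(list(config = config, image_size = image_size,
                 class_names = class_names, params = params, struct = st,
                 training_log = data.frame()),
            class = "s2i_model")
}

#' @export
print.s2i_model <- function(x, ...) {
  cat(sprintf("<s2i_model> arch=%s image=%dx%d classes=%d params=%d%s\n",
              x$config$arch, x$image_size, x$image_size,
              x$config$n_classes, count_parameters(x),
              if (nrow(x$training_log)) " (trained)" else " (untrained)"))
  invisible(x)
}

#' Number of learnable parameters
#' @param model An `s2i_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

model_forward_sample <- function(model, img, train = FALSE) {
  if (model$config$arch == "transformer")
    tr_forward_sample(model$params, model$config, model$struct, img, train)
  else
    cnn_forward_sample(model$params, model$config, model$struct, img, train)
}

model_backward_sample <- function(model, cache, dlogits) {
  if (model$config$arch == "transformer")
    tr_backward_sample(model$params, model$config, model$struct, cache,
                       dlogits)
  else
    cnn_backward_sample(model$params, model$config, model$struct, cache,
                        dlogits)
}

# Mean cross-entropy and averaged gradients over one minibatch.
model_batch_fb <- function(model, images, labels, train = TRUE) {
  n <- length(images)
  total <- NULL
  loss <- 0
  for (b in seq_len(n)) {
    fw <- model_forward_sample(model, images[[b]], train = train)
    z <- fw$logits - max(fw$logits)
    probs <- exp(z) / sum(exp(z))
    loss <- loss - log(max(probs[labels[b]], 1e-12))
    dlog <- probs
    dlog[labels[b]] <- dlog[labels[b]] - 1
    total <- accumulate_grads(total,
                              model_backward_sample(model, fw$cache, dlog))
  }
  list(loss = loss / n, grads = scale_grads(total, 1 / n))
}

model_probs <- function(model, images) {
  out <- matrix(0, length(images), model$config$n_classes)
  for (b in seq_along(images)) {
    lg <- model_forward_sample(model, images[[b]], train = FALSE)$logits
    z <- lg - max(lg)
    out[b, ] <- exp(z) / sum(exp(z))
  }
  colnames(out) <- model$class_names
  out
}

check_images_match <- function(model, ds) {
  stopifnot(inherits(ds, "image_dataset"))
  if (ds$image_size != model$image_size)
    stop2("image size ", ds$image_size, " does not match model (",
          model$image_size, ")")
}

#' Train a classifier
#'
#' Adam with per-epoch multiplicative learning-rate decay (`lr *
#' lr_decay^(epoch-1)`), minibatch shuffling and dropout all seeded by
#' `config$seed`.  Per-epoch training loss, learning rate and validation
#' accuracy are logged; the returned model carries the parameters of the
#' epoch with the best validation accuracy (ties resolved to the later
#' epoch).  `epochs = 0` returns the initialized model unchanged with an
#' empty log.
#'
#' @param model An `s2i_model` from [build_model()].
#' @param train An [image_dataset()] used for gradient steps.
#' @param val An [image_dataset()] used for epoch selection.
#' @param config Optional [model_config()] overriding `model$config` for
#'   the training schedule.
#' @return The trained `s2i_model` with a populated `training_log`
#'   data frame (`epoch`, `lr`, `train_loss`, `val_accuracy`).
#' @export
train_model <- function(model, train, val, config = model$config) {
  stopifnot(inherits(model, "s2i_model"))
  check_images_match(model, train)
  check_images_match(model, val)
  if (length(train) == 0L || length(val) == 0L)
    stop2("training and validation datasets must be nonempty")
  if (max(train$labels) > model$config$n_classes ||
      max(val$labels) > model$config$n_classes)
    stop2("label index outside the model's classes")
  if (config$epochs == 0L) {
    model$training_log <- data.frame(epoch = integer(), lr = numeric(),
                                     train_loss = numeric(),
                                     val_accuracy = numeric())
    return(model)
  }
  n <- length(train)
  state <- adam_init(model$params)
  best <- list(acc = -Inf, params = model$params)
  log <- vector("list", config$epochs)
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr_e <- config$lr * config$lr_decay^(epoch - 1)
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        fb <- model_batch_fb(model, train$images[idx], train$labels[idx],
                             train = TRUE)
        upd <- adam_step(model$params, fb$grads, state, lr_e)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + fb$loss
        nb <- nb + 1L
      }
      pr <- model_probs(model, val$images)
      acc <- mean(max.col(pr, ties.method = "first") == val$labels)
      if (acc >= best$acc) best <- list(acc = acc, params = model$params)
      log[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                                 train_loss = ep_loss / nb,
                                 val_accuracy = acc)
    }
  })
  model$params <- best$params
  model$training_log <- do.call(rbind, log)
  model
}

#' Predict class probabilities and labels
#'
#' Deterministic (dropout disabled); argmax ties break to the lowest
#' class index.
#'
#' @param object A trained (or untrained) `s2i_model`.
#' @param images An [image_dataset()] matching the model's image size.
#' @param ... Unused.
#' @return List with `prob` (n x n_classes matrix, rows on the simplex),
#'   `labels` (integer argmax indices) and `class_names`.
#' @export
predict.s2i_model <- function(object, images, ...) {
  check_images_match(object, images)
  if (length(images) == 0L) {
    return(list(prob = matrix(0, 0L, object$config$n_classes),
                labels = integer(0), class_names = object$class_names))
  }
  pr <- model_probs(object, images$images)
  list(prob = pr,
       labels = max.col(pr, ties.method = "first"),
       class_names = object$class_names)
}
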