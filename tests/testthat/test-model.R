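test_that("scaled dot-product attention matches hand-computed cases", {
  # identical keys -> uniform weights -> every row is the column mean of V
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  K <- matrix(1, 3, 2)
  Q <- matrix(rnorm(4), 2, 2)
  out <- scaled_dot_product_attention(Q, K, V)
  expect_equal(out, matrix(colMeans(V), 2, 2, byrow = TRUE))

  # single key/value row: output is that row regardless of the query
  out <- scaled_dot_product_attention(matrix(rnorm(6), 3, 2),
                                      matrix(c(9, 9), 1, 2),
                                      matrix(c(4, 7), 1, 2))
  expect_equal(out, matrix(c(4, 7), 3, 2, byrow = TRUE))

  # 2x2 identity everywhere: closed-form softmax entry
  out <- scaled_dot_product_attention(diag(2), diag(2), diag(2))
  e <- exp(1 / sqrt(2))
  expect_equal(out[1, 1], e / (e + 1), tolerance = 1e-4)
  expect_equal(rowSums(out), c(1, 1))   # convex combinations of V rows

  expect_error(scaled_dot_product_attention(matrix(0, 2, 3),
                                            matrix(0, 2, 2),
                                            matrix(0, 2, 2)),
               "same number of columns")
  expect_error(scaled_dot_product_attention(matrix(0, 2, 2),
                                            matrix(0, 3, 2),
                                            matrix(0, 2, 2)),
               "same number of rows")
})

test_that("attention is equivariant under key/value permutation", {
  set.seed(3)
  Q <- matrix(rnorm(8), 4, 2)
  K <- matrix(rnorm(10), 5, 2)
  V <- matrix(rnorm(15), 5, 3)
  perm <- sample(5)
  expect_equal(scaled_dot_product_attention(Q, K, V),
               scaled_dot_product_attention(Q, K[perm, ], V[perm, ]))
})

test_that("multi-head attention reduces to the bare operator", {
  set.seed(4)
  H <- 4L
  X <- matrix(rnorm(3 * H), 3, H)
  W <- list(Wq = diag(H), bq = numeric(H), Wk = diag(H), bk = numeric(H),
            Wv = diag(H), bv = numeric(H), Wo = diag(H), bo = numeric(H))
  out <- sig2image:::mha_forward(X, X, W, n_heads = 1L)$out
  expect_equal(out, scaled_dot_product_attention(X, X, X))
})

test_that("feature extraction computes population moments", {
  f <- extract_features(raw_record("a", c(1, 2, 3), "x"))
  expect_equal(f$length, 3)
  expect_equal(f$mean, 2)
  expect_equal(f$std, sqrt(2 / 3))

  f <- extract_features(c(5, 5))
  expect_equal(f$std, 0)
  expect_equal(f$skewness, 0)
  expect_equal(f$kurtosis, 0)

  f <- extract_features(c(0, 0, 0, 1))
  expect_equal(f$mean, 0.25)
  expect_equal(f$median, 0)
  expect_lte(f$min, f$median)
  expect_lte(f$median, f$max)

  ds <- make_toy_signals(2)
  fd <- extract_features_dataset(ds)
  expect_equal(nrow(fd), length(ds))
  expect_s3_class(fd$label, "factor")
})

tiny_config <- function(arch = "transformer", ...) {
  defaults <- list(n_classes = 2L, arch = arch, n_encoder_layers = 1L,
                   n_decoder_layers = 1L, hidden_size = 8L, n_heads = 2L,
                   dropout = 0.1, patch_size = 4L, ff_mult = 2L,
                   batch_size = 16L, epochs = 3L, seed = 5L)
  do.call(model_config, modifyList(defaults, list(...)))
}

const_images <- function(levels, n_each, size = 8L, noise = 0.02,
                         seed = 1L) {
  set.seed(seed)
  imgs <- list(); labs <- integer(0)
  for (k in seq_along(levels)) {
    for (j in seq_len(n_each)) {
      imgs[[length(imgs) + 1L]] <-
        matrix(levels[k] + rnorm(size^2, 0, noise), size)
      labs <- c(labs, k)
    }
  }
  image_dataset(imgs, labs, paste0("lv", seq_along(levels)), "gadf", size)
}

test_that("model building is deterministic and validated", {
  cfg <- tiny_config()
  m1 <- build_model(cfg, 8L)
  m2 <- build_model(cfg, 8L)
  expect_identical(m1$params, m2$params)
  expect_error(build_model(cfg, 10L), "divisible")
  expect_error(model_config(n_classes = 2, hidden_size = 9, n_heads = 2),
               "divisible")
  expect_error(model_config(n_classes = 2, dropout = 1), "dropout")
  # 64x64 image with 8x8 patches tokenizes to 64 patches
  m <- build_model(tiny_config(patch_size = 8L), 64L)
  expect_equal(m$struct$n_tokens, 64L)
})

test_that("untrained models emit probability rows on the simplex", {
  set.seed(6)
  imgs <- const_images(c(0.2, 0.8), 3)
  for (arch in c("transformer", "cnn")) {
    m <- build_model(tiny_config(arch), if (arch == "cnn") 16L else 8L)
    batch <- if (arch == "cnn") const_images(c(0.2, 0.8), 3, size = 16L)
             else imgs
    pred <- predict(m, batch)
    expect_equal(rowSums(pred$prob), rep(1, 6), tolerance = 1e-6)
    pred2 <- predict(m, batch)
    expect_identical(pred$prob, pred2$prob)   # eval mode is deterministic
  }
})

test_that("empty prediction batches give empty outputs", {
  m <- build_model(tiny_config(), 8L)
  empty <- image_dataset(list(), integer(0), c("a", "b"), "gadf", 8L)
  pred <- predict(m, empty)
  expect_equal(dim(pred$prob), c(0L, 2L))
  expect_length(pred$labels, 0)
})

test_that("zero-epoch training returns the initialized model unchanged", {
  imgs <- const_images(c(0.1, 0.9), 4)
  m <- build_model(tiny_config(epochs = 0L), 8L)
  fit <- train_model(m, imgs, imgs)
  expect_identical(fit$params, m$params)
  expect_equal(nrow(fit$training_log), 0L)
})

test_that("the learning-rate schedule decays multiplicatively per epoch", {
  imgs <- const_images(c(0.1, 0.9), 3)
  cfg <- tiny_config(epochs = 10L, hidden_size = 4L, ff_mult = 1L)
  fit <- train_model(build_model(cfg, 8L), imgs, imgs)
  expect_equal(fit$training_log$lr[10], 0.001 * 0.97^9, tolerance = 1e-12)
  expect_equal(fit$training_log$lr[1], 0.001)
})

test_that("both architectures solve linearly separable constant images", {
  train <- const_images(c(0.1, 0.9), 25, size = 16L, seed = 2)
  val <- const_images(c(0.1, 0.9), 10, size = 16L, seed = 3)
  for (arch in c("transformer", "cnn")) {
    cfg <- tiny_config(arch, epochs = 10L, seed = 7L)
    fit <- train_model(build_model(cfg, 16L), train, val)
    expect_equal(max(fit$training_log$val_accuracy), 1.0)
    # best-so-far validation accuracy is monotone over epochs
    expect_true(all(diff(cummax(fit$training_log$val_accuracy)) >= 0))
  }
})

test_that("training rejects mismatched or empty inputs", {
  imgs <- const_images(c(0.1, 0.9), 3)
  m <- build_model(tiny_config(), 8L)
  empty <- image_dataset(list(), integer(0), c("a", "b"), "gadf", 8L)
  expect_error(train_model(m, empty, imgs), "nonempty")
  wrong <- const_images(c(0.1, 0.9), 2, size = 16L)
  expect_error(train_model(m, wrong, imgs), "does not match")
  bad <- imgs
  bad$labels[1] <- 5L
  expect_error(train_model(m, bad, imgs), "outside")
})

numeric_grad_check <- function(arch, image_size) {
  cfg <- model_config(n_classes = 3, arch = arch, n_encoder_layers = 2,
                      n_decoder_layers = 2, hidden_size = 4, n_heads = 2,
                      dropout = 0, patch_size = 2, ff_mult = 2,
                      epochs = 1, seed = 5)
  m <- build_model(cfg, image_size)
  set.seed(14)
  imgs <- lapply(1:2, function(i) matrix(rnorm(image_size^2), image_size))
  labs <- c(1L, 3L)
  fb <- sig2image:::model_batch_fb(m, imgs, labs, train = FALSE)
  lossfn <- function(mm) {
    tot <- 0
    for (b in 1:2) {
      lg <- sig2image:::model_forward_sample(mm, imgs[[b]])$logits
      z <- lg - max(lg)
      p <- exp(z) / sum(exp(z))
      tot <- tot - log(p[labs[b]])
    }
    tot / 2
  }
  worst <- 0
  set.seed(15)
  for (nm in names(m$params)) {
    np <- length(m$params[[nm]])
    for (j in sample.int(np, min(2, np))) {
      h <- 1e-5
      mp <- m; mp$params[[nm]][j] <- mp$params[[nm]][j] + h
      mn <- m; mn$params[[nm]][j] <- mn$params[[nm]][j] - h
      num <- (lossfn(mp) - lossfn(mn)) / (2 * h)
      ana <- fb$grads[[nm]][j]
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  worst
}

test_that("analytic gradients match finite differences", {
  expect_lt(numeric_grad_check("transformer", 4L), 1e-3)
  expect_lt(numeric_grad_check("cnn", 16L), 1e-5)
})

test_that("transformer and cnn differ structurally but share contracts", {
  tr <- build_model(tiny_config("transformer"), 16L)
  cn <- build_model(tiny_config("cnn"), 16L)
  expect_false(count_parameters(tr) == count_parameters(cn))
  expect_true(all(c("out.W", "out.b") %in% names(tr$params)))
  expect_true(all(c("out.W", "out.b") %in% names(cn$params)))
})
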