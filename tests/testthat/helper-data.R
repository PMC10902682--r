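# Shared fixtures, independent oracles and the memoized scaled-down
# barcode experiment reused by several acceptance checks.

# Small ragged dataset with two classes, built in code.
make_toy_signals <- function(n_per_class = 6L, seed = 123L) {
  recs <- list()
  set.seed(seed)
  for (k in 1:2) {
    for (j in seq_len(n_per_class)) {
      n <- sample(20:60, 1)
      sig <- k / 2 + sin(seq_len(n) / 3) + rnorm(n, 0, 0.05)
      recs[[length(recs) + 1L]] <-
        raw_record(sprintf("c%d_%02d", k, j), sig, paste0("class", k))
    }
  }
  signal_dataset(recs)
}

# Brute-force PAA oracle: average the step function over each window on
# a regular grid whose cell count is a multiple of both n and l, so every
# sample and window boundary falls exactly on a cell edge and the
# discretized mean is exact up to float rounding.
paa_oracle <- function(signal, l, K = 3L) {
  n <- length(signal)
  N <- n * l * K
  ts <- (seq_len(N) - 0.5) * (n / N)          # cell midpoints in (0, n)
  vals <- signal[floor(ts) + 1L]
  win <- pmin(floor(ts / (n / l)) + 1L, l)
  as.numeric(tapply(vals, win, mean))
}

# Vectorized Gram-style GAF forms used as the independent oracle for the
# trigonometric implementations: for scaled x with sin(phi) = sqrt(1-x^2),
# GASF = x x' - s s'  and  GADF = s x' - x s'.
gaf_oracle <- function(x) {
  s <- sqrt(pmax(1 - x^2, 0))
  list(gasf = outer(x, x) - outer(s, s),
       gadf = outer(s, x) - outer(x, s))
}

# Closed-form pooled-variance two-sample t statistic.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Scaled-down barcode experiment shared by the end-to-end checks:
# 8 classes x (90 train + 10 val + 25 test), sigma = 0.05, GADF 32x32,
# 1 encoder + 1 decoder layer, hidden 32, 2 heads, patch 4, dropout 0.1,
# batch 32, 20 epochs.  Computed once per test run.
.acceptance_cache <- new.env(parent = emptyenv())

barcode_experiment <- function(seed = 11L) {
  key <- paste0("run", seed)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  spec <- synthetic_spec("barcode", n_per_class = 125L,
                         noise_sigma = 0.05, seed = seed)
  ds <- gen_barcode(spec)
  split <- split_dataset(ds, c(0.72, 0.08, 0.20), seed = seed)
  imgs <- lapply(split, transform_signals, strategy = "gadf", l = 32L)
  res <- list(classes = ds$classes, images = imgs)
  for (arch in c("transformer", "cnn")) {
    cfg <- model_config(n_classes = 8L, arch = arch,
                        n_encoder_layers = 1L, n_decoder_layers = 1L,
                        hidden_size = 32L, n_heads = 2L, dropout = 0.1,
                        patch_size = 4L, lr = 0.001, lr_decay = 0.97,
                        batch_size = 32L, epochs = 20L, seed = seed)
    model <- build_model(cfg, 32L, class_names = ds$classes)
    model <- train_model(model, imgs$train, imgs$val)
    pred <- predict(model, imgs$test)
    res[[arch]] <- list(
      model = model,
      report = evaluate_predictions(imgs$test$labels, pred$labels,
                                    pred$prob))
  }
  .acceptance_cache[[key]] <- res
  res
}
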