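# Evaluation and orchestration: metrics with micro-averaged ROC/PR,
# stratified cross-validation, the transformation-strategy comparison,
# the transformer-vs-CNN ablation, and the normality-then-t-test
# comparison of run vectors.

micro_curves <- function(true_labels, scores) {
  n <- length(true_labels)
  k <- ncol(scores)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), true_labels)] <- 1
  y <- as.vector(onehot)
  s <- as.vector(scores)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]; s <- s[ord]
  P <- sum(y); N <- length(y) - P
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied thresholds: keep the last point of each score value
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  prec <- c(1, tp / (tp + fp))
  rec <- c(0, tp / P)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr),
       pr = data.frame(recall = rec, precision = prec),
       auc = auc)
}

#' Evaluate predictions against true labels
#'
#' Accuracy, macro-averaged recall and F1 (classes absent from the truth
#' are excluded from the macro averages), the confusion matrix (rows =
#' true, columns = predicted), per-class accuracy, and micro-averaged
#' ROC/PR curve points obtained by pooling all one-vs-rest
#' (indicator, score) pairs.
#'
#' @param true_labels Integer class indices (1-based).
#' @param pred_labels Integer class indices, same length.
#' @param scores Optional n x n_classes probability matrix (rows on the
#'   simplex) for the ROC/PR curves.
#' @param n_classes Number of classes; defaults to `ncol(scores)` or the
#'   largest index seen.
#' @return An `eval_report` list: `accuracy`, `recall_macro`, `f1_macro`,
#'   `confusion`, `per_class_accuracy`, `roc_points`, `pr_points`,
#'   `roc_auc`.
#' @export
evaluate_predictions <- function(true_labels, pred_labels, scores = NULL,
                                 n_classes = NULL) {
  true_labels <- as.integer(true_labels)
  pred_labels <- as.integer(pred_labels)
  if (length(true_labels) != length(pred_labels))
    stop2("true and predicted label lengths differ")
  if (is.null(n_classes))
    n_classes <- if (!is.null(scores)) ncol(scores)
                 else max(true_labels, pred_labels)
  conf <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    conf[true_labels[i], pred_labels[i]] <-
      conf[true_labels[i], pred_labels[i]] + 1L
  present <- which(rowSums(conf) > 0)
  recall_c <- diag(conf)[present] / rowSums(conf)[present]
  prec_den <- colSums(conf)[present]
  prec_c <- ifelse(prec_den > 0, diag(conf)[present] / prec_den, 0)
  f1_c <- ifelse(prec_c + recall_c > 0,
                 2 * prec_c * recall_c / (prec_c + recall_c), 0)
  curves <- if (!is.null(scores)) micro_curves(true_labels, scores)
            else NULL
  structure(list(
    accuracy = if (length(true_labels)) mean(true_labels == pred_labels)
               else NA_real_,
    recall_macro = mean(recall_c),
    f1_macro = mean(f1_c),
    confusion = conf,
    per_class_accuracy = recall_c,
    roc_points = curves$roc, pr_points = curves$pr,
    roc_auc = curves$auc), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy=%.4f recall=%.4f f1=%.4f%s\n",
              x$accuracy, x$recall_macro, x$f1_macro,
              if (!is.null(x$roc_auc)) sprintf(" auc=%.4f", x$roc_auc)
              else ""))
  invisible(x)
}

#' A labeled vector of per-fold (or per-repeat) accuracies
#'
#' @param values Numeric vector of accuracies in `[0, 1]`, length >= 2.
#' @param label Name of the method that produced them.
#' @return A `run_vector`.
#' @export
run_vector <- function(values, label = "run") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop2("run vector needs at least 2 values")
  if (any(values < 0 | values > 1)) stop2("accuracies must lie in [0, 1]")
  structure(list(values = values, label = label), class = "run_vector")
}

#' Compare two run vectors: KS normality check, then two-sample t test
#'
#' Each vector is tested against a normal distribution with its own
#' sample mean and standard deviation (Kolmogorov-Smirnov); normality is
#' accepted at P > .05.  The vectors are then compared with a two-sided
#' pooled-variance two-sample t test; the difference is called
#' significant at P < .05.
#'
#' @param a,b [run_vector()]s (or bare numeric vectors), each with
#'   nonzero variance.
#' @return A `comparison_result` list: `ks_p_a`, `ks_p_b`, `normal_a`,
#'   `normal_b`, `t_stat`, `t_p`, `significant`, `mean_diff`
#'   (`mean(a) - mean(b)`).
#' @export
compare_runs <- function(a, b) {
  va <- if (inherits(a, "run_vector")) a$values else as.numeric(a)
  vb <- if (inherits(b, "run_vector")) b$values else as.numeric(b)
  if (length(va) < 2L || length(vb) < 2L)
    stop2("both run vectors need at least 2 values")
  if (sd(va) == 0 || sd(vb) == 0)
    stop2("degenerate run vector: zero variance")
  ks_a <- suppressWarnings(ks.test(va, "pnorm", mean(va), sd(va)))
  ks_b <- suppressWarnings(ks.test(vb, "pnorm", mean(vb), sd(vb)))
  tt <- t.test(va, vb, var.equal = TRUE)
  structure(list(ks_p_a = ks_a$p.value, ks_p_b = ks_b$p.value,
                 normal_a = ks_a$p.value > 0.05,
                 normal_b = ks_b$p.value > 0.05,
                 t_stat = unname(tt$statistic), t_p = tt$p.value,
                 significant = tt$p.value < 0.05,
                 mean_diff = mean(va) - mean(vb)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(paste0("<comparison_result> t=%.4f p=%.3g (%s); ",
                     "KS p: %.3f / %.3f; mean diff %.4f\n"),
              x$t_stat, x$t_p,
              if (x$significant) "significant" else "not significant",
              x$ks_p_a, x$ks_p_b, x$mean_diff))
  invisible(x)
}

# Stratified fold assignment: per class, seeded shuffle then round-robin.
make_folds <- function(labels, classes, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop2("class '", cl, "' has ", length(idx),
              " records, fewer than k = ", k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Per fold: transform the signals (the chosen strategy), carve a
#' stratified validation subset out of the training portion for epoch
#' selection, train, and evaluate on the held-out fold.  Deterministic
#' for a fixed seed.
#'
#' @param ds A [signal_dataset()]; every class needs at least `k`
#'   records.
#' @param config A [model_config()].
#' @param strategy Transform strategy (see [transform_record()]).
#' @param image_size Image side length.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param val_fraction Fraction of each fold's training portion held out
#'   for validation.
#' @param ... Extra arguments to [transform_signals()].
#' @return List with `accuracies` (a [run_vector()] of length `k`),
#'   `reports` (per-fold `eval_report`s) and `folds` (fold assignment).
#' @export
cross_validate <- function(ds, config, strategy = "gadf", image_size = 64L,
                           k = 10L, seed = 1L, val_fraction = 0.1, ...) {
  stopifnot(inherits(ds, "signal_dataset"))
  labels <- dataset_labels(ds)
  fold <- make_folds(labels, ds$classes, k, seed)
  imgs <- transform_signals(ds, strategy = strategy, l = image_size, ...)
  acc <- numeric(k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    val_idx <- integer(0)
    with_seed(seed + f, {
      for (cl in ds$classes) {
        cl_idx <- train_idx[labels[train_idx] == cl]
        n_val <- max(1L, round(val_fraction * length(cl_idx)))
        val_idx <- c(val_idx, cl_idx[sample.int(length(cl_idx), n_val)])
      }
    })
    fit_idx <- setdiff(train_idx, val_idx)
    subset_imgs <- function(ix) {
      image_dataset(imgs$images[ix], imgs$labels[ix], imgs$classes,
                    imgs$strategy, imgs$image_size)
    }
    model <- build_model(config, image_size, class_names = ds$classes)
    model <- train_model(model, subset_imgs(fit_idx), subset_imgs(val_idx))
    pred <- predict(model, subset_imgs(test_idx))
    reports[[f]] <- evaluate_predictions(imgs$labels[test_idx],
                                         pred$labels, pred$prob)
    acc[f] <- reports[[f]]$accuracy
  }
  list(accuracies = run_vector(acc, "cv"), reports = reports, folds = fold)
}

run_single_experiment <- function(imgs_train, imgs_val, imgs_test, config,
                                  class_names) {
  model <- build_model(config, imgs_train$image_size,
                       class_names = class_names)
  model <- train_model(model, imgs_train, imgs_val)
  pred <- predict(model, imgs_test)
  list(model = model,
       report = evaluate_predictions(imgs_test$labels, pred$labels,
                                     pred$prob))
}

#' Compare transformation strategies on one shared split
#'
#' All strategies share a single stratified train/val/test split and an
#' identical model configuration and seed, so only the transform varies.
#'
#' @param ds A [signal_dataset()].
#' @param config A [model_config()].
#' @param strategies Subset of `c("rp", "mtf", "gasf", "gadf")`.
#' @param image_size Image side length.
#' @param seed Split seed.
#' @param fractions Train/val/test split fractions.
#' @param ... Extra arguments to [transform_signals()].
#' @return List with `table` (one row per strategy: accuracy,
#'   recall_macro, f1_macro) and `reports` (named `eval_report`s).
#' @export
strategy_comparison <- function(ds, config,
                                strategies = c("rp", "mtf", "gasf", "gadf"),
                                image_size = 64L, seed = 1L,
                                fractions = c(0.7, 0.1, 0.2), ...) {
  strategies <- match.arg(strategies, c("rp", "mtf", "gasf", "gadf"),
                          several.ok = TRUE)
  split <- split_dataset(ds, fractions, seed)
  reports <- list()
  for (s in strategies) {
    tr <- transform_signals(split$train, strategy = s, l = image_size, ...)
    va <- transform_signals(split$val, strategy = s, l = image_size, ...)
    te <- transform_signals(split$test, strategy = s, l = image_size, ...)
    reports[[s]] <- run_single_experiment(tr, va, te, config,
                                          ds$classes)$report
  }
  tab <- data.frame(
    strategy = strategies,
    accuracy = vapply(reports, function(r) r$accuracy, numeric(1)),
    recall_macro = vapply(reports, function(r) r$recall_macro, numeric(1)),
    f1_macro = vapply(reports, function(r) r$f1_macro, numeric(1)),
    row.names = NULL)
  list(table = tab, reports = reports)
}

#' Transformer-vs-CNN ablation on identical data
#'
#' Same split, transform and seed; only the architecture flips.  The
#' output table mirrors the ablation layout: one row without the
#' transformer module (the 4-conv network) and one with it.
#'
#' @param ds A [signal_dataset()].
#' @param config A [model_config()] (its `arch` is overridden per row).
#' @param strategy Transform strategy shared by both rows.
#' @param image_size Image side length (divisible by 16 for the CNN).
#' @param seed Split seed.
#' @param fractions Train/val/test split fractions.
#' @param ... Extra arguments to [transform_signals()].
#' @return List with `table` (columns `transformer`, `accuracy`,
#'   `recall_macro`, `f1_macro`, `n_parameters`) and `reports`.
#' @export
run_ablation <- function(ds, config, strategy = "gadf", image_size = 64L,
                         seed = 1L, fractions = c(0.7, 0.1, 0.2), ...) {
  split <- split_dataset(ds, fractions, seed)
  tr <- transform_signals(split$train, strategy = strategy, l = image_size,
                          ...)
  va <- transform_signals(split$val, strategy = strategy, l = image_size,
                          ...)
  te <- transform_signals(split$test, strategy = strategy, l = image_size,
                          ...)
  out <- list()
  nparam <- integer(2)
  archs <- c("cnn", "transformer")
  for (i in seq_along(archs)) {
    cfg <- config
    cfg$arch <- archs[i]
    res <- run_single_experiment(tr, va, te, cfg, ds$classes)
    out[[archs[i]]] <- res$report
    nparam[i] <- count_parameters(res$model)
  }
  tab <- data.frame(
    transformer = c(FALSE, TRUE),
    accuracy = vapply(out, function(r) r$accuracy, numeric(1)),
    recall_macro = vapply(out, function(r) r$recall_macro, numeric(1)),
    f1_macro = vapply(out, function(r) r$f1_macro, numeric(1)),
    n_parameters = nparam,
    row.names = NULL)
  list(table = tab, reports = out)
}
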