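# Hand-crafted statistical features for classical baseline learners.

#' Statistical feature vector of a raw signal
#'
#' Length, mean, population standard deviation (divisor n), min, max,
#' median, skewness and excess kurtosis (standardized central moments; 0
#' for a normal distribution).  For a constant signal the standardized
#' moments are defined as 0 by convention.
#'
#' @param rec A [raw_record()] or bare numeric vector.
#' @return A one-row `data.frame` with columns `length`, `mean`, `std`,
#'   `min`, `max`, `median`, `skewness`, `kurtosis`.
#' @export
extract_features <- function(rec) {
  x <- if (inherits(rec, "raw_record")) rec$signal else as.numeric(rec)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  data.frame(length = n, mean = m, std = sqrt(m2),
             min = min(x), max = max(x), median = median(x),
             skewness = skew, kurtosis = kurt)
}

#' Feature matrix for a whole dataset
#'
#' @param ds A [signal_dataset()].
#' @return A `data.frame` of per-record features plus a `label` column,
#'   ready for off-the-shelf classical learners.
#' @export
extract_features_dataset <- function(ds) {
  stopifnot(inherits(ds, "signal_dataset"))
  feats <- do.call(rbind, lapply(ds$records, extract_features))
  feats$label <- factor(dataset_labels(ds), levels = ds$classes)
  feats
}
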