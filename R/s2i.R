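# Sequence-to-image transforms: PAA length reduction, min-max scaling,
# polar encoding, and the four imaging strategies (GASF, GADF, MTF, RP).

#' Piecewise aggregate approximation
#'
#' Reduces (or stretches) a series to length `l` by averaging the
#' underlying step function over `l` equal-width windows with fractional
#' overlap weighting: `output[k]` is the mean of the signal over the
#' continuous interval `[(k-1)*n/l, k*n/l)`.  Exact, deterministic, and
#' uniform for `l > n` (samples are repeated/split proportionally);
#' `l == n` returns the input unchanged.
#'
#' @param signal Numeric vector, length n >= 1.
#' @param l Target length, integer >= 1.
#' @return Numeric vector of length `l`.
#' @export
paa_reduce <- function(signal, l) {
  n <- length(signal)
  if (n < 1L) stop2("empty signal")
  if (!is_count(l) || l < 1) stop2("`l` must be a positive integer")
  l <- as.integer(l)
  if (l == n) return(as.numeric(signal))
  out <- numeric(l)
  w <- n / l
  for (k in seq_len(l)) {
    a <- (k - 1) * w
    b <- k * w
    i0 <- floor(a)
    i1 <- min(ceiling(b), n)
    idx <- seq.int(i0, i1 - 1L)           # 0-based sample indices
    ov <- pmin(idx + 1, b) - pmax(idx, a) # overlap of [idx, idx+1) with [a,b)
    out[k] <- sum(signal[idx + 1L] * ov) / w
  }
  out
}

#' Min-max scaling to a fixed range
#'
#' `unit` maps to `[0, 1]` via `(x - min)/(max - min)`; `sym` maps to
#' `[-1, 1]` via `(2x - max - min)/(max - min)`.  The minimum maps to the
#' lower bound and the maximum to the upper bound exactly.
#'
#' @param signal Numeric vector, non-constant.
#' @param range `"unit"` (default) or `"sym"`.
#' @return A `normalized_series`: list with `values` and `range`.
#' @export
minmax_normalize <- function(signal, range = c("unit", "sym")) {
  range <- match.arg(range)
  signal <- as.numeric(signal)
  if (length(signal) < 2L) stop2("signal must have at least 2 samples")
  lo <- min(signal); hi <- max(signal)
  if (hi == lo) stop2("degenerate signal: max equals min")
  values <- if (range == "unit") (signal - lo) / (hi - lo)
            else (2 * signal - hi - lo) / (hi - lo)
  structure(list(values = values, range = range),
            class = "normalized_series")
}

#' Polar encoding of a normalized series
#'
#' Angles are the arccosine of the scaled values (applied directly on
#' either range; unit scaling yields angles in `[0, pi/2]`, symmetric
#' scaling in `[0, pi]`); radii are the time indices `i/l`.  Values
#' within 1e-12 of the `[-1, 1]` endpoints are clipped; anything further
#' outside is an error.
#'
#' @param ns A `normalized_series` from [minmax_normalize()].
#' @return A `polar_series`: list with `angles` (radians), `radii`, and
#'   the originating `range`.
#' @export
to_polar <- function(ns) {
  if (!inherits(ns, "normalized_series"))
    stop2("`ns` must be a normalized_series")
  v <- ns$values
  tol <- 1e-12
  if (any(v > 1 + tol) || any(v < -1 - tol))
    stop2("normalized values outside [-1, 1] beyond tolerance")
  v <- pmin(pmax(v, -1), 1)
  l <- length(v)
  structure(list(angles = acos(v), radii = seq_len(l) / l,
                 range = ns$range),
            class = "polar_series")
}

gaf_image <- function(matrix, strategy, size = nrow(matrix)) {
  structure(list(matrix = matrix, strategy = strategy, size = size),
            class = "gaf_image")
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("<gaf_image> %dx%d strategy=%s\n", x$size, x$size, x$strategy))
  invisible(x)
}

#' Gramian angular summation field
#'
#' `matrix[i, j] = cos(phi_i + phi_j)`, equivalently the Gram-style form
#' `x xT - sqrt(1 - x^2) sqrt(1 - x^2)T` with elementwise squares.
#' Symmetric with entries in `[-1, 1]`; the diagonal is `2 x_i^2 - 1`, so
#' under unit scaling the series is recoverable (see
#' [invert_gasf_diagonal()]).
#'
#' @param ps A `polar_series` from [to_polar()].
#' @return A `gaf_image` with strategy `"gasf"`.
#' @export
gasf <- function(ps) {
  if (!inherits(ps, "polar_series")) stop2("`ps` must be a polar_series")
  m <- cos(outer(ps$angles, ps$angles, "+"))
  gaf_image(m, "gasf")
}

#' Gramian angular difference field
#'
#' `matrix[i, j] = sin(phi_i - phi_j)`: antisymmetric with zero diagonal
#' and entries in `[-1, 1]`.
#'
#' @param ps A `polar_series` from [to_polar()].
#' @return A `gaf_image` with strategy `"gadf"`.
#' @export
gadf <- function(ps) {
  if (!inherits(ps, "polar_series")) stop2("`ps` must be a polar_series")
  m <- sin(outer(ps$angles, ps$angles, "-"))
  gaf_image(m, "gadf")
}

#' Recover a unit-scaled series from a GASF diagonal
#'
#' The GASF diagonal is `2 x_i^2 - 1`; `(diag + 1)/2` therefore yields the
#' squared scaled value, and the square root is the series itself —
#' unambiguously only when the series lies in `[0, 1]` (unit scaling).
#' Symmetric `[-1, 1]` scaling loses the sign and is refused.
#'
#' @param img A `gaf_image` with strategy `"gasf"`.
#' @param range Scaling range of the originating series; must be `"unit"`.
#' @return Numeric vector: the recovered scaled series.
#' @export
invert_gasf_diagonal <- function(img, range = c("unit", "sym")) {
  range <- match.arg(range)
  if (!inherits(img, "gaf_image") || img$strategy != "gasf")
    stop2("`img` must be a GASF gaf_image")
  if (range == "sym")
    stop2("sign-ambiguous inversion: symmetric scaling cannot be inverted")
  d <- diag(img$matrix)
  if (any(d < -1 - 1e-12))
    stop2("diagonal entry below -1 beyond tolerance")
  sqrt(pmax((d + 1) / 2, 0))
}

# Quantile bin assignment with ties broken by sample order: equal-count
# bins over the rank ordering, the standard choice when many samples tie.
mtf_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  b <- ceiling(r * n_bins / length(x))
  pmin(pmax(b, 1L), n_bins)
}

#' Markov transition field
#'
#' Samples are assigned to `n_bins` quantile bins (ties broken by sample
#' order); a first-order transition matrix `W` is estimated with rows
#' normalized by outflow (rows with no outflow stay all-zero — no invented
#' probability mass); the image is `matrix[i, j] = W[bin(i), bin(j)]`.
#'
#' @param signal Numeric vector, length >= 2, non-constant.
#' @param n_bins Number of quantile bins, `2 <= n_bins <= length(signal)`.
#' @return A `gaf_image` with strategy `"mtf"`; the fitted `W` is attached
#'   as attribute `"W"`.
#' @export
mtf <- function(signal, n_bins = 8L) {
  signal <- as.numeric(signal)
  l <- length(signal)
  if (l < 2L) stop2("signal must have at least 2 samples")
  if (!is_count(n_bins) || n_bins < 2 || n_bins > l)
    stop2("`n_bins` must be an integer in [2, length(signal)]")
  if (max(signal) == min(signal))
    stop2("constant signal: quantile bins degenerate")
  n_bins <- as.integer(n_bins)
  b <- mtf_bins(signal, n_bins)
  counts <- matrix(0, n_bins, n_bins)
  from <- b[-l]; to <- b[-1]
  for (i in seq_along(from))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  outflow <- rowSums(counts)
  W <- counts
  nz <- outflow > 0
  W[nz, ] <- counts[nz, , drop = FALSE] / outflow[nz]
  m <- W[b, b, drop = FALSE]
  dimnames(m) <- NULL
  img <- gaf_image(m, "mtf")
  attr(img, "W") <- W
  img
}

#' Recurrence plot
#'
#' Binary image marking pairs of time points whose values lie within
#' `epsilon` of each other: `matrix[i, j] = 1` iff
#' `|signal[i] - signal[j]| <= epsilon`.  Scalar recurrence without
#' time-delay embedding; symmetric with unit diagonal.
#'
#' @param signal Numeric vector, length >= 2.
#' @param epsilon Recurrence threshold, >= 0.
#' @return A `gaf_image` with strategy `"rp"` (entries 0/1).
#' @export
recurrence_plot <- function(signal, epsilon = 0.1) {
  signal <- as.numeric(signal)
  if (length(signal) < 2L) stop2("signal must have at least 2 samples")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
    stop2("`epsilon` must be a single non-negative number")
  m <- (abs(outer(signal, signal, "-")) <= epsilon) * 1
  gaf_image(m, "rp")
}

#' Transform one record into a fixed-size image
#'
#' The full sequence-to-image chain: PAA reduction to length `l`, min-max
#' scaling, then either polar encoding followed by GASF/GADF, or MTF/RP
#' applied to the scaled series.  PAA precedes scaling (scaling first
#' would change the window means).
#'
#' @param rec A [raw_record()] (or bare numeric vector).
#' @param strategy `"gadf"` (default), `"gasf"`, `"mtf"`, or `"rp"`.
#' @param l Image side length (default 64).
#' @param range Scaling range passed to [minmax_normalize()].
#' @param mtf_bins Bin count for the MTF strategy.
#' @param rp_epsilon Threshold for the RP strategy.
#' @return A `gaf_image` of size `l` by `l`.
#' @export
transform_record <- function(rec, strategy = c("gadf", "gasf", "mtf", "rp"),
                             l = 64L, range = c("unit", "sym"),
                             mtf_bins = 8L, rp_epsilon = 0.1) {
  strategy <- match.arg(strategy)
  range <- match.arg(range)
  signal <- if (inherits(rec, "raw_record")) rec$signal else as.numeric(rec)
  reduced <- paa_reduce(signal, l)
  ns <- minmax_normalize(reduced, range)
  switch(strategy,
    gasf = gasf(to_polar(ns)),
    gadf = gadf(to_polar(ns)),
    mtf  = mtf(ns$values, n_bins = min(mtf_bins, l)),
    rp   = recurrence_plot(ns$values, epsilon = rp_epsilon))
}

#' Transform a whole signal dataset into an image dataset
#'
#' @param ds A [signal_dataset()].
#' @inheritParams transform_record
#' @return An [image_dataset()] with the dataset's class indices.
#' @export
transform_signals <- function(ds, strategy = c("gadf", "gasf", "mtf", "rp"),
                              l = 64L, range = c("unit", "sym"),
                              mtf_bins = 8L, rp_epsilon = 0.1) {
  stopifnot(inherits(ds, "signal_dataset"))
  strategy <- match.arg(strategy)
  range <- match.arg(range)
  images <- lapply(ds$records, function(r) {
    transform_record(r, strategy, l, range, mtf_bins, rp_epsilon)$matrix
  })
  labels <- match(dataset_labels(ds), ds$classes)
  image_dataset(images, labels, ds$classes, strategy, l)
}
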