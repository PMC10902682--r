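# Synthetic nanopore-like signal generators: amplitude/morphology analyte
# classes and 3-bit peak-train barcodes, plus the peak-counting oracle
# used to certify that the barcode task is learnable.

# Template parameters for analyte class k (k = 1..16): baseline level,
# blockade (dwell) depth and dwell fraction.  Spacing chosen so class
# means stay strictly ordered and classes are near-perfectly separable at
# noise_sigma <= 0.05 for records of a few hundred samples.
analyte_template <- function(k) {
  list(baseline = 0.20 + 0.06 * (k - 1),
       depth    = 0.30 + 0.02 * ((k - 1) %% 8),
       dwell    = if (k <= 8) 0.30 else 0.40)
}

# Barcode geometry: peak centers as fractions of the record length.
BARCODE_FRACS <- c(start = 0.08, bit1 = 0.30, bit2 = 0.50, bit3 = 0.70,
                   end = 0.92)
BARCODE_PEAK_WIDTH <- 25L   # samples
BARCODE_JITTER <- 0.05      # +/- fraction of record length per peak

#' Specification of a synthetic signal task
#'
#' @param task `"analyte"` (amplitude/morphology classes) or `"barcode"`
#'   (3-bit peak trains, fixed 8 classes `"000"`..`"111"`).
#' @param n_classes Number of classes (analyte task; 2..16). Forced to 8
#'   for the barcode task.
#' @param n_per_class Records generated per class.
#' @param length_range Integer `(min_n, max_n)` of raw record lengths;
#'   `min_n >= 16`.
#' @param noise_sigma Standard deviation of the additive Gaussian noise.
#' @param pad_to Fixed output length for the barcode task: shorter records
#'   are right-padded with `N(0, 0.072)` noise (the average noise level of
#'   ONT barcode traces). `NULL` disables padding. Default 700 for
#'   barcodes.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(task = c("analyte", "barcode"),
                           n_classes = 4L, n_per_class = 100L,
                           length_range = c(200L, 2000L),
                           noise_sigma = 0.03,
                           pad_to = if (task[1] == "barcode") 700L else NULL,
                           seed = 1L) {
  task <- match.arg(task)
  if (task == "barcode") {
    n_classes <- 8L
    if (missing(length_range)) length_range <- c(400L, 650L)
  }
  if (!is_count(n_classes) || n_classes < 2)
    stop2("`n_classes` must be an integer >= 2")
  if (task == "analyte" && n_classes > 16)
    stop2("analyte task supports at most 16 template classes")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 16L ||
      length_range[2] < length_range[1])
    stop2("`length_range` must be (min_n, max_n) with min_n >= 16")
  if (!is.numeric(noise_sigma) || noise_sigma < 0)
    stop2("`noise_sigma` must be >= 0")
  if (!is.null(pad_to) && (!is_count(pad_to) || pad_to < length_range[2]))
    stop2("`pad_to` must be >= the maximum generated length")
  structure(list(task = task, n_classes = as.integer(n_classes),
                 n_per_class = as.integer(n_per_class),
                 length_range = length_range,
                 noise_sigma = noise_sigma,
                 pad_to = if (is.null(pad_to)) NULL else as.integer(pad_to),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Raised half-cosine (Hann-shaped) pulse of the given width: smooth,
# bandwidth-limited like real blockade events.
half_cosine_peak <- function(width) {
  t <- seq_len(width)
  0.5 * (1 - cos(2 * pi * t / (width + 1)))
}

#' Generate analyte-morphology signals
#'
#' Class `k` records are a flat baseline `b_k` with a square blockade
#' dwell of class-specific depth `d_k` over a fixed fraction of the
#' record (position jittered), plus `N(0, noise_sigma)` noise.  Lengths
#' are uniform over `length_range`, emulating the wide length variation of
#' raw analyte events at desk scale.  Baselines are strictly increasing in
#' `k`, so per-class mean levels are ordered.
#'
#' @param spec A [synthetic_spec()] with `task = "analyte"`.
#' @return A [signal_dataset()] with classes `"class01"`, `"class02"`, ...
#' @export
gen_analyte <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "analyte") stop2("spec task is not 'analyte'")
  classes <- sprintf("class%02d", seq_len(spec$n_classes))
  recs <- with_seed(spec$seed, {
    out <- vector("list", spec$n_classes * spec$n_per_class)
    i <- 0L
    for (k in seq_len(spec$n_classes)) {
      tpl <- analyte_template(k)
      for (j in seq_len(spec$n_per_class)) {
        n <- sample.int(spec$length_range[2] - spec$length_range[1] + 1L,
                        1L) + spec$length_range[1] - 1L
        sig <- rep(tpl$baseline, n)
        n_dwell <- max(1L, round(tpl$dwell * n))
        start_max <- n - n_dwell + 1L
        start <- 1L + floor(runif(1, 0.2, 0.6) * (start_max - 1L))
        sig[start:(start + n_dwell - 1L)] <- tpl$baseline - tpl$depth
        if (spec$noise_sigma > 0)
          sig <- sig + rnorm(n, 0, spec$noise_sigma)
        i <- i + 1L
        out[[i]] <- raw_record(sprintf("%s_r%04d", classes[k], j),
                               sig, classes[k])
      }
    }
    out
  })
  signal_dataset(recs, classes)
}

#' Generate 3-bit peak-train barcode signals
#'
#' Each record is a flat zero baseline carrying unit-amplitude raised
#' half-cosine peaks: a start peak, three bit slots (peak present iff the
#' bit is 1), and an end peak, at fixed fractional positions with +/-5%
#' jitter, plus `N(0, noise_sigma)` noise.  If `pad_to` is set, records
#' are right-padded to that length with `N(0, 0.072)` noise.
#'
#' @param spec A [synthetic_spec()] with `task = "barcode"`.
#' @return A [signal_dataset()] with classes `"000"`..`"111"`.
#' @export
gen_barcode <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "barcode") stop2("spec task is not 'barcode'")
  codes <- c("000", "001", "010", "011", "100", "101", "110", "111")
  peak <- half_cosine_peak(BARCODE_PEAK_WIDTH)
  recs <- with_seed(spec$seed, {
    out <- vector("list", 8L * spec$n_per_class)
    i <- 0L
    for (k in seq_len(8L)) {
      bits <- as.integer(strsplit(codes[k], "")[[1]])
      present <- c(TRUE, bits == 1L, TRUE)  # start, 3 bits, end
      for (j in seq_len(spec$n_per_class)) {
        n <- sample.int(spec$length_range[2] - spec$length_range[1] + 1L,
                        1L) + spec$length_range[1] - 1L
        sig <- numeric(n)
        jit <- runif(5, -BARCODE_JITTER, BARCODE_JITTER)
        centers <- round((BARCODE_FRACS + jit) * n)
        for (p in seq_len(5)) {
          if (!present[p]) next
          lo <- centers[p] - BARCODE_PEAK_WIDTH %/% 2L
          span <- lo:(lo + BARCODE_PEAK_WIDTH - 1L)
          keep <- span >= 1L & span <= n
          sig[span[keep]] <- sig[span[keep]] + peak[keep]
        }
        if (spec$noise_sigma > 0)
          sig <- sig + rnorm(n, 0, spec$noise_sigma)
        if (!is.null(spec$pad_to) && n < spec$pad_to)
          sig <- c(sig, rnorm(spec$pad_to - n, 0, 0.072))
        i <- i + 1L
        out[[i]] <- raw_record(sprintf("bc%s_r%04d", codes[k], j),
                               sig, codes[k])
      }
    }
    out
  })
  signal_dataset(recs, codes)
}

#' Fixed length-10 worked-example record
#'
#' A short blockade-like trace used throughout the documentation and tests
#' to illustrate the full sequence-to-image chain (PAA, scaling, polar
#' encoding, GASF/GADF).
#'
#' @return A [raw_record()] of length 10.
#' @export
gen_worked_example <- function() {
  raw_record("worked_example",
             c(4.2, 4.8, 5.5, 5.1, 4.0, 3.2, 3.8, 4.6, 5.0, 4.4),
             "demo")
}

#' Classify a barcode signal by counting peak excursions
#'
#' Model-free oracle for the barcode task: excursions are maximal runs of
#' at least `min_run` consecutive samples above `threshold`; the first and
#' last excursions anchor the start/end peaks and interior excursion
#' centers are snapped to the nearest of the three bit slots.  Certifies
#' that the synthetic task is solvable before any learned model is
#' blamed.
#'
#' @param signal Numeric vector (one barcode record).
#' @param threshold Excursion threshold; the conventional choice is
#'   baseline + 3 * noise_sigma.
#' @param min_run Minimum run length counting as a peak (rejects isolated
#'   noise exceedances in the padding).
#' @return The decoded 3-bit code string, or `NA_character_` if fewer than
#'   two excursions are found.
#' @export
classify_barcode_peaks <- function(signal, threshold, min_run = 8L) {
  above <- signal > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (sum(keep) < 2L) return(NA_character_)
  centers <- (starts[keep] + ends[keep]) / 2
  s <- centers[1]; e <- centers[length(centers)]
  interior <- centers[-c(1, length(centers))]
  # expected bit-slot positions relative to the start/end anchors
  slot_rel <- (BARCODE_FRACS[2:4] - BARCODE_FRACS[1]) /
    (BARCODE_FRACS[5] - BARCODE_FRACS[1])
  bits <- rep(0L, 3L)
  for (c0 in interior) {
    rel <- (c0 - s) / (e - s)
    bits[which.min(abs(slot_rel - rel))] <- 1L
  }
  paste(bits, collapse = "")
}

#' Peak-counting oracle accuracy over a barcode dataset
#'
#' @param ds A [signal_dataset()] from [gen_barcode()].
#' @param noise_sigma The generator's noise level (sets the threshold at
#'   `3 * noise_sigma` over the zero baseline).
#' @param min_run Passed to [classify_barcode_peaks()].
#' @return Fraction of records decoded to their true code.
#' @export
peak_oracle_accuracy <- function(ds, noise_sigma, min_run = 8L) {
  stopifnot(inherits(ds, "signal_dataset"))
  pred <- vapply(ds$records, function(r) {
    classify_barcode_peaks(r$signal, threshold = 3 * noise_sigma,
                           min_run = min_run)
  }, character(1))
  mean(pred == dataset_labels(ds), na.rm = FALSE)
}
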