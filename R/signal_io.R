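# Containers and I/O for ragged labeled signal collections and for the
# image datasets the transforms produce.

#' One labeled variable-length current signal
#'
#' A single nanopore event: an id, a numeric trace of at least two finite
#' samples (normalized blockade current, dimensionless), and a class label.
#'
#' @param id Character scalar record identifier.
#' @param signal Numeric vector, length >= 2, all finite.
#' @param label Character scalar class name.
#' @return An object of class `raw_record`.
#' @export
raw_record <- function(id, signal, label) {
  if (!is.character(id) || length(id) != 1L || is.na(id))
    stop2("`id` must be a single character string")
  signal <- as.numeric(signal)
  if (length(signal) < 2L)
    stop2("signal must contain at least 2 samples (got ", length(signal), ")")
  if (!all(is.finite(signal)))
    stop2("signal contains non-finite samples")
  label <- as.character(label)
  if (length(label) != 1L || is.na(label))
    stop2("`label` must be a single character string")
  structure(list(id = id, signal = signal, label = label),
            class = "raw_record")
}

#' @export
print.raw_record <- function(x, ...) {
  cat(sprintf("<raw_record> id=%s label=%s n=%d\n",
              x$id, x$label, length(x$signal)))
  invisible(x)
}

#' An ordered collection of labeled signals
#'
#' Holds records in insertion order together with the unique class list,
#' built from first-appearance order of the labels (no hidden sorting).
#'
#' @param records List of [raw_record()] objects.
#' @param classes Optional character vector of class names; defaults to the
#'   labels in first-appearance order. Must contain every record label and
#'   no duplicates.
#' @return An object of class `signal_dataset`.
#' @export
signal_dataset <- function(records = list(), classes = NULL) {
  if (!all(vapply(records, inherits, logical(1), "raw_record")))
    stop2("all elements of `records` must be raw_record objects")
  labels <- vapply(records, function(r) r$label, character(1))
  if (is.null(classes)) classes <- unique(labels)
  classes <- as.character(classes)
  if (anyDuplicated(classes))
    stop2("`classes` contains duplicates")
  if (length(records) && !all(labels %in% classes))
    stop2("record labels outside the class list: ",
          paste(setdiff(labels, classes), collapse = ", "))
  structure(list(records = records, classes = classes),
            class = "signal_dataset")
}

#' @export
length.signal_dataset <- function(x) length(x$records)

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d records, %d classes\n",
              length(x$records), length(x$classes)))
  if (length(x$records)) {
    tab <- table(factor(dataset_labels(x), levels = x$classes))
    for (cl in x$classes)
      cat(sprintf("  %-12s %d\n", cl, tab[[cl]]))
  }
  invisible(x)
}

#' Record labels of a signal dataset
#' @param ds A `signal_dataset`.
#' @return Character vector of per-record labels.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$records, function(r) r$label, character(1))
}

#' Read labeled signals from disk
#'
#' The delimited dialect is one record per line,
#' `id<TAB>label<TAB>v1,v2,...,vn` — ragged rows, so rectangular CSV
#' readers do not apply.  The `rds` format is the package's binary
#' container (lossless round trip of [write_signals()]).
#'
#' @param path File path.
#' @param format `"delimited"` (TSV, default) or `"rds"`.
#' @return A [signal_dataset()] preserving file order; classes in
#'   first-appearance order.
#' @export
read_signals <- function(path, format = c("delimited", "rds")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file does not exist: ", path)
  if (format == "rds") {
    obj <- readRDS(path)
    recs <- lapply(obj$records, function(r) raw_record(r$id, r$signal, r$label))
    return(signal_dataset(recs, obj$classes))
  }
  lines <- readLines(path)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(lines[[i]])) next
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop2("line ", i, ": expected 3 tab-separated fields, got ",
            length(parts))
    vals <- strsplit(parts[[3]], ",", fixed = TRUE)[[1]]
    sig <- suppressWarnings(as.numeric(vals))
    if (anyNA(sig))
      stop2("line ", i, ": non-numeric sample value '",
            vals[which(is.na(sig))[1]], "'")
    if (length(sig) < 2L)
      stop2("line ", i, ": signal has fewer than 2 samples")
    if (!all(is.finite(sig)))
      stop2("line ", i, ": non-finite sample value")
    recs[[i]] <- raw_record(parts[[1]], sig, parts[[2]])
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  signal_dataset(recs)
}

#' Write labeled signals to disk
#'
#' @param ds A [signal_dataset()].
#' @param path Output path.
#' @param format `"delimited"` (TSV dialect of [read_signals()]) or `"rds"`.
#' @param digits Significant digits for the delimited format (default 17,
#'   enough to round-trip doubles).
#' @return `path`, invisibly.
#' @export
write_signals <- function(ds, path, format = c("delimited", "rds"),
                          digits = 17L) {
  stopifnot(inherits(ds, "signal_dataset"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(records = lapply(ds$records, unclass), classes = ds$classes),
            path, version = 3)
    return(invisible(path))
  }
  lines <- vapply(ds$records, function(r) {
    paste(r$id, r$label,
          paste(formatC(r$signal, digits = digits, format = "g"),
                collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' A fixed-size image dataset
#'
#' The output container of the sequence-to-image transforms: a list of
#' l-by-l numeric matrices, 1-based integer class indices, the class
#' names, and the transform strategy tag.
#'
#' @param images List of numeric l-by-l matrices.
#' @param labels Integer vector of class indices in `[1, length(classes)]`.
#' @param classes Character vector of class names.
#' @param strategy One of `"gasf"`, `"gadf"`, `"mtf"`, `"rp"`.
#' @param image_size Side length l.
#' @return An object of class `image_dataset`.
#' @export
image_dataset <- function(images, labels, classes, strategy, image_size) {
  strategy <- match.arg(strategy, c("gasf", "gadf", "mtf", "rp"))
  if (length(images) != length(labels))
    stop2("images and labels lengths differ (",
          length(images), " vs ", length(labels), ")")
  labels <- as.integer(labels)
  if (length(labels) && (any(labels < 1L) || any(labels > length(classes))))
    stop2("labels must lie in [1, ", length(classes), "]")
  image_size <- as.integer(image_size)
  ok <- vapply(images, function(m) {
    is.matrix(m) && all(dim(m) == image_size) && is.numeric(m)
  }, logical(1))
  if (length(ok) && !all(ok))
    stop2("image ", which(!ok)[1], " is not a numeric ",
          image_size, "x", image_size, " matrix")
  structure(list(images = images, labels = labels,
                 classes = as.character(classes),
                 strategy = strategy, image_size = image_size),
            class = "image_dataset")
}

#' @export
length.image_dataset <- function(x) length(x$images)

#' @export
print.image_dataset <- function(x, ...) {
  cat(sprintf("<image_dataset> %d images, %dx%d, strategy=%s, %d classes\n",
              length(x$images), x$image_size, x$image_size, x$strategy,
              length(x$classes)))
  invisible(x)
}

#' Write an image dataset to the package's binary container
#'
#' Round-trip guarantee: [read_images()] on the written file reproduces
#' matrices bit-exactly, plus labels, class names, strategy and size.
#'
#' @param ds An [image_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_images <- function(ds, path) {
  if (!inherits(ds, "image_dataset"))
    stop2("`ds` must be an image_dataset")
  # re-validate so corrupt hand-built lists are refused
  ds <- image_dataset(ds$images, ds$labels, ds$classes, ds$strategy,
                      ds$image_size)
  saveRDS(unclass(ds), path, version = 3)
  invisible(path)
}

#' Read an image dataset written by [write_images()]
#' @param path File path.
#' @return An [image_dataset()].
#' @export
read_images <- function(path) {
  if (!file.exists(path)) stop2("file does not exist: ", path)
  obj <- readRDS(path)
  image_dataset(obj$images, obj$labels, obj$classes, obj$strategy,
                obj$image_size)
}

#' Export an image as 8-bit grayscale PNG (inspection only)
#'
#' Values are min-max mapped to `[0, 1]` gray; the mapping is lossy and the
#' PNG is never read back by the package.
#'
#' @param image Numeric matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop2("the 'png' package is required for PNG export")
  rng <- range(image)
  g <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
       else array(0.5, dim(image))
  png::writePNG(g, path)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Splits per class with deterministic seeded shuffling; the three outputs
#' partition the input (no loss, no duplication) and every part receives at
#' least one record of every class.
#'
#' @param ds A [signal_dataset()].
#' @param fractions Numeric length-3 vector (train, validation, test);
#'   positive, summing to 1 within 1e-9.
#' @param seed Integer seed.
#' @return Named list of three `signal_dataset`s: `train`, `val`, `test`.
#' @export
split_dataset <- function(ds, fractions, seed) {
  stopifnot(inherits(ds, "signal_dataset"))
  if (length(fractions) != 3L || any(fractions <= 0))
    stop2("`fractions` must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop2("`fractions` must sum to 1")
  labels <- dataset_labels(ds)
  parts <- vector("list", 3L)
  for (p in 1:3) parts[[p]] <- integer(0)
  with_seed(seed, {
    for (cl in ds$classes) {
      idx <- which(labels == cl)
      if (length(idx) < 3L)
        stop2("class '", cl, "' has ", length(idx),
              " records, fewer than the 3 split parts")
      idx <- idx[sample.int(length(idx))]
      counts <- allocate_counts(length(idx), fractions)
      bounds <- cumsum(counts)
      parts[[1]] <- c(parts[[1]], idx[seq_len(counts[1])])
      parts[[2]] <- c(parts[[2]], idx[(bounds[1] + 1):bounds[2]])
      parts[[3]] <- c(parts[[3]], idx[(bounds[2] + 1):bounds[3]])
    }
  })
  out <- lapply(parts, function(ix) {
    signal_dataset(ds$records[sort(ix)], ds$classes)
  })
  names(out) <- c("train", "val", "test")
  out
}
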