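# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

# Deterministic integer allocation of n items to parts with the given
# fractions: floor shares, remainders to the largest fractional parts
# (ties to the earlier part), then steal from the largest part so that
# every part receives at least one item (callers guarantee n >= parts).
allocate_counts <- function(n, fractions) {
  k <- length(fractions)
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  while (any(counts == 0L)) {
    counts[which.max(counts)] <- counts[which.max(counts)] - 1L
    counts[which(counts == 0L)[1L]] <- 1L
  }
  as.integer(counts)
}
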