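test_that("paa_reduce matches exact and brute-force window means", {
  expect_equal(paa_reduce(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(paa_reduce(rep(7, 5), 3), c(7, 7, 7))
  # non-divisible windows: fractional-overlap means over [0,2.5) and [2.5,5)
  expect_equal(paa_reduce(c(1, 2, 3, 4, 5), 2), c(1.8, 4.2))
  expect_identical(paa_reduce(c(2, 4, 6), 3), c(2, 4, 6))  # l == n
  expect_equal(paa_reduce(c(1, 2), 4), c(1, 1, 2, 2))      # l > n repeats
  expect_error(paa_reduce(1:4, 0), "positive")
})

test_that("paa_reduce agrees with fine-grid integration on random series", {
  set.seed(21)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    l <- sample(2:50, 1)
    x <- rnorm(n)
    expect_equal(paa_reduce(x, l), paa_oracle(x, l), tolerance = 1e-9)
  }
})

test_that("min-max scaling pins endpoints for both ranges", {
  expect_equal(minmax_normalize(c(0, 5, 10), "unit")$values, c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0, 5, 10), "sym")$values, c(-1, 0, 1))
  expect_error(minmax_normalize(c(3, 3, 3), "unit"), "degenerate")
})

test_that("polar encoding maps known values and clips float drift", {
  ps <- to_polar(minmax_normalize(c(-1, 0, 1), "sym"))
  expect_equal(ps$angles, c(pi, pi / 2, 0))
  ps <- to_polar(minmax_normalize(c(0, 0.5, 1), "unit"))
  expect_equal(ps$angles, c(pi / 2, pi / 3, 0))
  expect_equal(ps$radii, c(1, 2, 3) / 3)

  drifted <- structure(list(values = c(0, 1 + 1e-15), range = "unit"),
                       class = "normalized_series")
  expect_equal(to_polar(drifted)$angles[2], 0)
  bad <- structure(list(values = c(0, 1.01), range = "unit"),
                   class = "normalized_series")
  expect_error(to_polar(bad), "outside")
})

test_that("gasf and gadf reproduce hand-evaluated trigonometric matrices", {
  ps <- to_polar(minmax_normalize(c(0, 0.5, 1), "unit"))  # pi/2, pi/3, 0
  G <- gasf(ps)$matrix
  expect_equal(G, rbind(c(-1, -sqrt(3) / 2, 0),
                        c(-sqrt(3) / 2, -1 / 2, 1 / 2),
                        c(0, 1 / 2, 1)))
  D <- gadf(ps)$matrix
  expect_equal(D, rbind(c(0, 1 / 2, 1),
                        c(-1 / 2, 0, sqrt(3) / 2),
                        c(-1, -sqrt(3) / 2, 0)))
  # constant angles give the degenerate fields
  cps <- structure(list(angles = rep(0, 3), radii = (1:3) / 3,
                        range = "unit"), class = "polar_series")
  expect_equal(gasf(cps)$matrix, matrix(1, 3, 3))
  expect_equal(gadf(cps)$matrix, matrix(0, 3, 3))
})

test_that("trig fields equal the vectorized Gram forms on random series", {
  set.seed(42)
  worst <- 0
  for (i in 1:30) {
    x <- runif(sample(5:100, 1))
    ns <- minmax_normalize(x, "unit")
    ps <- to_polar(ns)
    o <- gaf_oracle(ns$values)
    worst <- max(worst,
                 max(abs(gasf(ps)$matrix - o$gasf)),
                 max(abs(gadf(ps)$matrix - o$gadf)))
  }
  expect_lt(worst, 1e-10)
})

test_that("GASF diagonal inverts back to the unit-scaled series", {
  ps <- to_polar(minmax_normalize(c(0, 0.5, 1), "unit"))
  img <- gasf(ps)
  expect_equal(diag(img$matrix), c(-1, -1 / 2, 1))
  expect_equal(invert_gasf_diagonal(img, "unit"), c(0, 0.5, 1))

  ones <- gaf_image(diag(2) * 0 + 1, "gasf")
  expect_equal(invert_gasf_diagonal(ones, "unit"), c(1, 1))

  expect_error(invert_gasf_diagonal(img, "sym"), "sign-ambiguous")
  expect_error(invert_gasf_diagonal(gadf(ps), "unit"), "GASF")

  set.seed(31)
  for (i in 1:50) {
    ns <- minmax_normalize(rnorm(sample(5:60, 1)), "unit")
    rec <- invert_gasf_diagonal(gasf(to_polar(ns)), "unit")
    expect_lt(max(abs(rec - ns$values)), 1e-9)
  }
})

test_that("mtf counts transitions into a row-stochastic W", {
  img <- mtf(c(0, 0, 1, 1), n_bins = 2)
  W <- attr(img, "W")
  expect_equal(W, rbind(c(0.5, 0.5), c(0, 1)))
  expect_equal(img$matrix[1, 4], 0.5)
  expect_equal(img$matrix[3, 4], 1)

  # strictly increasing signal, n_bins = l: superdiagonal transitions
  img <- mtf(c(1, 2, 3, 4), n_bins = 4)
  W <- attr(img, "W")
  for (a in 1:3) expect_equal(W[a, ], as.numeric(1:4 == a + 1))
  expect_equal(W[4, ], rep(0, 4))   # no outflow from the last bin

  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(10:80, 1))
    W <- attr(mtf(x, sample(2:8, 1)), "W")
    rs <- rowSums(W)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
  }
  expect_error(mtf(rep(2, 5), 2), "constant")
})

test_that("recurrence plot thresholds pairwise distances", {
  expect_equal(recurrence_plot(c(0, 1), 0.5)$matrix, diag(2))
  expect_equal(recurrence_plot(c(0, 0.3, 1), 0.5)$matrix,
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  x <- rnorm(10)
  expect_equal(recurrence_plot(x, diff(range(x)))$matrix,
               matrix(1, 10, 10))
  expect_error(recurrence_plot(1:3, -1), "non-negative")
})

test_that("transform_record composes the chain with strategy invariants", {
  ramp <- raw_record("ramp", seq(0, 1, length.out = 10), "x")
  D <- transform_record(ramp, "gadf", l = 4)
  expect_equal(dim(D$matrix), c(4, 4))
  expect_equal(D$matrix, -t(D$matrix))

  r2 <- transform_record(ramp, "gadf", l = 4)
  expect_identical(D$matrix, r2$matrix)   # determinism

  set.seed(77)
  long <- raw_record("bc", rnorm(700), "x")
  G <- transform_record(long, "gasf", l = 64)
  expect_equal(dim(G$matrix), c(64, 64))
  expect_equal(G$matrix, t(G$matrix))
  expect_true(all(abs(G$matrix) <= 1 + 1e-12))
})

test_that("signals of different length but identical shape give one image", {
  template <- sin(seq_len(32) / 4) + seq_len(32) / 16
  stretched <- rep(template, each = 3)   # 96 samples, same step shape
  for (s in c("gasf", "gadf", "mtf", "rp")) {
    a <- transform_record(raw_record("a", template, "x"), s, l = 32)
    b <- transform_record(raw_record("b", stretched, "x"), s, l = 32)
    expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
  }
})

test_that("structural invariants hold across strategies on random input", {
  set.seed(99)
  for (i in 1:40) {
    x <- raw_record("r", rnorm(sample(20:200, 1)), "x")
    l <- sample(c(8L, 16L, 32L), 1)
    G <- transform_record(x, "gasf", l = l)$matrix
    expect_equal(G, t(G))
    expect_true(all(G >= -1 - 1e-12 & G <= 1 + 1e-12))
    D <- transform_record(x, "gadf", l = l)$matrix
    expect_equal(D, -t(D))
    expect_true(all(abs(diag(D)) < 1e-15))
    M <- transform_record(x, "mtf", l = l)$matrix
    expect_true(all(M >= 0 & M <= 1))
    R <- transform_record(x, "rp", l = l)$matrix
    expect_true(all(R %in% c(0, 1)))
    expect_equal(R, t(R))
    expect_true(all(diag(R) == 1))
  }
})

test_that("transform_signals builds a labeled image dataset", {
  ds <- make_toy_signals(3)
  imgs <- transform_signals(ds, "gadf", l = 8)
  expect_s3_class(imgs, "image_dataset")
  expect_length(imgs, length(ds))
  expect_equal(imgs$classes, ds$classes)
  expect_equal(imgs$labels, match(dataset_labels(ds), ds$classes))
  expect_identical(imgs$strategy, "gadf")
})
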