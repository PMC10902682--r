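# Convolutional ablation network: four blocks of 3x3 same-padding
# convolution (channels 16, 32, 64, 64) + ReLU + 2x2 max-pool, then a
# linear layer and softmax.  Convolutions run as im2col matrix products
# with index maps precomputed at build time; backprop scatters gradients
# back through the same index maps.

CNN_CHANNELS <- c(16L, 32L, 64L, 64L)

# Linear indices into the zero-padded (h+2)x(w+2)xCin array for each
# output pixel (rows, r-fastest) and each (channel, kernel-offset) column.
im2col_idx <- function(h, w, cin) {
  r <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  base <- matrix(0L, h * w, 9L)
  k <- 0L
  for (dc in -1:1) {
    for (dr in -1:1) {
      k <- k + 1L
      base[, k] <- (cc + dc) * (h + 2L) + (r + dr + 1L)
    }
  }
  do.call(cbind, lapply(seq_len(cin) - 1L,
                        function(ch) base + ch * (h + 2L) * (w + 2L)))
}

# Candidate linear indices (into the h x w x C flat array) of the four
# pixels feeding each 2x2 pooled cell.
pool_idx <- function(h, w, channels) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  pr <- rep(seq_len(h2), times = w2)
  pc <- rep(seq_len(w2), each = h2)
  cand <- cbind((2L * pc - 2L) * h + 2L * pr - 1L,
                (2L * pc - 2L) * h + 2L * pr,
                (2L * pc - 1L) * h + 2L * pr - 1L,
                (2L * pc - 1L) * h + 2L * pr)
  do.call(rbind, lapply(seq_len(channels) - 1L,
                        function(ch) cand + ch * h * w))
}

cnn_struct <- function(image_size) {
  if (image_size %% 16L != 0L)
    stop2("cnn architecture needs image_size divisible by 16 (got ",
          image_size, ")")
  chans <- c(1L, CNN_CHANNELS)
  layers <- vector("list", 4L)
  s <- as.integer(image_size)
  for (i in 1:4) {
    layers[[i]] <- list(h = s, cin = chans[i], cout = chans[i + 1L],
                        idx = im2col_idx(s, s, chans[i]),
                        pool = pool_idx(s, s, chans[i + 1L]))
    s <- s %/% 2L
  }
  list(layers = layers, flat_dim = s * s * chans[5L])
}

cnn_init_params <- function(cfg, st) {
  p <- list()
  for (i in 1:4) {
    L <- st$layers[[i]]
    p[[sprintf("conv%d.W", i)]] <- he_mat(9L * L$cin, L$cout)
    p[[sprintf("conv%d.b", i)]] <- zeros(L$cout)
  }
  p[["out.W"]] <- xavier(st$flat_dim, cfg$n_classes)
  p[["out.b"]] <- zeros(cfg$n_classes)
  p
}

cnn_forward_sample <- function(p, cfg, st, img, train = FALSE) {
  a <- as.vector(img)            # h x w x 1, column-major
  caches <- vector("list", 4L)
  for (i in 1:4) {
    L <- st$layers[[i]]
    h <- L$h
    pad <- array(0, c(h + 2L, h + 2L, L$cin))
    pad[2:(h + 1L), 2:(h + 1L), ] <- a
    xp <- as.vector(pad)
    Xcol <- matrix(xp[L$idx], nrow = h * h)
    W <- p[[sprintf("conv%d.W", i)]]
    Y <- add_bias(Xcol %*% W, p[[sprintf("conv%d.b", i)]])
    mask <- Y > 0
    Z <- Y * mask
    v <- matrix(as.vector(Z)[L$pool], nrow = nrow(L$pool))
    am <- max.col(v, ties.method = "first")
    sel <- L$pool[cbind(seq_len(nrow(L$pool)), am)]
    a <- pmax(pmax(v[, 1], v[, 2]), pmax(v[, 3], v[, 4]))
    caches[[i]] <- list(Xcol = Xcol, mask = mask, sel = sel,
                        ylen = length(Z))
  }
  logits <- as.vector(a %*% p[["out.W"]]) + p[["out.b"]]
  list(logits = logits, cache = list(layers = caches, flat = a))
}

cnn_backward_sample <- function(p, cfg, st, cache, dlogits) {
  g <- list()
  g[["out.W"]] <- cache$flat %o% dlogits
  g[["out.b"]] <- dlogits
  da <- as.vector(p[["out.W"]] %*% dlogits)
  for (i in 4:1) {
    L <- st$layers[[i]]
    ci <- cache$layers[[i]]
    h <- L$h
    dz <- numeric(ci$ylen)
    dz[ci$sel] <- da
    dY <- matrix(dz, nrow = h * h) * ci$mask
    W <- p[[sprintf("conv%d.W", i)]]
    g[[sprintf("conv%d.W", i)]] <- t(ci$Xcol) %*% dY
    g[[sprintf("conv%d.b", i)]] <- colSums(dY)
    dXcol <- dY %*% t(W)
    rs <- rowsum(as.vector(dXcol), as.vector(L$idx))
    dxp <- numeric((h + 2L) * (h + 2L) * L$cin)
    dxp[as.integer(rownames(rs))] <- rs[, 1]
    dpad <- array(dxp, c(h + 2L, h + 2L, L$cin))
    da <- as.vector(dpad[2:(h + 1L), 2:(h + 1L), , drop = FALSE])
  }
  g
}
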