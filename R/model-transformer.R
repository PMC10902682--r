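# Patch-based transformer encoder-decoder classifier.  The image is cut
# into non-overlapping patches (ViT-style), linearly embedded with a
# learned positional embedding, passed through the encoder stack, and a
# single learned class-query token cross-attends to the encoder memory in
# the decoder stack; a linear head plus softmax yields class
# probabilities.  All backward passes are hand-derived and checked by
# finite differences in the test suite.

mha_W <- function(p, pre) {
  list(Wq = p[[paste0(pre, "Wq")]], bq = p[[paste0(pre, "bq")]],
       Wk = p[[paste0(pre, "Wk")]], bk = p[[paste0(pre, "bk")]],
       Wv = p[[paste0(pre, "Wv")]], bv = p[[paste0(pre, "bv")]],
       Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]])
}

prefix_names <- function(g, pre) {
  names(g) <- paste0(pre, names(g))
  g
}

mha_init <- function(H) {
  list(Wq = xavier(H, H), bq = zeros(H),
       Wk = xavier(H, H), bk = zeros(H),
       Wv = xavier(H, H), bv = zeros(H),
       Wo = xavier(H, H), bo = zeros(H))
}

ln_init <- function(H) list(g = rep(1, H), b = zeros(H))

ff_init <- function(H, Hf) {
  list(W1 = xavier(H, Hf), b1 = zeros(Hf),
       W2 = xavier(Hf, H), b2 = zeros(H))
}

# Precomputed geometry: linear indices of each patch's pixels so a token
# matrix is a single subscript operation.
tr_struct <- function(image_size, patch_size) {
  g <- image_size %/% patch_size
  n_tokens <- g * g
  patch_idx <- matrix(0L, n_tokens, patch_size * patch_size)
  t0 <- 0L
  for (pc in seq_len(g)) {          # patch grid, row-fastest within column
    for (pr in seq_len(g)) {
      t0 <- t0 + 1L
      rows <- ((pr - 1L) * patch_size + 1L):(pr * patch_size)
      cols <- ((pc - 1L) * patch_size + 1L):(pc * patch_size)
      patch_idx[t0, ] <- as.integer(outer(rows, (cols - 1L) * image_size,
                                          "+"))
    }
  }
  list(n_tokens = n_tokens, patch_dim = patch_size * patch_size,
       patch_idx = patch_idx)
}

tr_init_params <- function(cfg, st) {
  H <- cfg$hidden_size
  Hf <- cfg$ff_mult * H
  p <- list()
  p[["embed.W"]] <- xavier(st$patch_dim, H)
  p[["embed.b"]] <- zeros(H)
  p[["pos"]] <- matrix(rnorm(st$n_tokens * H, 0, 0.02), st$n_tokens, H)
  p[["query"]] <- matrix(rnorm(H, 0, 0.02), 1L, H)
  for (i in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%d.", i)
    p <- c(p, prefix_names(mha_init(H), paste0(pre, "attn.")),
           prefix_names(ln_init(H), paste0(pre, "ln1.")),
           prefix_names(ff_init(H, Hf), paste0(pre, "ff.")),
           prefix_names(ln_init(H), paste0(pre, "ln2.")))
  }
  for (j in seq_len(cfg$n_decoder_layers)) {
    pre <- sprintf("dec%d.", j)
    p <- c(p, prefix_names(mha_init(H), paste0(pre, "self.")),
           prefix_names(ln_init(H), paste0(pre, "ln1.")),
           prefix_names(mha_init(H), paste0(pre, "cross.")),
           prefix_names(ln_init(H), paste0(pre, "ln2.")),
           prefix_names(ff_init(H, Hf), paste0(pre, "ff.")),
           prefix_names(ln_init(H), paste0(pre, "ln3.")))
  }
  p[["out.W"]] <- xavier(H, cfg$n_classes)
  p[["out.b"]] <- zeros(cfg$n_classes)
  p
}

tr_forward_sample <- function(p, cfg, st, img, train = FALSE) {
  tok <- matrix(img[st$patch_idx], nrow = st$n_tokens)
  X <- add_bias(tok %*% p[["embed.W"]], p[["embed.b"]]) + p[["pos"]]
  enc <- vector("list", cfg$n_encoder_layers)
  for (i in seq_len(cfg$n_encoder_layers)) {
    pre <- sprintf("enc%d.", i)
    at <- mha_forward(X, X, mha_W(p, paste0(pre, "attn.")), cfg$n_heads)
    d1 <- drop_forward(at$out, cfg$dropout, train)
    l1 <- ln_forward(X + d1$out,
                     p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    ff <- ff_forward(l1$out,
                     p[[paste0(pre, "ff.W1")]], p[[paste0(pre, "ff.b1")]],
                     p[[paste0(pre, "ff.W2")]], p[[paste0(pre, "ff.b2")]])
    d2 <- drop_forward(ff$out, cfg$dropout, train)
    l2 <- ln_forward(l1$out + d2$out,
                     p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    enc[[i]] <- list(at = at, d1 = d1, l1 = l1, ff = ff, d2 = d2, l2 = l2)
    X <- l2$out
  }
  M <- X
  y <- p[["query"]]
  dec <- vector("list", cfg$n_decoder_layers)
  for (j in seq_len(cfg$n_decoder_layers)) {
    pre <- sprintf("dec%d.", j)
    sa <- mha_forward(y, y, mha_W(p, paste0(pre, "self.")), cfg$n_heads)
    ds <- drop_forward(sa$out, cfg$dropout, train)
    l1 <- ln_forward(y + ds$out,
                     p[[paste0(pre, "ln1.g")]], p[[paste0(pre, "ln1.b")]])
    ca <- mha_forward(l1$out, M, mha_W(p, paste0(pre, "cross.")),
                      cfg$n_heads)
    dc <- drop_forward(ca$out, cfg$dropout, train)
    l2 <- ln_forward(l1$out + dc$out,
                     p[[paste0(pre, "ln2.g")]], p[[paste0(pre, "ln2.b")]])
    ff <- ff_forward(l2$out,
                     p[[paste0(pre, "ff.W1")]], p[[paste0(pre, "ff.b1")]],
                     p[[paste0(pre, "ff.W2")]], p[[paste0(pre, "ff.b2")]])
    df <- drop_forward(ff$out, cfg$dropout, train)
    l3 <- ln_forward(l2$out + df$out,
                     p[[paste0(pre, "ln3.g")]], p[[paste0(pre, "ln3.b")]])
    dec[[j]] <- list(sa = sa, ds = ds, l1 = l1, ca = ca, dc = dc,
                     l2 = l2, ff = ff, df = df, l3 = l3)
    y <- l3$out
  }
  logits <- add_bias(y %*% p[["out.W"]], p[["out.b"]])
  list(logits = as.vector(logits),
       cache = list(tok = tok, enc = enc, dec = dec, y = y))
}

tr_backward_sample <- function(p, cfg, st, cache, dlogits) {
  g <- list()
  dlog <- matrix(dlogits, 1L)
  g[["out.W"]] <- t(cache$y) %*% dlog
  g[["out.b"]] <- as.vector(dlog)
  dy <- dlog %*% t(p[["out.W"]])
  dM <- NULL
  for (j in rev(seq_len(cfg$n_decoder_layers))) {
    pre <- sprintf("dec%d.", j)
    cj <- cache$dec[[j]]
    b3 <- ln_backward(dy, cj$l3)
    g[[paste0(pre, "ln3.g")]] <- b3$dg
    g[[paste0(pre, "ln3.b")]] <- b3$db
    fb <- ff_backward(drop_backward(b3$dx, cj$df), cj$ff$cache,
                      p[[paste0(pre, "ff.W1")]], p[[paste0(pre, "ff.W2")]])
    g <- c(g, prefix_names(fb$grads, paste0(pre, "ff.")))
    dl2 <- b3$dx + fb$dx
    b2 <- ln_backward(dl2, cj$l2)
    g[[paste0(pre, "ln2.g")]] <- b2$dg
    g[[paste0(pre, "ln2.b")]] <- b2$db
    cb <- mha_backward(drop_backward(b2$dx, cj$dc), cj$ca$cache,
                       mha_W(p, paste0(pre, "cross.")))
    g <- c(g, prefix_names(cb$grads, paste0(pre, "cross.")))
    dM <- if (is.null(dM)) cb$dXkv else dM + cb$dXkv
    dl1 <- b2$dx + cb$dXq
    b1 <- ln_backward(dl1, cj$l1)
    g[[paste0(pre, "ln1.g")]] <- b1$dg
    g[[paste0(pre, "ln1.b")]] <- b1$db
    sb <- mha_backward(drop_backward(b1$dx, cj$ds), cj$sa$cache,
                       mha_W(p, paste0(pre, "self.")))
    g <- c(g, prefix_names(sb$grads, paste0(pre, "self.")))
    dy <- b1$dx + sb$dXq + sb$dXkv
  }
  g[["query"]] <- dy
  dX <- dM
  for (i in rev(seq_len(cfg$n_encoder_layers))) {
    pre <- sprintf("enc%d.", i)
    ci <- cache$enc[[i]]
    b2 <- ln_backward(dX, ci$l2)
    g[[paste0(pre, "ln2.g")]] <- b2$dg
    g[[paste0(pre, "ln2.b")]] <- b2$db
    fb <- ff_backward(drop_backward(b2$dx, ci$d2), ci$ff$cache,
                      p[[paste0(pre, "ff.W1")]], p[[paste0(pre, "ff.W2")]])
    g <- c(g, prefix_names(fb$grads, paste0(pre, "ff.")))
    dl1 <- b2$dx + fb$dx
    b1 <- ln_backward(dl1, ci$l1)
    g[[paste0(pre, "ln1.g")]] <- b1$dg
    g[[paste0(pre, "ln1.b")]] <- b1$db
    ab <- mha_backward(drop_backward(b1$dx, ci$d1), ci$at$cache,
                       mha_W(p, paste0(pre, "attn.")))
    g <- c(g, prefix_names(ab$grads, paste0(pre, "attn.")))
    dX <- b1$dx + ab$dXq + ab$dXkv
  }
  g[["pos"]] <- dX
  g[["embed.W"]] <- t(cache$tok) %*% dX
  g[["embed.b"]] <- colSums(dX)
  g
}
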