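# Low-level neural-network primitives with hand-derived backward passes.
# All activations are plain matrices (tokens in rows, features in
# columns); parameters live in flat named lists so the Adam optimizer can
# treat them uniformly.

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' The core attention operator: `softmax(Q K' / sqrt(d_k)) V`, with the
#' softmax taken over each row so every output row is a convex
#' combination of the rows of `V`.
#'
#' @param Q Query matrix (n_q x d_k).
#' @param K Key matrix (n_kv x d_k).
#' @param V Value matrix (n_kv x d_v).
#' @return The attended output matrix (n_q x d_v).
#' @export
scaled_dot_product_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K))
    stop2("Q and K must have the same number of columns (d_k)")
  if (nrow(K) != nrow(V))
    stop2("K and V must have the same number of rows")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  A %*% V
}

add_bias <- function(X, b) X + rep(b, each = nrow(X))

# ---- layer normalization (per row, over features) ------------------------

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(out = add_bias(xhat * rep(g, each = nrow(X)), b),
       xhat = xhat, inv = inv, g = g)
}

ln_backward <- function(dY, cache) {
  n <- nrow(dY)
  dxhat <- dY * rep(cache$g, each = n)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) -
                       cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, dg = dg, db = db)
}

# ---- dropout -------------------------------------------------------------

drop_forward <- function(X, p, train) {
  if (!train || p <= 0) return(list(out = X, mask = NULL))
  mask <- (matrix(runif(length(X)), nrow(X)) >= p) / (1 - p)
  list(out = X * mask, mask = mask)
}

drop_backward <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# ---- multi-head attention ------------------------------------------------

# W: list(Wq, bq, Wk, bk, Wv, bv, Wo, bo); Xq (Tq x H), Xkv (Tkv x H).
mha_forward <- function(Xq, Xkv, W, n_heads) {
  H <- ncol(Xq)
  dk <- H %/% n_heads
  Q <- add_bias(Xq %*% W$Wq, W$bq)
  K <- add_bias(Xkv %*% W$Wk, W$bk)
  V <- add_bias(Xkv %*% W$Wv, W$bv)
  O <- matrix(0, nrow(Xq), H)
  A_list <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    A <- softmax_rows(S)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  list(out = add_bias(O %*% W$Wo, W$bo),
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, O = O,
                    A = A_list, n_heads = n_heads, dk = dk))
}

mha_backward <- function(dOut, cache, W) {
  Xq <- cache$Xq; Xkv <- cache$Xkv
  dk <- cache$dk
  dWo <- t(cache$O) %*% dOut
  dbo <- colSums(dOut)
  dO <- dOut %*% t(W$Wo)
  dQ <- matrix(0, nrow(Xq), ncol(Xq))
  dK <- matrix(0, nrow(Xkv), ncol(Xkv))
  dV <- matrix(0, nrow(Xkv), ncol(Xkv))
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dk)
    dK[, cols] <- t(dS) %*% cache$Q[, cols, drop = FALSE] / sqrt(dk)
  }
  list(dXq = dQ %*% t(W$Wq),
       dXkv = dK %*% t(W$Wk) + dV %*% t(W$Wv),
       grads = list(Wq = t(Xq) %*% dQ, bq = colSums(dQ),
                    Wk = t(Xkv) %*% dK, bk = colSums(dK),
                    Wv = t(Xkv) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

# ---- feed-forward block (H -> ff -> H, ReLU) -----------------------------

ff_forward <- function(X, W1, b1, W2, b2) {
  Z <- add_bias(X %*% W1, b1)
  Hid <- pmax(Z, 0)
  list(out = add_bias(Hid %*% W2, b2),
       cache = list(X = X, Hid = Hid, mask = Z > 0))
}

ff_backward <- function(dY, cache, W1, W2) {
  dHid <- (dY %*% t(W2)) * cache$mask
  list(dx = dHid %*% t(W1),
       grads = list(W1 = t(cache$X) %*% dHid, b1 = colSums(dHid),
                    W2 = t(cache$Hid) %*% dY, b2 = colSums(dY)))
}

# ---- parameter initialization helpers ------------------------------------

xavier <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

he_mat <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

zeros <- function(n) numeric(n)

# ---- Adam optimizer over flat named parameter lists ----------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
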