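# Neural-network primitives with hand-derived backward passes.
#
# Every *_fwd returns list(out, cache); every *_bwd consumes the upstream
# gradient plus the cache and returns gradients for inputs and parameters.
# Correctness is pinned by finite-difference gradient checks in the tests.

linear_fwd <- function(X, W, b = NULL) {
  out <- X %*% W
  if (!is.null(b)) out <- add_bias(out, b)
  list(out = out, cache = list(X = X, W = W, has_b = !is.null(b)))
}

linear_bwd <- function(dout, cache) {
  list(dX = dout %*% t(cache$W),
       dW = crossprod(cache$X, dout),
       db = if (cache$has_b) colSums(dout) else NULL)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)
  s <- sqrt(v + eps)
  Xhat <- Xc / s
  out <- add_bias(Xhat * rep(g, each = nrow(X)), b)
  # rep(g, each=n) relies on column-major layout: g broadcast over rows
  list(out = out, cache = list(Xhat = Xhat, s = s, g = g))
}

layernorm_bwd <- function(dout, cache) {
  Xhat <- cache$Xhat
  n <- nrow(dout)
  dg <- colSums(dout * Xhat)
  db <- colSums(dout)
  dXhat <- dout * rep(cache$g, each = n)
  m1 <- rowMeans(dXhat)
  m2 <- rowMeans(dXhat * Xhat)
  dX <- (dXhat - m1 - Xhat * m2) / cache$s
  list(dX = dX, dg = dg, db = db)
}

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(out = X * Phi, cache = list(X = X, Phi = Phi))
}

gelu_bwd <- function(dout, cache) {
  dout * (cache$Phi + cache$X * stats::dnorm(cache$X))
}

# Multi-head scaled-dot-product self-attention.
mha_fwd <- function(X, p, num_heads) {
  d <- ncol(X)
  dk <- d %/% num_heads
  Q <- add_bias(X %*% p$Wq, p$bq)
  K <- add_bias(X %*% p$Wk, p$bk)
  V <- add_bias(X %*% p$Wv, p$bv)
  O <- matrix(0, nrow(X), d)
  Ps <- vector("list", num_heads)
  for (h in seq_len(num_heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(dk)
    P <- softmax_rows(S)
    O[, idx] <- P %*% V[, idx, drop = FALSE]
    Ps[[h]] <- P
  }
  out <- add_bias(O %*% p$Wo, p$bo)
  list(out = out,
       cache = list(X = X, Q = Q, K = K, V = V, O = O, Ps = Ps,
                    p = p, num_heads = num_heads, dk = dk))
}

mha_bwd <- function(dout, cache) {
  p <- cache$p
  nh <- cache$num_heads
  dk <- cache$dk
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(dout), ncol(dout))
  for (h in seq_len(nh)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    P <- cache$Ps[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dP <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(P, dOh)
    dS <- P * (dP - rowSums(dP * P))
    dS <- dS / sqrt(dk)
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  dX <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dX = dX,
       dWq = crossprod(cache$X, dQ), dbq = colSums(dQ),
       dWk = crossprod(cache$X, dK), dbk = colSums(dK),
       dWv = crossprod(cache$X, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}

# Post-layer-norm Transformer encoder block:
#   Y1 = LN(X + MHA(X));  Y2 = LN(Y1 + W2 gelu(W1 Y1))
transformer_layer_fwd <- function(X, p, num_heads) {
  att <- mha_fwd(X, p, num_heads)
  ln1 <- layernorm_fwd(X + att$out, p$ln1_g, p$ln1_b)
  Y1 <- ln1$out
  h1 <- linear_fwd(Y1, p$W1, p$b1)
  act <- gelu_fwd(h1$out)
  h2 <- linear_fwd(act$out, p$W2, p$b2)
  ln2 <- layernorm_fwd(Y1 + h2$out, p$ln2_g, p$ln2_b)
  list(out = ln2$out,
       cache = list(att = att, ln1 = ln1, h1 = h1, act = act, h2 = h2,
                    ln2 = ln2))
}

transformer_layer_bwd <- function(dout, cache) {
  l2 <- layernorm_bwd(dout, cache$ln2$cache)
  dY1 <- l2$dX
  g2 <- linear_bwd(l2$dX, cache$h2$cache)
  dact <- gelu_bwd(g2$dX, cache$act$cache)
  g1 <- linear_bwd(dact, cache$h1$cache)
  dY1 <- dY1 + g1$dX
  l1 <- layernorm_bwd(dY1, cache$ln1$cache)
  att <- mha_bwd(l1$dX, cache$att$cache)
  dX <- l1$dX + att$dX
  grads <- att[names(att) != "dX"]
  grads$dW1 <- g1$dW; grads$db1 <- g1$db
  grads$dW2 <- g2$dW; grads$db2 <- g2$db
  grads$dln1_g <- l1$dg; grads$dln1_b <- l1$db
  grads$dln2_g <- l2$dg; grads$dln2_b <- l2$db
  list(dX = dX, grads = grads)
}

# Bidirectional LSTM over a sequence of d-dim vectors; each direction has
# hidden size d/2 so the concatenated output keeps width d.
bilstm_fwd <- function(X, p) {
  n <- nrow(X)
  Xpf <- add_bias(X %*% p$f_W, p$f_b)
  ff <- lstm_forward_cpp(Xpf, p$f_U)
  Xrev <- X[n:1, , drop = FALSE]
  Xpb <- add_bias(Xrev %*% p$b_W, p$b_b)
  bb <- lstm_forward_cpp(Xpb, p$b_U)
  out <- cbind(ff$H, bb$H[n:1, , drop = FALSE])
  list(out = out, cache = list(X = X, Xrev = Xrev, ff = ff, bb = bb, p = p))
}

bilstm_bwd <- function(dout, cache) {
  p <- cache$p
  n <- nrow(dout)
  h <- ncol(dout) %/% 2L
  dHf <- dout[, seq_len(h), drop = FALSE]
  dHb <- dout[n:1, (h + 1L):(2L * h), drop = FALSE]
  ff <- cache$ff; bb <- cache$bb
  bf <- lstm_backward_cpp(dHf, p$f_U, ff$H, ff$C, ff$I, ff$F, ff$O, ff$G)
  bbk <- lstm_backward_cpp(dHb, p$b_U, bb$H, bb$C, bb$I, bb$F, bb$O, bb$G)
  dX <- bf$dXp %*% t(p$f_W) + (bbk$dXp %*% t(p$b_W))[n:1, , drop = FALSE]
  list(dX = dX,
       df_W = crossprod(cache$X, bf$dXp), df_b = colSums(bf$dXp),
       df_U = bf$dU,
       db_W = crossprod(cache$Xrev, bbk$dXp), db_b = colSums(bbk$dXp),
       db_U = bbk$dU)
}

# ---- parameter initialisation ------------------------------------------

# Fan-in scaled Gaussian init: keeps layer outputs at unit scale for any
# width, so small desk-scale encoders train as readily as wide ones.
rnorm_mat <- function(nr, nc, sd = 1 / sqrt(nr)) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

init_transformer_layer <- function(d, ff) {
  list(Wq = rnorm_mat(d, d), bq = numeric(d),
       Wk = rnorm_mat(d, d), bk = numeric(d),
       Wv = rnorm_mat(d, d), bv = numeric(d),
       Wo = rnorm_mat(d, d), bo = numeric(d),
       ln1_g = rep(1, d), ln1_b = numeric(d),
       W1 = rnorm_mat(d, ff), b1 = numeric(ff),
       W2 = rnorm_mat(ff, d), b2 = numeric(d),
       ln2_g = rep(1, d), ln2_b = numeric(d))
}

init_bilstm <- function(d) {
  h <- d %/% 2L
  forget_bias <- rep(0, 4L * h)
  forget_bias[(h + 1L):(2L * h)] <- 1  # open forget gates at init
  list(f_W = rnorm_mat(d, 4L * h), f_U = rnorm_mat(h, 4L * h),
       f_b = forget_bias,
       b_W = rnorm_mat(d, 4L * h), b_U = rnorm_mat(h, 4L * h),
       b_b = forget_bias)
}

# Flatten nested parameter lists for the optimiser: numeric leaves only.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    p[[path]] <- flat[[key]]
  }
  p
}

# ---- Adam ---------------------------------------------------------------

adam_state <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 1.0) {
  if (!is.null(clip_norm) && is.finite(clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
    if (gn > clip_norm) grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = flat, state = state)
}
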