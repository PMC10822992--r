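# Layer primitives for the ViT detector: each has a forward returning the
# values needed by the matching backward. All maths is plain matrix algebra;
# gradients are hand-derived and validated by a finite-difference test.

LN_EPS <- 1e-6

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise layer normalization with learned gain/bias.
ln_forward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, `*`) + matrix(b, nrow(x), length(b), byrow = TRUE),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# Inverted dropout: mask carries the 1/(1-p) rescale; identity in eval mode.
drop_mask <- function(dims, p, train) {
  if (!train || p <= 0) return(1)
  array(stats::rbinom(prod(dims), 1, 1 - p) / (1 - p), dims)
}

# Multi-head self-attention over an N x d token matrix.
mha_forward <- function(x, ap, num_heads, attention_dropout = 0, train = FALSE) {
  d <- ncol(x)
  dh <- d %/% num_heads
  if (dh * num_heads != d)
    stop("num_heads must divide the embedding dimension", call. = FALSE)
  scal <- 1 / sqrt(dh)
  Q <- x %*% ap$Wq + matrix(ap$bq, nrow(x), d, byrow = TRUE)
  K <- x %*% ap$Wk + matrix(ap$bk, nrow(x), d, byrow = TRUE)
  V <- x %*% ap$Wv + matrix(ap$bv, nrow(x), d, byrow = TRUE)
  O <- matrix(0, nrow(x), d)
  P_list <- vector("list", num_heads)
  mask_list <- vector("list", num_heads)
  for (h in seq_len(num_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) * scal
    P <- softmax_rows(S)
    m <- drop_mask(dim(P), attention_dropout, train)
    P_list[[h]] <- P
    mask_list[[h]] <- m
    O[, idx] <- (P * m) %*% V[, idx, drop = FALSE]
  }
  out <- O %*% ap$Wo + matrix(ap$bo, nrow(x), d, byrow = TRUE)
  list(out = out,
       cache = list(x = x, Q = Q, K = K, V = V, O = O,
                    P = P_list, mask = mask_list, dh = dh, scal = scal))
}

mha_backward <- function(dout, cache, ap, num_heads) {
  x <- cache$x
  d <- ncol(x)
  dh <- cache$dh
  scal <- cache$scal
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dO <- dout %*% t(ap$Wo)
  dQ <- matrix(0, nrow(x), d)
  dK <- matrix(0, nrow(x), d)
  dV <- matrix(0, nrow(x), d)
  for (h in seq_len(num_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$P[[h]]
    m <- cache$mask[[h]]
    Pd <- P * m
    dOh <- dO[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    dPd <- dOh %*% t(Vh)
    dV[, idx] <- t(Pd) %*% dOh
    dP <- dPd * m
    dS <- P * (dP - rowSums(dP * P))
    dQ[, idx] <- (dS %*% cache$K[, idx, drop = FALSE]) * scal
    dK[, idx] <- (t(dS) %*% cache$Q[, idx, drop = FALSE]) * scal
  }
  dx <- dQ %*% t(ap$Wq) + dK %*% t(ap$Wk) + dV %*% t(ap$Wv)
  list(dx = dx,
       grads = list(Wq = t(x) %*% dQ, bq = colSums(dQ),
                    Wk = t(x) %*% dK, bk = colSums(dK),
                    Wv = t(x) %*% dV, bv = colSums(dV),
                    Wo = dWo, bo = dbo))
}

# One pre-norm encoder block: x + MHA(LN(x)), then + MLP(LN(.)).
block_forward <- function(x, bp, num_heads, attention_dropout = 0,
                          mlp_dropout = 0, train = FALSE) {
  l1 <- ln_forward(x, bp$ln1$g, bp$ln1$b)
  at <- mha_forward(l1$out, bp$attn, num_heads, attention_dropout, train)
  mid <- x + at$out
  l2 <- ln_forward(mid, bp$ln2$g, bp$ln2$b)
  Z1 <- l2$out %*% bp$mlp$W1 + matrix(bp$mlp$b1, nrow(x), ncol(bp$mlp$W1),
                                      byrow = TRUE)
  A1 <- gelu(Z1)
  m1 <- drop_mask(dim(A1), mlp_dropout, train)
  A1d <- A1 * m1
  Z2 <- A1d %*% bp$mlp$W2 + matrix(bp$mlp$b2, nrow(x), ncol(bp$mlp$W2),
                                   byrow = TRUE)
  m2 <- drop_mask(dim(Z2), mlp_dropout, train)
  out <- mid + Z2 * m2
  list(out = out,
       cache = list(x = x, l1 = l1, at = at, mid = mid, l2 = l2,
                    Z1 = Z1, A1d = A1d, m1 = m1, m2 = m2))
}

block_backward <- function(dout, cache, bp, num_heads) {
  dmid <- dout
  dZ2 <- dout * cache$m2
  dW2 <- t(cache$A1d) %*% dZ2
  db2 <- colSums(dZ2)
  dA1d <- dZ2 %*% t(bp$mlp$W2)
  dZ1 <- dA1d * cache$m1 * gelu_grad(cache$Z1)
  dW1 <- t(cache$l2$out) %*% dZ1
  db1 <- colSums(dZ1)
  dH2 <- dZ1 %*% t(bp$mlp$W1)
  l2b <- ln_backward(dH2, cache$l2, bp$ln2$g)
  dmid <- dmid + l2b$dx
  atb <- mha_backward(dmid, cache$at$cache, bp$attn, num_heads)
  l1b <- ln_backward(atb$dx, cache$l1, bp$ln1$g)
  dx <- dmid + l1b$dx
  list(dx = dx,
       grads = list(ln1 = list(g = l1b$dg, b = l1b$db),
                    attn = atb$grads,
                    ln2 = list(g = l2b$dg, b = l2b$db),
                    mlp = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)))
}

#' One ViT encoder block applied to a token matrix
#'
#' The pre-normalization ordering used throughout the detector:
#' `x + MHA(LN(x))` followed by `+ MLP(LN(.))`, where the MLP has widths
#' `c(2, 1) * ncol(x)` with GELU activations. Exposed so the block's
#' algebraic properties (residual identity with zeroed weights,
#' permutation-equivariance) can be exercised directly; dropout is off here,
#' so the map is deterministic.
#'
#' @param x `N x d` token matrix.
#' @param params block parameter list with elements `ln1`, `attn`, `ln2`,
#'   `mlp` as produced inside [train_vit()] models (`model$params$blocks[[i]]`).
#' @param num_heads number of attention heads; must divide `d`.
#' @return `N x d` matrix.
#' @export
transformer_block <- function(x, params, num_heads) {
  block_forward(x, params, num_heads)$out
}
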