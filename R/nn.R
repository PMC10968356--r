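# Minimal matrix-level neural-net primitives with hand-written backward
# passes. Only the alignment adapter and the descriptor bank are ever
# trained, so frozen layers implement input gradients only.
#
# Conventions: token matrices are N x d (row per token). Feature grids are
# (gh, gw, d) arrays; grid <-> token index mapping is column-major,
# t = (j - 1) * gh + i.

grid_to_mat <- function(g) {
  d <- dim(g); matrix(g, d[1] * d[2], d[3])
}
mat_to_grid <- function(m, gh, gw) {
  array(m, c(gh, gw, ncol(m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

relu6 <- function(x) pmin(pmax(x, 0), 6)
relu6_grad <- function(x) (x > 0 & x < 6) * 1

# ---- layer norm (frozen affine) --------------------------------------------

layernorm_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat, 2, gamma, `*`)
  out <- sweep(out, 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

layernorm_bwd <- function(G, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dxhat <- sweep(G, 2, cache$gamma, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  (dxhat - m1 - xhat * m2) * inv
}

# ---- single-head attention (frozen projections) ----------------------------
# Q, K, V are raw inputs; Wq/Wk may be the same matrix (shared) to preserve
# inner-product structure between positional codes.

attn_fwd <- function(Q, K, V, W) {
  d <- ncol(W$Wq)
  q <- Q %*% W$Wq; k <- K %*% W$Wk; v <- V %*% W$Wv
  S <- tcrossprod(q, k) / sqrt(d)
  A <- softmax_rows(S)
  H <- A %*% v
  out <- H %*% W$Wo
  list(out = out, cache = list(q = q, k = k, v = v, A = A, H = H, W = W, d = d))
}

attn_bwd <- function(G, cache) {
  W <- cache$W; A <- cache$A
  dH <- tcrossprod(G, W$Wo)
  dA <- tcrossprod(dH, cache$v)
  dv <- crossprod(A, dH)
  dS <- A * (dA - rowSums(dA * A))
  sc <- 1 / sqrt(cache$d)
  dq <- (dS %*% cache$k) * sc
  dk <- (crossprod(dS, cache$q)) * sc
  list(dQ = tcrossprod(dq, W$Wq),
       dK = tcrossprod(dk, W$Wk),
       dV = tcrossprod(dv, W$Wv))
}

# ---- frozen 2-layer MLP ----------------------------------------------------

mlp_fwd <- function(X, W1, b1, W2, b2) {
  A1 <- sweep(X %*% W1, 2, b1, `+`)
  H1 <- gelu(A1)
  out <- sweep(H1 %*% W2, 2, b2, `+`)
  list(out = out, cache = list(X = X, A1 = A1, W1 = W1, W2 = W2))
}

mlp_bwd <- function(G, cache) {
  dH1 <- tcrossprod(G, cache$W2)
  dA1 <- dH1 * gelu_grad(cache$A1)
  tcrossprod(dA1, cache$W1)
}

# ---- depthwise 3x3 convolution on a (gh, gw, C) grid -----------------------
# out[i,j,c] = sum_{u,v in -1..1} W[u+2, v+2, c] * X[i+u, j+v, c], zero pad.

shift3d <- function(X, di, dj) {
  d <- dim(X)
  out <- array(0, d)
  src_i <- max(1L, 1L - di):min(d[1], d[1] - di)
  src_j <- max(1L, 1L - dj):min(d[2], d[2] - dj)
  if (length(src_i) < 1L || length(src_j) < 1L) return(out)
  out[src_i + di, src_j + dj, ] <- X[src_i, src_j, , drop = FALSE]
  out
}

dwconv_fwd <- function(X, Wd) {
  d <- dim(X)
  out <- array(0, d)
  for (u in -1:1) for (v in -1:1) {
    S <- shift3d(X, -u, -v)           # S[i,j,] = X[i+u, j+v, ]
    w <- Wd[u + 2L, v + 2L, ]
    out <- out + sweep(S, 3, w, `*`)
  }
  list(out = out, cache = list(X = X, Wd = Wd))
}

dwconv_bwd <- function(G, cache) {
  X <- cache$X; Wd <- cache$Wd
  dX <- array(0, dim(X))
  dW <- array(0, dim(Wd))
  for (u in -1:1) for (v in -1:1) {
    w <- Wd[u + 2L, v + 2L, ]
    dX <- dX + sweep(shift3d(G, u, v), 3, w, `*`)
    S <- shift3d(X, -u, -v)
    dW[u + 2L, v + 2L, ] <- colSums(matrix(G * S, prod(dim(G)[1:2]), dim(G)[3]))
  }
  list(dX = dX, dW = dW)
}

# ---- bilinear interpolation matrix for grid -> pixel upsampling ------------
# Row s gives the interpolation weights of output pixel s over grid cells.
# Grid cell centres sit at (k - 0.5) * p - 0.5 in 0-based pixel coordinates.

interp_matrix <- function(S, g, p) {
  u <- (((seq_len(S) - 1) + 0.5) / p) - 0.5    # pixel centre in grid units
  U <- matrix(0, S, g)
  i0 <- floor(u)
  w <- u - i0
  # outside the grid-centre range both neighbours clamp to the same cell,
  # so the row still sums to 1 (constant extrapolation at the borders)
  lo <- pmin(pmax(i0, 0), g - 1)
  hi <- pmin(pmax(i0 + 1, 0), g - 1)
  for (s in seq_len(S)) {
    U[s, lo[s] + 1] <- U[s, lo[s] + 1] + (1 - w[s])
    U[s, hi[s] + 1] <- U[s, hi[s] + 1] + w[s]
  }
  U
}

# ---- Adam over a nested list of arrays -------------------------------------

adam_init <- function(params) {
  list(m = rapply(params, function(a) array(0, dim(a) %||% length(a)),
                  how = "replace"),
       v = rapply(params, function(a) array(0, dim(a) %||% length(a)),
                  how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mhat <- m2 / (1 - beta1^t)
    vhat <- v2 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}
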