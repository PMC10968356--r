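#' Domain-alignment adapter
#'
#' A stack of `L` lightweight inverted-residual layers (MobileNetV2 style)
#' inserted between the patch-embedding layer and the frozen transformer
#' blocks. Each layer expands the `d`-dimensional patch features to
#' `inner_channels`, applies a 3x3 depthwise (channel-wise) spatial
#' convolution over the feature grid, projects back to `d`, and adds the
#' result to its input. The final projection of every layer is zero-
#' initialized, so a fresh adapter is exactly the identity map and training
#' starts from the vanilla frozen-model behaviour.
#'
#' @param L Number of inverted-residual layers (default 12).
#' @param embed_dim Patch-feature width `d` (must match the backend).
#' @param inner_channels Bottleneck expansion width (default 96).
#' @param seed Seed for the (non-zero) expansion weights.
#' @return An object of class `alignment_adapter` holding the trainable
#'   layer parameters.
#' @export
alignment_adapter <- function(L = 12L, embed_dim = 64L, inner_channels = 96L,
                              seed = 11L) {
  if (L < 0) stop_input("L must be >= 0")
  d <- as.integer(embed_dim); ic <- as.integer(inner_channels)
  layers <- with_seed(seed, lapply(seq_len(L), function(l) {
    list(
      We = matrix(stats::rnorm(d * ic, 0, 1 / sqrt(d)), d, ic),
      be = rep(0, ic),
      Wd = array(stats::rnorm(9 * ic, 0, 1 / 3), c(3, 3, ic)),
      bd = rep(0, ic),
      Wp = matrix(0, ic, d),      # zero init => identity at initialization
      bp = rep(0, d)
    )
  }))
  structure(list(L = as.integer(L), embed_dim = d, inner_channels = ic,
                 layers = layers),
            class = "alignment_adapter")
}

#' @export
print.alignment_adapter <- function(x, ...) {
  cat("<alignment_adapter> ", x$L, " inverted-residual layers, ",
      x$embed_dim, " -> ", x$inner_channels, " -> ", x$embed_dim, "\n",
      sep = "")
  invisible(x)
}

# Forward pass over a (gh, gw, d) feature grid; caches for backprop.
adapter_fwd <- function(grid, adapter, want_grad = FALSE) {
  d <- dim(grid)
  if (d[3] != adapter$embed_dim)
    stop_input("feature width does not match the adapter's embedding width")
  caches <- if (want_grad) vector("list", adapter$L)
  X <- grid
  for (l in seq_len(adapter$L)) {
    P <- adapter$layers[[l]]
    Xm <- grid_to_mat(X)
    A1 <- sweep(Xm %*% P$We, 2, P$be, `+`)
    H1 <- relu6(A1)
    cf <- dwconv_fwd(mat_to_grid(H1, d[1], d[2]), P$Wd)
    A2 <- sweep(grid_to_mat(cf$out), 2, P$bd, `+`)
    H2 <- relu6(A2)
    delta <- sweep(H2 %*% P$Wp, 2, P$bp, `+`)
    Xout <- X + mat_to_grid(delta, d[1], d[2])
    if (want_grad)
      caches[[l]] <- list(Xm = Xm, A1 = A1, H1 = H1, cconv = cf$cache,
                          A2 = A2, H2 = H2)
    X <- Xout
  }
  list(out = X, cache = caches)
}

#' Apply the alignment adapter to a patch-feature grid
#'
#' @param features `gh x gw x d` feature grid (or `N x d` token matrix with
#'   attribute-free square grid assumed).
#' @param adapter An [alignment_adapter()].
#' @return Aligned features of identical shape. A freshly initialized
#'   adapter returns its input exactly.
#' @export
align_features <- function(features, adapter) {
  if (!inherits(adapter, "alignment_adapter"))
    stop_input("adapter must be an alignment_adapter")
  if (length(dim(features)) != 3L)
    stop_input("features must be a gh x gw x d array")
  adapter_fwd(features, adapter, want_grad = FALSE)$out
}

# Backward pass: returns per-layer parameter gradients (same nesting as
# adapter$layers). The gradient w.r.t. the grid input is not propagated
# further because everything upstream (patch embedding) is frozen.
adapter_bwd <- function(dOut, caches, adapter) {
  d <- dim(dOut)
  grads <- vector("list", adapter$L)
  dX <- dOut
  for (l in rev(seq_len(adapter$L))) {
    P <- adapter$layers[[l]]
    cc <- caches[[l]]
    dXm <- grid_to_mat(dX)                 # gradient at this layer's output
    dH2 <- dXm %*% t(P$Wp)
    dWp <- crossprod(cc$H2, dXm)
    dbp <- colSums(dXm)
    dA2 <- dH2 * relu6_grad(cc$A2)
    dbd <- colSums(dA2)
    cb <- dwconv_bwd(mat_to_grid(dA2, d[1], d[2]), cc$cconv)
    dH1 <- grid_to_mat(cb$dX)
    dA1 <- dH1 * relu6_grad(cc$A1)
    dWe <- crossprod(cc$Xm, dA1)
    dbe <- colSums(dA1)
    grads[[l]] <- list(We = dWe, be = dbe, Wd = cb$dW, bd = dbd,
                       Wp = dWp, bp = dbp)
    # residual: d(input) = d(output) + backprop through the bottleneck
    dX <- dX + mat_to_grid(dA1 %*% t(P$We), d[1], d[2])
  }
  grads
}

# Extract / replace the trainable parameter list of an adapter.
adapter_params <- function(adapter) adapter$layers
set_adapter_params <- function(adapter, layers) {
  adapter$layers <- layers
  adapter
}
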