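#' Frozen promptable-segmentation backends
#'
#' A backend bundles the three frozen components of a promptable
#' segmentation foundation model: the patch-embedding + transformer image
#' encoder, the positional/point prompt encoder, and the two-way-attention
#' mask decoder. Backends satisfy a common contract (`patch_size`,
#' `embed_dim`, frozen parameters, deterministic forward passes) so that the
#' miniature surrogate used in tests and a real ViT-B checkpoint are
#' interchangeable from the caller's point of view.
#'
#' `surrogate_backend()` builds the miniature CPU backend: patch embedding,
#' sinusoidal/Fourier positional codes, `n_blocks` pre-norm transformer
#' blocks, and a one-round two-way-attention mask decoder with an
#' IoU-style confidence head. All weights are randomly initialized once and
#' permanently frozen; gradient ever flows only to the alignment adapter and
#' the descriptor bank.
#'
#' @param patch_size Patch size in pixels (crop sides must be divisible).
#' @param embed_dim Token width `d`. Descriptor banks used with the backend
#'   must share this token dimension.
#' @param n_blocks Number of frozen transformer blocks.
#' @param seed Seed for the frozen random initialization.
#' @return An object of class `seg_backend`.
#' @export
surrogate_backend <- function(patch_size = 16L, embed_dim = 64L,
                              n_blocks = 2L, seed = 7L) {
  d <- as.integer(embed_dim)
  p <- as.integer(patch_size)
  params <- with_seed(seed, {
    rmat <- function(nr, nc, sc = 1 / sqrt(nc)) {
      matrix(stats::rnorm(nr * nc, 0, sc), nr, nc)
    }
    attn_w <- function(shared_qk = FALSE) {
      Wq <- rmat(d, d)
      list(Wq = Wq, Wk = if (shared_qk) Wq else rmat(d, d),
           Wv = rmat(d, d), Wo = rmat(d, d))
    }
    ln_w <- function() list(gamma = rep(1, d), beta = rep(0, d))
    block_w <- function() list(
      ln1 = ln_w(), attn = attn_w(),
      ln2 = ln_w(), W1 = rmat(d, 2L * d), b1 = rep(0, 2L * d),
      W2 = rmat(2L * d, d), b2 = rep(0, d)
    )
    list(
      Wpe = rmat(3L * p * p, d, sc = 1 / sqrt(3 * p * p)),
      bpe = rep(0, d),
      posF = matrix(stats::rnorm(2L * (d %/% 2L), 0, 1.5), 2L, d %/% 2L),
      blocks = lapply(seq_len(n_blocks), function(i) block_w()),
      dec = list(
        ln_a = ln_w(), self_attn = attn_w(),
        ln_b = ln_w(), cross_ti = attn_w(shared_qk = TRUE),
        ln_c = ln_w(), M1 = rmat(d, 2L * d), mb1 = rep(0, 2L * d),
        M2 = rmat(2L * d, d), mb2 = rep(0, d),
        ln_d = ln_w(), cross_it = attn_w(shared_qk = TRUE),
        Wm = rmat(d, d), bm = rep(0, d),
        # sub-pixel mask head: one probe projection per position in an
        # upF x upF cell, biased toward the shared cell probe
        upF = 2L,
        logit_scale = 1 / sqrt(d),
        # mask prior: an arbitrary prompt selects (almost) nothing, so
        # untrained channels sit near zero probability instead of 0.5
        logit_bias = -2,
        Wsub = lapply(seq_len(4L), function(o)
          diag(0.7, d) + rmat(d, d, sc = 0.3 / sqrt(d))),
        w_iou = stats::rnorm(d, 0, 1 / sqrt(d)), b_iou = 0,
        mask_token = stats::rnorm(d, 0, 1 / sqrt(d)),
        iou_token = stats::rnorm(d, 0, 1 / sqrt(d)),
        polarity = rmat(2L, d, sc = 1 / sqrt(d))
      ),
      point_amp = 4, point_sigma = 6
    )
  })
  structure(
    list(name = "surrogate", patch_size = p, embed_dim = d,
         n_blocks = as.integer(n_blocks),
         pixel_mean = c(0.5, 0.5, 0.5), pixel_sd = c(0.25, 0.25, 0.25),
         params = params),
    class = "seg_backend"
  )
}

#' @export
print.seg_backend <- function(x, ...) {
  cat("<seg_backend> ", x$name, ": patch ", x$patch_size, ", width ",
      x$embed_dim, ", ", x$n_blocks, " blocks\n", sep = "")
  invisible(x)
}

#' Create a backend by name
#'
#' @param name `"surrogate"` (the miniature CPU backend) or `"vit_b"`
#'   (a real ViT-B foundation-model checkpoint; requires external weights
#'   and a deep-learning runtime, and is not available in this build).
#' @param ... Passed to the backend constructor.
#' @return A `seg_backend`.
#' @export
create_backend <- function(name = c("surrogate", "vit_b"), ...) {
  name <- match.arg(name)
  if (name == "vit_b")
    stop_input("the 'vit_b' backend requires external foundation-model ",
               "weights and a tensor runtime; use the 'surrogate' backend")
  surrogate_backend(...)
}

#' Checksum of a backend's frozen parameters
#'
#' Used by the freezing contract: the checksum must be identical before and
#' after any number of training steps.
#'
#' @param backend A `seg_backend`.
#' @return A character digest.
#' @export
backend_checksum <- function(backend) {
  v <- unlist(backend$params, use.names = FALSE)
  paste0(length(v), "-", format(sum(v), digits = 17), "-",
         format(sum(abs(v)), digits = 17), "-",
         format(sum(v * seq_along(v) %% 97), digits = 17))
}

# Fourier positional code for 0-based (x, y) pixel coordinates, normalized
# by the crop size. Shared between grid tokens and point prompts so that
# query/key inner products reflect spatial proximity.
positional_code <- function(xy, crop_size, backend) {
  z <- 2 * pi * (xy / crop_size)
  proj <- z %*% backend$params$posF
  cbind(sin(proj), cos(proj))
}

# Positional codes of the gh x gw grid-cell centres (column-major order).
grid_positional <- function(gh, gw, crop_size, backend) {
  p <- backend$patch_size
  ii <- rep(seq_len(gh), times = gw)
  jj <- rep(seq_len(gw), each = gh)
  xy <- cbind((jj - 0.5) * p - 0.5, (ii - 0.5) * p - 0.5)
  positional_code(xy, crop_size, backend)
}

# Normalize an RGB crop (0..255) into patch-token rows (N x 3p^2),
# column-major patch order matching the grid token layout.
patchify <- function(image, backend) {
  p <- backend$patch_size
  H <- dim(image)[1]; W <- dim(image)[2]
  if (H %% p != 0L || W %% p != 0L)
    stop_input("crop dimensions must be divisible by the patch size")
  gh <- H %/% p; gw <- W %/% p
  x <- image / 255
  for (ch in 1:3)
    x[, , ch] <- (x[, , ch] - backend$pixel_mean[ch]) / backend$pixel_sd[ch]
  # reshape (gh*p, gw*p, 3) -> (N, p*p*3)
  dim(x) <- c(p, gh, p, gw, 3L)
  x <- aperm(x, c(2, 4, 1, 3, 5))          # gh, gw, p, p, 3
  dim(x) <- c(gh * gw, p * p * 3L)
  list(X = x, gh = gh, gw = gw)
}

#' Encode an image crop into an embedding grid
#'
#' Runs the full frozen encoder pipeline: patch embedding, optional
#' domain-alignment adapter on the low-level patch features, positional
#' codes, then the frozen transformer blocks. Encoder weights are never
#' modified; when gradients are requested they flow only to the adapter.
#'
#' @param image `S x S x 3` crop with intensities in `[0, 255]`.
#' @param backend A `seg_backend`.
#' @param adapter An [alignment_adapter()] or `NULL` for the adapter-free
#'   pass.
#' @param want_grad Keep forward caches for a later backward pass.
#' @return List with `emb` (`N x d` token matrix), `gh`, `gw`, `pos`
#'   (positional codes) and, if requested, `cache`.
#' @export
encode_image <- function(image, backend, adapter = NULL, want_grad = FALSE) {
  pt <- patchify(image, backend)
  tok <- sweep(pt$X %*% backend$params$Wpe, 2, backend$params$bpe, `+`)
  ad_cache <- NULL
  if (!is.null(adapter)) {
    af <- adapter_fwd(mat_to_grid(tok, pt$gh, pt$gw), adapter,
                      want_grad = want_grad)
    tok <- grid_to_mat(af$out)
    ad_cache <- af$cache
  }
  pos <- grid_positional(pt$gh, pt$gw, nrow(image), backend)
  z <- tok + pos
  blk_caches <- vector("list", backend$n_blocks)
  for (b in seq_len(backend$n_blocks)) {
    bf <- block_fwd(z, backend$params$blocks[[b]])
    z <- bf$out
    if (want_grad) blk_caches[[b]] <- bf$cache
  }
  out <- list(emb = z, gh = pt$gh, gw = pt$gw, pos = pos)
  if (want_grad)
    out$cache <- list(adapter = ad_cache, blocks = blk_caches,
                      gh = pt$gh, gw = pt$gw)
  out
}

# Backward through the frozen blocks down to the adapter parameters.
encode_bwd <- function(dZ, cache, backend, adapter) {
  for (b in rev(seq_len(backend$n_blocks)))
    dZ <- block_bwd(dZ, cache$blocks[[b]])
  if (is.null(adapter) || is.null(cache$adapter)) return(NULL)
  dG <- mat_to_grid(dZ, cache$gh, cache$gw)
  adapter_bwd(dG, cache$adapter, adapter)
}

# One pre-norm transformer block (frozen).
block_fwd <- function(z, bw) {
  l1 <- layernorm_fwd(z, bw$ln1$gamma, bw$ln1$beta)
  a1 <- attn_fwd(l1$out, l1$out, l1$out, bw$attn)
  z1 <- z + a1$out
  l2 <- layernorm_fwd(z1, bw$ln2$gamma, bw$ln2$beta)
  m1 <- mlp_fwd(l2$out, bw$W1, bw$b1, bw$W2, bw$b2)
  list(out = z1 + m1$out,
       cache = list(l1 = l1, a1 = a1, l2 = l2, m1 = m1))
}

block_bwd <- function(G, cache) {
  dz1 <- G + layernorm_bwd(mlp_bwd(G, cache$m1$cache), cache$l2$cache)
  ga <- attn_bwd(dz1, cache$a1$cache)
  dz1 + layernorm_bwd(ga$dQ + ga$dK + ga$dV, cache$l1$cache)
}
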