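#' Prompt set for one output channel
#'
#' The prompt fed to the mask decoder for a single output channel: the
#' channel's descriptor token stack plus optional interactive point prompts.
#'
#' @param tokens `K x D` matrix of descriptor tokens (see
#'   [init_descriptor_bank()]), or `NULL` when prompting with points alone.
#' @param points Optional data.frame with columns `x`, `y` (0-based
#'   crop-local pixel coordinates) and `polarity` (`"foreground"` or
#'   `"background"`).
#' @return An object of class `prompt_set`.
#' @export
prompt_set <- function(tokens = NULL, points = NULL) {
  if (is.null(tokens) && (is.null(points) || nrow(points) == 0L))
    stop_input("a prompt set needs at least one token or point")
  if (!is.null(points) && nrow(points)) {
    if (!all(c("x", "y", "polarity") %in% names(points)))
      stop_input("points need columns x, y, polarity")
    if (!all(points$polarity %in% c("foreground", "background")))
      stop_input("point polarity must be 'foreground' or 'background'")
  }
  structure(list(tokens = tokens, points = points), class = "prompt_set")
}

# Build the token matrix entering the decoder for one channel:
# [mask slot; iou token; K descriptors; point tokens]. The mask slot is
# seeded by the mean of the channel's prompt tokens: with a frozen decoder
# the slot cannot learn to route channel identity by itself, so the probe
# direction is placed directly under the descriptors' control.
assemble_prompt_tokens <- function(prompt, crop_size, backend) {
  dec <- backend$params$dec
  pool <- prompt$tokens
  n_desc <- if (is.null(prompt$tokens)) 0L else nrow(prompt$tokens)
  pts_tok <- NULL
  if (!is.null(prompt$points) && nrow(prompt$points)) {
    pts <- prompt$points
    if (any(pts$x < 0 | pts$x >= crop_size | pts$y < 0 | pts$y >= crop_size))
      stop_input("point coordinates fall outside the crop")
    pe <- positional_code(cbind(pts$x, pts$y), crop_size, backend)
    pol <- dec$polarity[ifelse(pts$polarity == "foreground", 1L, 2L), ,
                        drop = FALSE]
    pts_tok <- pe + pol
  }
  seed <- if (n_desc > 0L) colMeans(pool) else colMeans(pts_tok)
  T0 <- rbind(dec$mask_token + seed, dec$iou_token)
  if (!is.null(pool)) T0 <- rbind(T0, pool)
  if (!is.null(pts_tok)) T0 <- rbind(T0, pts_tok)
  list(T0 = T0, n_desc = n_desc)
}

# One-round two-way-attention decoding of a single channel (frozen weights).
decode_channel_fwd <- function(Z, pos, T0, backend, want_grad = FALSE) {
  dec <- backend$params$dec
  d <- backend$embed_dim
  la <- layernorm_fwd(T0, dec$ln_a$gamma, dec$ln_a$beta)
  sa <- attn_fwd(la$out, la$out, la$out, dec$self_attn)
  T1 <- T0 + sa$out
  lb <- layernorm_fwd(T1, dec$ln_b$gamma, dec$ln_b$beta)
  ca <- attn_fwd(lb$out, Z + pos, Z, dec$cross_ti)
  T2 <- T1 + ca$out
  lc <- layernorm_fwd(T2, dec$ln_c$gamma, dec$ln_c$beta)
  ml <- mlp_fwd(lc$out, dec$M1, dec$mb1, dec$M2, dec$mb2)
  T3 <- T2 + ml$out
  ld <- layernorm_fwd(Z, dec$ln_d$gamma, dec$ln_d$beta)
  ci <- attn_fwd(ld$out + pos, T3, T3, dec$cross_it)
  Z2 <- Z + ci$out
  m <- as.numeric(T3[1, ] %*% dec$Wm + dec$bm)
  # sub-pixel mask head: one probe per position in the upF x upF cell
  Q <- vapply(dec$Wsub, function(W) as.numeric(W %*% m), numeric(d))
  logits_sub <- (Z2 %*% Q) * dec$logit_scale + dec$logit_bias  # N x upF^2
  conf <- sigmoid(sum(T3[2, ] * dec$w_iou) + dec$b_iou)
  out <- list(logits_sub = logits_sub, conf = conf)
  if (want_grad)
    out$cache <- list(la = la, sa = sa, lb = lb, ca = ca, lc = lc, ml = ml,
                      ld = ld, ci = ci, T3 = T3, Z2 = Z2, m = m, Q = Q,
                      d = d, dec = dec)
  out
}

# Assemble N x upF^2 sub-pixel logits into the (upF*gh) x (upF*gw) mask
# grid (offset o = (b-1)*upF + a lands on rows a::upF, cols b::upF).
assemble_subgrid <- function(Lsub, gh, gw, F) {
  big <- matrix(0, F * gh, F * gw)
  for (o in seq_len(F * F)) {
    a <- ((o - 1L) %% F) + 1L
    b <- ((o - 1L) %/% F) + 1L
    big[seq(a, by = F, length.out = gh),
        seq(b, by = F, length.out = gw)] <- matrix(Lsub[, o], gh, gw)
  }
  big
}

disassemble_subgrid <- function(big, gh, gw, F) {
  Lsub <- matrix(0, gh * gw, F * F)
  for (o in seq_len(F * F)) {
    a <- ((o - 1L) %% F) + 1L
    b <- ((o - 1L) %/% F) + 1L
    Lsub[, o] <- as.numeric(big[seq(a, by = F, length.out = gh),
                                seq(b, by = F, length.out = gw)])
  }
  Lsub
}

# Backward: gradient of the channel's sub-pixel logits w.r.t. the image
# embedding Z and the prompt tokens T0 (frozen weights get no gradients).
decode_channel_bwd <- function(dLsub, cache) {
  dec <- cache$dec; d <- cache$d
  dLsub <- dLsub * dec$logit_scale
  dZ2 <- dLsub %*% t(cache$Q)
  dQ <- crossprod(cache$Z2, dLsub)
  dm <- numeric(d)
  for (o in seq_along(dec$Wsub))
    dm <- dm + as.numeric(crossprod(dec$Wsub[[o]], dQ[, o]))
  dT3 <- matrix(0, nrow(cache$T3), ncol(cache$T3))
  dT3[1, ] <- as.numeric(dec$Wm %*% dm)
  dZ <- dZ2                                   # residual around cross i->t
  gi <- attn_bwd(dZ2, cache$ci$cache)
  dZ <- dZ + layernorm_bwd(gi$dQ, cache$ld$cache)
  dT3 <- dT3 + gi$dK + gi$dV
  dT2 <- dT3 + layernorm_bwd(mlp_bwd(dT3, cache$ml$cache), cache$lc$cache)
  gc <- attn_bwd(dT2, cache$ca$cache)
  dZ <- dZ + gc$dK + gc$dV                    # K input was Z + pos, V was Z
  dT1 <- dT2 + layernorm_bwd(gc$dQ, cache$lb$cache)
  gs <- attn_bwd(dT1, cache$sa$cache)
  dT0 <- dT1 + layernorm_bwd(gs$dQ + gs$dK + gs$dV, cache$la$cache)
  list(dZ = dZ, dT0 = dT0)
}

# Additive local logit bias of interactive point prompts (inference only).
point_bump <- function(points, S, backend) {
  B <- matrix(0, S, S)
  if (is.null(points) || !nrow(points)) return(B)
  xs <- (seq_len(S) - 1)
  for (r in seq_len(nrow(points))) {
    sgn <- if (points$polarity[r] == "foreground") 1 else -1
    dx2 <- (xs - points$x[r])^2
    dy2 <- (xs - points$y[r])^2
    B <- B + sgn * backend$params$point_amp *
      outer(exp(-dy2 / (2 * backend$params$point_sigma^2)),
            exp(-dx2 / (2 * backend$params$point_sigma^2)))
  }
  B
}

#' Decode per-channel probability maps from an image embedding
#'
#' Invokes the frozen mask decoder once per output channel on a shared
#' image embedding, one [prompt_set()] per channel. Grid-resolution mask
#' logits are bilinearly upsampled to crop resolution and passed through a
#' logistic map; interactive point prompts additionally contribute a local
#' additive logit bias on their own channel. The per-channel confidence is
#' the decoder's mask-quality estimate.
#'
#' @param embedding Result of [encode_image()].
#' @param prompts List of [prompt_set()], one per output channel.
#' @param backend The `seg_backend` that produced the embedding.
#' @param crop_size Side length of the decoded crop in pixels.
#' @param want_grad Keep caches for the training backward pass.
#' @return An object of class `channel_prediction`: `probs`
#'   (`crop_size x crop_size x n_channels` array in `[0,1]`) and
#'   `confidence` (one scalar per channel).
#' @export
decode_channel_maps <- function(embedding, prompts, backend, crop_size,
                                want_grad = FALSE) {
  if (!length(prompts)) stop_input("prompt list must not be empty")
  nch <- length(prompts)
  gh <- embedding$gh; gw <- embedding$gw
  F <- backend$params$dec$upF
  Uh <- interp_matrix(crop_size, F * gh, backend$patch_size / F)
  Uw <- interp_matrix(crop_size, F * gw, backend$patch_size / F)
  probs <- array(0, c(crop_size, crop_size, nch))
  conf <- numeric(nch)
  caches <- if (want_grad) vector("list", nch)
  for (ch in seq_len(nch)) {
    ap <- assemble_prompt_tokens(prompts[[ch]], crop_size, backend)
    fw <- decode_channel_fwd(embedding$emb, embedding$pos, ap$T0, backend,
                             want_grad = want_grad)
    Lg <- assemble_subgrid(fw$logits_sub, gh, gw, F)
    full <- Uh %*% Lg %*% t(Uw)
    full <- full + point_bump(prompts[[ch]]$points, crop_size, backend)
    probs[, , ch] <- sigmoid(full)
    conf[ch] <- fw$conf
    if (want_grad) caches[[ch]] <- list(dec = fw$cache, n_desc = ap$n_desc)
  }
  out <- structure(list(probs = probs, confidence = conf),
                   class = "channel_prediction")
  if (want_grad) {
    out$caches <- caches
    out$Uh <- Uh; out$Uw <- Uw; out$gh <- gh; out$gw <- gw; out$upF <- F
  }
  out
}
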