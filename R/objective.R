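#' Loss configuration
#'
#' @param gamma Margin in probability units: a pixel contributes loss on a
#'   channel only while its probability gap to the competing channels is
#'   below `gamma` (default 0.2). Pixels whose gap reaches `gamma` are
#'   confident and are ignored.
#' @param boundary_background_always_present Keep the background and
#'   boundary channels in the active set of every crop (default `TRUE`);
#'   the federated presence rule then applies only to nuclei categories.
#' @param aggregation `"channel_mean"` (mean over each active channel's
#'   contributing pixels, averaged over active channels -- every channel
#'   carries equal weight regardless of how many pixels its class covers;
#'   the default), `"mean"` (one global mean over contributing pixels) or
#'   `"sum"`.
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(gamma = 0.2, boundary_background_always_present = TRUE,
                        aggregation = c("channel_mean", "mean", "sum")) {
  if (gamma < 0 || gamma >= 1) stop_input("gamma must lie in [0, 1)")
  structure(list(gamma = gamma,
                 boundary_background_always_present =
                   boundary_background_always_present,
                 aggregation = match.arg(aggregation)),
            class = "loss_config")
}

# Flatten an (H, W, ch) array to a pixels x channels matrix.
flatten_channels <- function(a) {
  d <- dim(a); matrix(a, d[1] * d[2], d[3])
}

#' Multi-class hinge ambiguity mask
#'
#' For channel `c` at pixel `p`, the probability gap is
#' `probs[c,p] - max_{c' != c} probs[c',p]` where the target of channel `c`
#' is 1, and `max_{c': target=1} probs[c',p] - probs[c,p]` where it is 0.
#' The pixel is ambiguous on that channel (mask 1) iff the gap is strictly
#' below `gamma`; gap ties count as confident.
#'
#' @param probs `H x W x ch` array of per-channel probabilities in `[0,1]`.
#' @param targets A `channel_targets` (see [derive_channel_targets()]) or an
#'   `H x W x ch` binary array.
#' @param gamma Margin, see [loss_config()].
#' @return `H x W x ch` binary (0/1) array of ambiguous pixels.
#' @export
margin_ambiguity_mask <- function(probs, targets, gamma = 0.2) {
  tg <- if (inherits(targets, "channel_targets")) targets$maps else targets
  if (any(probs < 0) || any(probs > 1))
    stop_input("probs must lie in [0, 1]")
  if (!all(dim(probs) == dim(tg))) stop_input("probs/targets shape mismatch")
  P <- flatten_channels(probs)
  Tm <- flatten_channels(tg)
  nch <- ncol(P)
  # per-pixel top-2 over all channels, and max over target channels
  ord1 <- max.col(P, ties.method = "first")
  m1 <- P[cbind(seq_len(nrow(P)), ord1)]
  P2 <- P; P2[cbind(seq_len(nrow(P)), ord1)] <- -Inf
  m2 <- P2[cbind(seq_len(nrow(P)), max.col(P2, ties.method = "first"))]
  Pt <- P; Pt[Tm == 0] <- -Inf
  tmax <- do.call(pmax, c(lapply(seq_len(nch), function(c) Pt[, c]),
                          list(-Inf)))
  gap <- matrix(0, nrow(P), nch)
  for (c in seq_len(nch)) {
    other <- ifelse(ord1 == c, m2, m1)      # best competing channel
    gap[, c] <- ifelse(Tm[, c] == 1, P[, c] - other, tmax - P[, c])
  }
  mask <- (gap < gamma) * 1L
  array(mask, dim(probs))
}

#' Federated multi-class hinge loss
#'
#' Per-channel binary cross-entropy restricted twice: (a) federated class
#' presence -- nuclei-category channels whose category is absent from the
#' crop contribute zero loss and zero gradient, so rare classes never
#' receive spurious negatives from images they do not appear in; (b) the
#' hinge margin -- only ambiguous pixels (see [margin_ambiguity_mask()])
#' contribute, silencing confidently classified pixels.
#'
#' @param probs `H x W x ch` probability array.
#' @param targets A `channel_targets` from [derive_channel_targets()].
#' @param config A [loss_config()].
#' @return List with `loss` (scalar, `>= 0`), `pixel_counts` (contributing
#'   pixels per channel), `contrib_mask` (the combined federated x hinge
#'   mask) and `n_contrib` (total contributing pixels).
#' @export
federated_hinge_loss <- function(probs, targets, config = loss_config()) {
  tg <- targets$maps
  nch <- dim(tg)[3]
  C <- nch - 2L
  active <- rep(FALSE, nch)
  active[targets$present_classes] <- TRUE
  if (config$boundary_background_always_present) active[c(C + 1L, C + 2L)] <- TRUE
  if (!any(active)) stop_input("degenerate batch: empty active channel set")
  amb <- margin_ambiguity_mask(probs, targets, config$gamma)
  for (c in which(!active)) amb[, , c] <- 0L
  P <- flatten_channels(probs)
  Tm <- flatten_channels(tg)
  M <- flatten_channels(amb)
  eps <- 1e-12
  bce <- -(Tm * log(pmax(P, eps)) + (1 - Tm) * log(pmax(1 - P, eps)))
  ch_tot <- colSums(bce * M)
  counts <- colSums(M)
  n <- sum(counts)
  loss <- switch(config$aggregation,
    channel_mean = if (sum(active) > 0)
      sum(ifelse(counts > 0, ch_tot / pmax(counts, 1), 0)) / sum(active)
    else 0,
    mean = if (n > 0) sum(ch_tot) / n else 0,
    sum = sum(ch_tot)
  )
  list(loss = loss, pixel_counts = counts, contrib_mask = amb, n_contrib = n,
       n_active = sum(active))
}
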