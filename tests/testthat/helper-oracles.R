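# Brute-force oracles, kept deliberately independent of the package's
# implementation paths: per-pixel neighbourhood checks, recursive flood
# fill, exhaustive assignment enumeration, and a direct re-derivation of
# the interpolated-AP protocol.

# Boundary oracle: pixel is boundary iff some pixel within chessboard
# distance <= thickness (or the outside of the image) carries a different
# label.
oracle_boundary <- function(m, thickness = 1L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (m[i, j] == 0L) next
    lab <- m[i, j]
    isb <- FALSE
    for (di in -thickness:thickness) for (dj in -thickness:thickness) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W) { isb <- TRUE }
      else if (m[ii, jj] != lab) isb <- TRUE
    }
    if (isb) out[i, j] <- 1L
  }
  out
}

# 8-connected components by recursive flood fill (stack-based).
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nid <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    nid <- nid + 1L
    stack <- list(c(i, j)); lab[i, j] <- nid
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- nid
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

oracle_iou <- function(maskA, maskB) {
  inter <- sum(maskA & maskB)
  uni <- sum(maskA | maskB)
  if (uni == 0) return(0)
  inter / uni
}

# Exhaustive optimal one-to-one assignment: maximum number of matched
# (IoU > thr, same class) pairs, enumerated over all injections of the
# smaller side into the larger.
oracle_match_counts <- function(pred, gt, thr = 0.5) {
  pids <- as.integer(names(pred$classes))
  gids <- as.integer(names(gt$classes))
  iou <- matrix(0, length(pids), length(gids))
  ok <- matrix(FALSE, length(pids), length(gids))
  for (a in seq_along(pids)) for (b in seq_along(gids)) {
    v <- oracle_iou(pred$instance_map == pids[a], gt$instance_map == gids[b])
    iou[a, b] <- v
    ok[a, b] <- v > thr &&
      pred$classes[[as.character(pids[a])]] == gt$classes[[as.character(gids[b])]]
  }
  np <- length(pids); ng <- length(gids)
  best <- 0L
  if (np && ng) {
    perm_of <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (k in seq_along(v))
        for (p in perm_of(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
      out
    }
    if (np <= ng) {
      for (p in perm_of(seq_len(ng))) {
        sel <- p[seq_len(np)]
        best <- max(best, sum(ok[cbind(seq_len(np), sel)]))
      }
    } else {
      for (p in perm_of(seq_len(np))) {
        sel <- p[seq_len(ng)]
        best <- max(best, sum(ok[cbind(sel, seq_len(ng))]))
      }
    }
  }
  list(tp = best, fp = np - best, fn = ng - best)
}

# Independent interpolated-AP oracle: per threshold, sequential matching in
# score order, then precision at 101 recall points computed directly from
# ranked prefixes (no envelope recursion).
oracle_ap <- function(preds, gts, category, thr) {
  det <- list()
  n_gt <- 0L
  for (i in seq_along(preds)) {
    p <- preds[[i]]; g <- gts[[i]]
    gids <- as.integer(names(g$classes)[g$classes == category])
    n_gt <- n_gt + length(gids)
    pids <- as.integer(names(p$classes)[p$classes == category])
    for (id in pids)
      det[[length(det) + 1L]] <- list(img = i, id = id,
                                      score = p$scores[[as.character(id)]])
  }
  if (n_gt == 0L) return(NA_real_)
  if (!length(det)) return(0)
  det <- det[order(-vapply(det, function(d) d$score, 0))]
  taken <- lapply(seq_along(gts), function(i) integer())
  tp_seq <- logical(length(det))
  for (k in seq_along(det)) {
    d <- det[[k]]
    g <- gts[[d$img]]
    gids <- as.integer(names(g$classes)[g$classes == category])
    gids <- setdiff(gids, taken[[d$img]])
    if (!length(gids)) next
    pm <- preds[[d$img]]$instance_map == d$id
    ious <- vapply(gids, function(gid) oracle_iou(pm, g$instance_map == gid), 0)
    if (max(ious) >= thr) {
      tp_seq[k] <- TRUE
      taken[[d$img]] <- c(taken[[d$img]], gids[which.max(ious)])
    }
  }
  prec <- cumsum(tp_seq) / seq_along(tp_seq)
  rec <- cumsum(tp_seq) / n_gt
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    sel <- rec >= r
    if (!any(sel)) 0 else max(prec[sel])
  }, 0))
}

oracle_map <- function(preds, gts, categories,
                       thrs = seq(0.5, 0.95, by = 0.05)) {
  ap <- vapply(seq_len(categories$C), function(c)
    mean(vapply(thrs, function(t) oracle_ap(preds, gts, c, t), 0)), 0)
  list(ap_per_category = ap, mAP = mean(ap, na.rm = TRUE))
}
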