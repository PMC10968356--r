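# Pairwise IoUs between two instance-label maps, as a data.frame of
# overlapping (pred_id, gt_id, iou) triples plus per-instance areas.
pairwise_ious <- function(pred_map, gt_map) {
  if (!all(dim(pred_map) == dim(gt_map)))
    stop_input("prediction and ground-truth dimensions disagree")
  p <- as.integer(pred_map); g <- as.integer(gt_map)
  pa <- tabulate(p[p > 0L])
  ga <- tabulate(g[g > 0L])
  sel <- p > 0L & g > 0L
  if (!any(sel)) {
    return(list(pairs = data.frame(pred_id = integer(), gt_id = integer(),
                                   iou = numeric()),
                pred_area = pa, gt_area = ga))
  }
  key <- paste(p[sel], g[sel])
  tab <- table(key)
  sp <- strsplit(names(tab), " ", fixed = TRUE)
  pid <- vapply(sp, function(x) as.integer(x[1]), 0L)
  gid <- vapply(sp, function(x) as.integer(x[2]), 0L)
  inter <- as.integer(tab)
  iou <- inter / (pa[pid] + ga[gid] - inter)
  list(pairs = data.frame(pred_id = pid, gt_id = gid, iou = iou),
       pred_area = pa, gt_area = ga)
}

#' Match predicted to ground-truth instances one-to-one
#'
#' Candidate pairs are those with IoU strictly above `iou_threshold` (and
#' equal category when `class_aware`); pairs are taken greedily by
#' descending IoU (ties toward the lower ground-truth id), each prediction
#' and each ground-truth instance matched at most once. Unmatched
#' predictions are false positives, unmatched ground-truth instances false
#' negatives.
#'
#' @param pred An [instance_prediction()].
#' @param gt A [nuclei_scene()] (or another `instance_prediction` acting as
#'   ground truth).
#' @param iou_threshold Minimum IoU for a candidate pair (default 0.5).
#' @param class_aware Require equal category for a match (default `TRUE`).
#' @return An object of class `match_result`: `pairs`
#'   (pred_id, gt_id, iou), `fp_ids`, `fn_ids`, and `per_category`
#'   (data.frame category, tp, fp, fn).
#' @export
match_objects <- function(pred, gt, iou_threshold = 0.5, class_aware = TRUE) {
  cats <- pred$categories
  pi <- pairwise_ious(pred$instance_map, gt$instance_map)
  cand <- pi$pairs[pi$pairs$iou > iou_threshold, , drop = FALSE]
  pcls <- pred$classes; gcls <- gt$classes
  if (class_aware && nrow(cand)) {
    same <- pcls[as.character(cand$pred_id)] == gcls[as.character(cand$gt_id)]
    cand <- cand[same, , drop = FALSE]
  }
  cand <- cand[order(-cand$iou, cand$gt_id), , drop = FALSE]
  used_p <- character(); used_g <- character()
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    pid <- as.character(cand$pred_id[r]); gid <- as.character(cand$gt_id[r])
    if (pid %in% used_p || gid %in% used_g) next
    keep[r] <- TRUE
    used_p <- c(used_p, pid); used_g <- c(used_g, gid)
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  all_p <- as.integer(names(pcls)); all_g <- as.integer(names(gcls))
  fp <- setdiff(all_p, pairs$pred_id)
  fn <- setdiff(all_g, pairs$gt_id)
  per_cat <- data.frame(
    category = seq_len(cats$C),
    tp = vapply(seq_len(cats$C), function(c)
      sum(gcls[as.character(pairs$gt_id)] == c), 0L),
    fp = vapply(seq_len(cats$C), function(c)
      sum(pcls[as.character(fp)] == c), 0L),
    fn = vapply(seq_len(cats$C), function(c)
      sum(gcls[as.character(fn)] == c), 0L)
  )
  structure(list(pairs = pairs, fp_ids = fp, fn_ids = fn,
                 per_category = per_cat, categories = cats),
            class = "match_result")
}

#' Object-level detection F1 per category
#'
#' `F1 = TP / (TP + (FP + FN) / 2)` per category; categories with neither
#' ground-truth nor predicted instances are excluded from the mean (they
#' carry no evidence either way on a small tile).
#'
#' @param match A [match_objects()] result, or a list of them (counts are
#'   pooled across scenes before computing F1).
#' @param categories A [category_set()].
#' @return List with `per_category` (named numeric, `NA` for excluded
#'   categories) and `mean`.
#' @export
object_f1_scores <- function(match, categories = NULL) {
  if (inherits(match, "match_result")) match <- list(match)
  cats <- categories %||% match[[1]]$categories
  counts <- Reduce(`+`, lapply(match, function(m)
    as.matrix(m$per_category[, c("tp", "fp", "fn")])))
  f1 <- rep(NA_real_, cats$C)
  for (c in seq_len(cats$C)) {
    tp <- counts[c, "tp"]; fp <- counts[c, "fp"]; fn <- counts[c, "fn"]
    if (tp + fp + fn == 0) next
    f1[c] <- tp / (tp + 0.5 * (fp + fn))
  }
  names(f1) <- cats$names
  list(per_category = f1, mean = mean(f1, na.rm = TRUE))
}

# 101-point interpolated average precision from a scored TP/FP sequence.
interp_ap <- function(is_tp, scores, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(is_tp)) return(0)
  ord <- order(-scores)
  tp <- cumsum(is_tp[ord]); fp <- cumsum(!is_tp[ord])
  prec <- tp / (tp + fp)
  rec <- tp / n_gt
  # precision envelope, then 101 evenly spaced recall points
  for (i in rev(seq_len(length(prec) - 1L)))
    prec[i] <- max(prec[i], prec[i + 1L])
  rpts <- seq(0, 1, by = 0.01)
  idx <- findInterval(rpts, rec, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(prec), prec[idx], 0)
  mean(p)
}

#' COCO-style instance-segmentation mAP
#'
#' Per category and per IoU threshold in `{0.50, 0.55, ..., 0.95}`,
#' predictions pooled over all scenes are ranked by score and greedily
#' matched (each prediction to the highest-IoU unmatched ground-truth
#' instance of its category with IoU at or above the threshold); the
#' 101-point interpolated area under the precision-recall curve gives the
#' AP at that threshold. `AP_k` averages over the 10 thresholds, `mAP`
#' averages `AP_k` over categories with ground truth, and `mAP50` averages
#' the per-category AP at threshold 0.50.
#'
#' @param preds List of [instance_prediction()] (scored), one per scene.
#' @param gts List of [nuclei_scene()] ground truths, parallel to `preds`.
#' @param categories A [category_set()].
#' @param iou_thresholds Vector of IoU thresholds.
#' @return List with `ap_per_category` (named; `NA` where a category has no
#'   ground truth), `mAP`, `mAP50`.
#' @export
coco_map <- function(preds, gts, categories = category_set(),
                     iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (length(preds) != length(gts)) stop_input("preds/gts length mismatch")
  for (p in preds)
    if (anyNA(p$scores)) stop_input("every prediction needs a score")
  C <- categories$C
  per_img <- lapply(seq_along(preds), function(i)
    pairwise_ious(preds[[i]]$instance_map, gts[[i]]$instance_map))
  ap_cat <- rep(NA_real_, C); ap50_cat <- rep(NA_real_, C)
  for (c in seq_len(C)) {
    dets <- list(); n_gt <- 0L
    for (i in seq_along(preds)) {
      pids <- as.integer(names(preds[[i]]$classes)[preds[[i]]$classes == c])
      gids <- as.integer(names(gts[[i]]$classes)[gts[[i]]$classes == c])
      n_gt <- n_gt + length(gids)
      if (!length(pids)) next
      dets[[length(dets) + 1L]] <- list(
        img = i, pids = pids,
        scores = as.numeric(preds[[i]]$scores[as.character(pids)]),
        gids = gids, ious = per_img[[i]]$pairs
      )
    }
    if (n_gt == 0L) next
    aps <- vapply(iou_thresholds, function(thr) {
      is_tp <- numeric(); sc <- numeric()
      for (d in dets) {
        matched <- rep(FALSE, length(d$gids))
        ord <- order(-d$scores)
        tp_local <- logical(length(d$pids))
        for (j in ord) {
          pid <- d$pids[j]
          cand <- d$ious[d$ious$pred_id == pid &
                           d$ious$gt_id %in% d$gids[!matched] &
                           d$ious$iou >= thr, , drop = FALSE]
          if (nrow(cand)) {
            best <- cand$gt_id[which.max(cand$iou)]
            matched[match(best, d$gids)] <- TRUE
            tp_local[j] <- TRUE
          }
        }
        is_tp <- c(is_tp, tp_local)
        sc <- c(sc, d$scores)
      }
      interp_ap(as.logical(is_tp), sc, n_gt)
    }, 0)
    ap_cat[c] <- mean(aps)
    ap50_cat[c] <- aps[1]
  }
  names(ap_cat) <- categories$names
  names(ap50_cat) <- categories$names
  list(ap_per_category = ap_cat,
       mAP = mean(ap_cat, na.rm = TRUE),
       mAP50 = mean(ap50_cat, na.rm = TRUE))
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether the differences `a - b` come from a distribution whose
#' median is greater than zero, with the standard zero-discard and mid-rank
#' tie conventions.
#'
#' @param a,b Paired score vectors of equal length (>= 5).
#' @return The one-sided p-value. Exact (full enumeration of the signed-rank
#'   distribution with mid-ranks) for up to 20 nonzero differences; the
#'   standard normal approximation beyond that.
#' @export
wilcoxon_greater <- function(a, b) {
  if (length(a) != length(b)) stop_input("paired vectors differ in length")
  if (length(a) < 5L) stop_input("need at least 5 pairs")
  d <- a - b
  if (all(d == 0)) stop_input("all paired differences are zero; test undefined")
  d <- d[d != 0]                      # standard zero-discard convention
  n <- length(d)
  r <- rank(abs(d))                   # mid-ranks under ties
  W <- sum(r[d > 0])
  if (n <= 20L) {
    # exact null distribution of W by convolution over sign patterns;
    # doubling the ranks keeps mid-ranks (x.5) on an integer lattice
    r2 <- as.integer(round(2 * r))
    counts <- numeric(sum(r2) + 1L)   # counts[w + 1] = #patterns with 2W = w
    counts[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), counts[seq_len(length(counts) - rk)])
      counts <- counts + shifted
    }
    p <- sum(counts[seq.int(round(2 * W) + 1L, length(counts))]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- stats::pnorm(W - 0.5, mean = mu, sd = sqrt(sig2),
                      lower.tail = FALSE)
  }
  p
}

#' Full evaluation report
#'
#' Pools object-level F1 counts across scenes and computes the COCO-style
#' mAP on the same predictions.
#'
#' @param preds List of [instance_prediction()].
#' @param gts Parallel list of [nuclei_scene()].
#' @param categories A [category_set()].
#' @param iou_threshold F1 matching threshold (default 0.5).
#' @return Object of class `eval_report` with `f1_per_category`, `f1_mean`,
#'   `ap_per_category`, `mAP`, `mAP50`, `N` (category count).
#' @export
eval_report <- function(preds, gts, categories = category_set(),
                        iou_threshold = 0.5) {
  matches <- lapply(seq_along(preds), function(i)
    match_objects(preds[[i]], gts[[i]], iou_threshold = iou_threshold))
  f1 <- object_f1_scores(matches, categories)
  ap <- coco_map(preds, gts, categories)
  structure(list(f1_per_category = f1$per_category, f1_mean = f1$mean,
                 ap_per_category = ap$ap_per_category, mAP = ap$mAP,
                 mAP50 = ap$mAP50, N = categories$C),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n  mean object F1:", round(x$f1_mean, 4),
      "\n  mAP:", round(x$mAP, 4), " mAP50:", round(x$mAP50, 4), "\n")
  cat("  per-category F1: ",
      paste(names(x$f1_per_category), round(x$f1_per_category, 3),
            sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An [eval_report()].
#' @param path Output file.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
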