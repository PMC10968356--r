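test_that("object matching: exact, competing and sub-threshold cases", {
  cats <- tiny_cats(2)
  # perfect prediction: 5 instances, all IoU 1
  set.seed(3)
  fx <- random_fixture(100, n_cells = 4L)
  gt <- fx$gt
  ident <- instance_prediction(gt$instance_map, gt$classes,
                               stats::setNames(rep(1, length(gt$classes)),
                                               names(gt$classes)),
                               gt$categories)
  m <- match_objects(ident, gt)
  expect_equal(nrow(m$pairs), length(gt$classes))
  expect_true(all(m$pairs$iou == 1))
  expect_length(m$fp_ids, 0); expect_length(m$fn_ids, 0)

  # one gt square, two competing predictions: the higher-IoU one wins
  gm <- matrix(0L, 20, 20); gm[5:14, 5:14] <- 1L          # 10x10 gt
  pm <- matrix(0L, 20, 20)
  pm[5:14, 5:12] <- 1L                                    # IoU 80/100 = 0.8
  pm[15:18, 5:12] <- 2L                                   # disjoint, IoU 0
  g <- nuclei_scene(array(0, c(20, 20, 3)), gm,
                    stats::setNames(1L, "1"), cats)
  p <- toy_prediction(pm, c("1" = 1L, "2" = 1L), cats = cats)
  m2 <- match_objects(p, g, iou_threshold = 0.5)
  expect_equal(m2$pairs$pred_id, 1L)
  expect_equal(m2$fp_ids, 2L)
  expect_length(m2$fn_ids, 0)
  expect_equal(m2$per_category$tp[1], 1L)
  expect_equal(m2$per_category$fp[1], 1L)

  # 2x3 rectangles overlapping in a 2x1 strip: IoU 2/10 = 0.2, no match
  gm3 <- matrix(0L, 10, 10); gm3[3:4, 3:5] <- 1L
  pm3 <- matrix(0L, 10, 10); pm3[3:4, 5:7] <- 1L
  g3 <- nuclei_scene(array(0, c(10, 10, 3)), gm3, stats::setNames(1L, "1"),
                     cats)
  p3 <- toy_prediction(pm3, c("1" = 1L), cats = cats)
  raw <- nucleiprompt:::pairwise_ious(pm3, gm3)
  expect_equal(raw$pairs$iou, 0.2)
  m3 <- match_objects(p3, g3, iou_threshold = 0.5)
  expect_equal(nrow(m3$pairs), 0L)
  expect_equal(m3$fp_ids, 1L)
  expect_equal(m3$fn_ids, 1L)

  expect_error(
    match_objects(toy_prediction(matrix(0L, 4, 4),
                                 stats::setNames(integer(), character()),
                                 cats = cats), g3), "disagree")
})

test_that("greedy matching equals the exhaustive assignment oracle", {
  for (seed in 1:25) {
    fx <- random_fixture(seed)
    m <- match_objects(fx$pred, fx$gt, iou_threshold = 0.5)
    o <- oracle_match_counts(fx$pred, fx$gt, thr = 0.5)
    expect_equal(nrow(m$pairs), o$tp)
    expect_equal(length(m$fp_ids), o$fp)
    expect_equal(length(m$fn_ids), o$fn)
    # count identities per category
    expect_equal(sum(m$per_category$tp) + sum(m$per_category$fn),
                 length(fx$gt$classes))
    expect_equal(sum(m$per_category$tp) + sum(m$per_category$fp),
                 length(fx$pred$classes))
  }
})

test_that("object F1 follows TP / (TP + (FP+FN)/2) with vacuous classes excluded", {
  cats <- tiny_cats(3)
  counts <- data.frame(category = 1:3, tp = c(3L, 0L, 0L),
                       fp = c(1L, 2L, 0L), fn = c(2L, 1L, 0L))
  m <- structure(list(per_category = counts, categories = cats),
                 class = "match_result")
  f1 <- object_f1_scores(m, cats)
  expect_equal(unname(f1$per_category[1]), 3 / (3 + 0.5 * 3), tolerance = 1e-12)
  expect_equal(unname(f1$per_category[2]), 0)
  expect_true(is.na(f1$per_category[3]))           # no gt, no pred: excluded
  expect_equal(f1$mean, mean(c(2 / 3, 0)))
})

test_that("coco mAP: exact masks, partial IoU and empty predictions", {
  cats <- tiny_cats(1)
  gm <- matrix(0L, 20, 20); gm[5:14, 5:14] <- 1L
  gt <- nuclei_scene(array(0, c(20, 20, 3)), gm, stats::setNames(1L, "1"),
                     cats)
  exact <- toy_prediction(gm, c("1" = 1L), c("1" = 0.9), cats)
  r <- coco_map(list(exact), list(gt), cats)
  expect_equal(r$mAP, 1.0)
  expect_equal(r$mAP50, 1.0)

  # a prediction with IoU exactly 0.6 earns AP 1 at thresholds
  # {0.50, 0.55, 0.60} and 0 beyond -> AP_k = 3/10
  pm2 <- matrix(0L, 20, 20); pm2[5:14, 5:10] <- 1L   # IoU 60/100 = 0.6
  expect_equal(nucleiprompt:::pairwise_ious(pm2, gm)$pairs$iou, 0.6)
  pr <- toy_prediction(pm2, c("1" = 1L), c("1" = 0.8), cats)
  r2 <- coco_map(list(pr), list(gt), cats)
  expect_equal(unname(r2$ap_per_category[1]), 3 / 10)
  expect_equal(r2$mAP50, 1.0)

  # no predictions at all
  empty <- instance_prediction(matrix(0L, 20, 20),
                               stats::setNames(integer(), character()),
                               stats::setNames(numeric(), character()), cats)
  r3 <- coco_map(list(empty), list(gt), cats)
  expect_equal(r3$mAP, 0)
})

test_that("coco mAP agrees with the independent protocol oracle", {
  cats <- tiny_cats(3)
  for (seed in 1:12) {
    fxs <- lapply(seed * 10 + 1:2, random_fixture)
    preds <- lapply(fxs, `[[`, "pred")
    gts <- lapply(fxs, `[[`, "gt")
    r <- coco_map(preds, gts, cats)
    o <- oracle_map(preds, gts, cats)
    expect_equal(r$ap_per_category, o$ap_per_category,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(r$mAP, o$mAP, tolerance = 1e-9)
  }
})

test_that("one-sided Wilcoxon signed-rank behaves per the exact distribution", {
  a <- c(2, 3, 1, 4, 5, 2, 3, 1, 4, 5)
  expect_gte(wilcoxon_greater(a, a + 0.01), 0.5)
  # all positive differences, n = 10, no ties: p = 1/2^10
  b <- a + 1
  expect_equal(wilcoxon_greater(b, a), 1 / 1024, tolerance = 1e-12)
  # antisymmetry up to the discrete atom
  p_fwd <- wilcoxon_greater(b, a)
  p_rev <- wilcoxon_greater(a, b)
  expect_gte(p_rev, 1 - p_fwd - 1e-9)
  # agrees with the reference exact test when differences are untied
  set.seed(9)
  x <- rnorm(12); y <- x + rnorm(12, 0.3)
  expect_equal(wilcoxon_greater(y, x),
               stats::wilcox.test(y, x, paired = TRUE, exact = TRUE,
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(wilcoxon_greater(a, a), "zero")
  expect_error(wilcoxon_greater(1:3, 4:6), "at least 5")
  expect_error(wilcoxon_greater(1:5, 1:6), "length")
})

test_that("evaluation reports stay in [0,1] and are permutation invariant", {
  cats <- tiny_cats(3)
  fxs <- lapply(c(501, 502), random_fixture)
  preds <- lapply(fxs, `[[`, "pred")
  gts <- lapply(fxs, `[[`, "gt")
  rep <- eval_report(preds, gts, cats)
  vals <- c(rep$f1_mean, rep$mAP, rep$mAP50,
            rep$f1_per_category[!is.na(rep$f1_per_category)],
            rep$ap_per_category[!is.na(rep$ap_per_category)])
  expect_true(all(vals >= 0 & vals <= 1))
  # renumbering prediction ids changes nothing
  fx <- fxs[[1]]
  pm <- fx$pred$instance_map
  ids <- sort(unique(pm[pm > 0]))
  perm <- rev(seq_along(ids))
  pm2 <- pm; pm2[pm > 0] <- perm[match(pm[pm > 0], ids)]
  nm2 <- as.character(perm)
  pred2 <- instance_prediction(
    pm2,
    stats::setNames(as.integer(fx$pred$classes[as.character(ids)]), nm2),
    stats::setNames(as.numeric(fx$pred$scores[as.character(ids)]), nm2),
    cats)
  r1 <- eval_report(list(fx$pred), list(fx$gt), cats)
  r2 <- eval_report(list(pred2), list(fx$gt), cats)
  expect_equal(r1$f1_mean, r2$f1_mean)
  expect_equal(r1$mAP, r2$mAP)
})
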