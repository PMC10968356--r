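test_that("sliding-window plans match hand enumeration, with edge clamping", {
  p <- plan_sliding_windows(512L, 512L)
  expect_equal(nrow(p), 9L)
  expect_equal(sort(unique(p$x0)), c(0L, 128L, 256L))
  expect_equal(sort(unique(p$y0)), c(0L, 128L, 256L))

  p1 <- plan_sliding_windows(256L, 256L)
  expect_equal(nrow(p1), 1L)
  expect_equal(c(p1$x0, p1$y0), c(0L, 0L))
  expect_equal(c(p1$cx0, p1$cx1, p1$cy0, p1$cy1), c(0L, 256L, 0L, 256L))

  p2 <- plan_sliding_windows(300L, 300L)
  expect_equal(nrow(p2), 4L)
  expect_equal(sort(unique(p2$x0)), c(0L, 44L))

  # interior windows carry the [x0 + size/4, x0 + 3 size/4) central region
  p3 <- plan_sliding_windows(640L, 640L)
  mid <- p3[p3$x0 == 256L & p3$y0 == 256L, ]
  expect_equal(c(mid$cx0, mid$cx1), c(256L + 64L, 256L + 192L))

  expect_error(plan_sliding_windows(200L, 300L), "smaller")
})

test_that("central regions partition every tested image exactly once", {
  for (dims in list(c(256L, 256L), c(300L, 300L), c(512L, 512L),
                    c(384L, 700L), c(1000L, 1000L))) {
    p <- plan_sliding_windows(dims[1], dims[2])
    covx <- integer(dims[2]); covy <- integer(dims[1])
    for (r in seq_len(nrow(p))) {
      covx[(p$cx0[r] + 1):p$cx1[r]] <- covx[(p$cx0[r] + 1):p$cx1[r]] + 1L
      covy[(p$cy0[r] + 1):p$cy1[r]] <- covy[(p$cy0[r] + 1):p$cy1[r]] + 1L
    }
    # each axis interval is covered by the right number of windows in the
    # other axis, so per-pixel coverage = covx * covy / windows must be 1
    nx <- length(unique(p$x0)); ny <- length(unique(p$y0))
    expect_true(all(covx == ny))
    expect_true(all(covy == nx))
  }
})

test_that("instance decoding splits touching nuclei and reabsorbs the rim", {
  cats <- tiny_cats(2)
  # two 5x5 same-class squares separated by a 1-pixel boundary-argmax line
  H <- 13L; W <- 9L
  probs <- array(0, c(H, W, 4))
  probs[, , 3] <- 1                      # background wins by default
  probs[2:6, 3:7, 1] <- 0; probs[2:6, 3:7, 3] <- 0; probs[2:6, 3:7, 1] <- 1
  probs[8:12, 3:7, 1] <- 1; probs[8:12, 3:7, 3] <- 0
  probs[7, 3:7, ] <- 0; probs[7, 3:7, 4] <- 1   # boundary line
  pred <- decode_instances(probs, cats, min_area = 5L)
  expect_length(pred$classes, 2L)
  expect_true(all(pred$classes == 1L))
  # every boundary-line pixel is reabsorbed into an instance; with equal
  # component areas the documented tie rule sends them to the lower id
  expect_true(all(pred$instance_map[7, 3:7] > 0L))
  expect_true(all(pred$instance_map[7, 3:7] == 1L))
  # with unequal areas the larger component claims the contested rim
  probsU <- array(0, c(15, 9, 4)); probsU[, , 3] <- 1
  probsU[2:6, 3:7, 3] <- 0; probsU[2:6, 3:7, 1] <- 1        # 5x5
  probsU[8:14, 2:8, 3] <- 0; probsU[8:14, 2:8, 1] <- 1      # 7x7
  probsU[7, 3:7, ] <- 0; probsU[7, 3:7, 4] <- 1             # boundary line
  predU <- decode_instances(probsU, cats, min_area = 5L)
  big <- names(which.max(table(predU$instance_map[predU$instance_map > 0])))
  expect_true(all(predU$instance_map[7, 3:7] == as.integer(big)))

  # single blob with probability 1: one instance, score 1
  probs1 <- array(0, c(10, 10, 4)); probs1[, , 3] <- 1
  probs1[3:8, 3:8, ] <- 0; probs1[3:8, 3:8, 2] <- 1
  p1 <- decode_instances(probs1, cats, min_area = 5L)
  expect_length(p1$classes, 1L)
  expect_equal(unname(p1$scores[["1"]]), 1.0)
  expect_equal(unname(p1$classes[["1"]]), 2L)

  # blobs below min_area are discarded
  p2 <- decode_instances(probs1, cats, min_area = 50L)
  expect_length(p2$classes, 0L)
})

test_that("instance decoding equals the flood-fill oracle on small maps", {
  set.seed(31)
  cats <- tiny_cats(2)
  for (rep in 1:12) {
    H <- 24L; W <- 24L
    probs <- array(0, c(H, W, 4))
    probs[, , 3] <- 0.9
    # scatter a few rectangles of the two classes
    for (k in 1:3) {
      i <- sample(1:(H - 6), 1); j <- sample(1:(W - 6), 1)
      sz <- sample(3:6, 1); cls <- sample(1:2, 1)
      probs[i:(i + sz), j:(j + sz), ] <- 0
      probs[i:(i + sz), j:(j + sz), cls] <- 1
    }
    pred <- decode_instances(probs, cats, min_area = 4L)
    # oracle: per class, flood-fill the argmax map, drop small components
    arg <- apply(probs, c(1, 2), which.max)
    n_expected <- 0L
    for (cls in 1:2) {
      lab <- oracle_components(arg == cls)
      if (max(lab) > 0)
        n_expected <- n_expected +
          sum(tabulate(lab[lab > 0]) >= 4L)
    }
    expect_length(pred$classes, n_expected)
    # with no boundary activations, predicted pixels stay inside the
    # nuclei-argmax region
    nuc <- arg <= 2
    keep <- pred$instance_map > 0
    expect_equal(sum(keep & !nuc), 0)
  }
})

test_that("stitching keeps each nucleus exactly once and prefers high scores", {
  cats <- tiny_cats(1)
  # two crops with central regions [0,192) and [192,384) on x
  specs <- plan_sliding_windows(256L, 384L, size = 256L, step = 128L)
  m1 <- matrix(0L, 256, 256); m1[100:110, 100:110] <- 1L   # centroid x=104
  m2 <- matrix(0L, 256, 256); m2[100:110, 150:160] <- 1L   # x=128+154=282
  pr1 <- toy_prediction(m1, c("1" = 1L), c("1" = 0.9), cats)
  pr2 <- toy_prediction(m2, c("1" = 1L), c("1" = 0.8), cats)
  crops <- list(list(spec = specs[1, ], pred = pr1),
                list(spec = specs[2, ], pred = pr2))
  st <- stitch_predictions(crops, 256L, 384L, cats)
  expect_length(st$classes, 2L)
  expect_equal(sum(st$instance_map > 0), 11 * 11 * 2)

  # an instance outside its crop's central region is dropped
  m3 <- matrix(0L, 256, 256); m3[10:20, 200:210] <- 1L     # x~205 >= 192
  crops2 <- list(list(spec = specs[1, ],
                      pred = toy_prediction(m3, c("1" = 1L), cats = cats)))
  st2 <- stitch_predictions(crops2, 256L, 384L, cats)
  expect_length(st2$classes, 0L)

  # empty crops give an empty map
  st3 <- stitch_predictions(list(), 64L, 64L, cats)
  expect_equal(sum(st3$instance_map), 0)
})

test_that("stitching is conservative and idempotent on generated scenes", {
  # decode ground-truth channel maps through the instance decoder per crop:
  # every nucleus whose centroid is interior must appear exactly once
  cats <- category_set()
  simc <- sim_config(H = 256L, W = 256L, n_nuclei = 30L)
  sc <- generate_scene(simc, seed = 123)
  tg <- derive_channel_targets(sc)
  plan <- plan_sliding_windows(256L, 256L, size = 128L, step = 64L)
  crops <- lapply(seq_len(nrow(plan)), function(r) {
    spec <- plan[r, ]
    sub <- tg$maps[(spec$y0 + 1):(spec$y0 + 128),
                   (spec$x0 + 1):(spec$x0 + 128), , drop = FALSE]
    list(spec = spec, pred = decode_instances(sub + 0.0, cats, min_area = 5L))
  })
  st <- stitch_predictions(crops, 256L, 256L, cats)
  expect_equal(length(st$classes), length(sc$classes))
  # classes preserved per centroid ownership
  expect_equal(sort(table(factor(st$classes, 1:6))),
               sort(table(factor(sc$classes, 1:6))))
  # idempotence: re-cropping the stitched map and stitching again
  crops2 <- lapply(seq_len(nrow(plan)), function(r) {
    spec <- plan[r, ]
    m <- st$instance_map[(spec$y0 + 1):(spec$y0 + 128),
                         (spec$x0 + 1):(spec$x0 + 128), drop = FALSE]
    ids <- sort(unique(as.integer(m[m > 0])))
    loc <- matrix(0L, 128, 128)
    loc[m > 0] <- match(m[m > 0], ids)
    nm <- as.character(seq_along(ids))
    list(spec = spec,
         pred = instance_prediction(
           loc, stats::setNames(st$classes[as.character(ids)], nm),
           stats::setNames(st$scores[as.character(ids)], nm), cats))
  })
  st2 <- stitch_predictions(crops2, 256L, 256L, cats)
  # same instance pixel sets (ids may be renumbered)
  expect_equal(sum(st2$instance_map > 0), sum(st$instance_map > 0))
  expect_equal(length(st2$classes), length(st$classes))
  tab1 <- table(st$instance_map[st$instance_map > 0])
  tab2 <- table(st2$instance_map[st2$instance_map > 0])
  expect_equal(sort(as.integer(tab1)), sort(as.integer(tab2)))
})

test_that("refinement with zero rounds is the identity", {
  cats <- tiny_cats(2)
  model <- tiny_model(cats, K = 2L, L = 0L, adapter = FALSE)
  simc <- sim_config(H = 64L, W = 64L, n_nuclei = 4L,
                     class_proportions = c(a = 0.5, b = 0.5),
                     categories = cats)
  sc <- generate_scene(simc, seed = 9)
  out <- refine_with_points(sc$image, model, sc, rounds = 0L, window = 64L)
  base <- predict_scene(sc$image, model, window = 64L)
  expect_identical(out$prediction$instance_map, base$instance_map)
  expect_equal(nrow(out$report), 1L)
  expect_error(refine_with_points(sc$image, model, sc, rounds = -1L), ">= 0")
})
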