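mk_targets <- function(maps, present) {
  structure(list(maps = maps, present_classes = present),
            class = "channel_targets")
}

test_that("margin mask silences confident pixels and keeps ambiguous ones", {
  # 1-pixel image, 3 channels (1 nuclei class + bg + boundary)
  probs <- array(c(0.9, 0.1, 0.05), c(1, 1, 3))
  tg <- array(c(1, 0, 0), c(1, 1, 3))
  m <- margin_ambiguity_mask(probs, tg, gamma = 0.2)
  expect_equal(m[1, 1, 1], 0)        # gap 0.8 >= gamma: confident, ignored

  probs2 <- array(c(0.55, 0.45, 0.05), c(1, 1, 3))
  m2 <- margin_ambiguity_mask(probs2, tg, gamma = 0.2)
  expect_equal(m2[1, 1, 1], 1)       # gap 0.10 < gamma: ambiguous

  # gamma = 0: only outscored-or-tied true channels remain ambiguous
  probs3 <- array(0, c(2, 1, 3))
  probs3[1, 1, ] <- c(0.40, 0.41, 0.10)   # true channel outscored
  probs3[2, 1, ] <- c(0.40, 0.39, 0.10)   # true channel strictly ahead
  tg3 <- array(0L, c(2, 1, 3)); tg3[, 1, 1] <- 1L
  m3 <- margin_ambiguity_mask(probs3, tg3, gamma = 0)
  expect_equal(m3[1, 1, 1], 1L)
  expect_equal(m3[2, 1, 1], 0L)

  # exact tie at the margin counts as confident (dyadic values, so the
  # gap is exactly representable)
  probs4 <- array(c(0.75, 0.5, 0.125), c(1, 1, 3))
  expect_equal(margin_ambiguity_mask(probs4, tg, gamma = 0.25)[1, 1, 1], 0L)

  expect_error(margin_ambiguity_mask(array(1.5, c(1, 1, 3)), tg), "\\[0, 1\\]")
})

test_that("margin mask matches a direct per-pixel recomputation", {
  set.seed(41)
  for (rep in 1:10) {
    nch <- 4L; H <- 5L; W <- 4L
    probs <- array(runif(H * W * nch), c(H, W, nch))
    tg <- array(0L, c(H, W, nch))
    for (i in 1:H) for (j in 1:W) tg[i, j, sample.int(nch, 1)] <- 1L
    gamma <- runif(1, 0.05, 0.5)
    m <- margin_ambiguity_mask(probs, tg, gamma)
    for (i in 1:H) for (j in 1:W) for (c in 1:nch) {
      p <- probs[i, j, ]
      gap <- if (tg[i, j, c] == 1) p[c] - max(p[-c])
             else max(p[tg[i, j, ] == 1]) - p[c]
      expect_equal(m[i, j, c], as.integer(gap < gamma))
    }
  }
})

test_that("federated rule: absent classes contribute exactly zero", {
  set.seed(11)
  nch <- 5L  # 3 nuclei classes + bg + boundary
  probs <- array(runif(6 * 6 * nch), c(6, 6, nch))
  # keep the absent channels (2, 3) strictly below every pixel's competing
  # maxima so they never enter the margin comparison the paper defines
  # over all categories; their own BCE terms are excluded by presence
  probs[, , 2:3] <- probs[, , 2:3] * 0.05
  tg <- array(0L, c(6, 6, nch))
  tg[, , 4] <- 1L                 # background everywhere
  tg[2:3, 2:3, 4] <- 0L
  tg[2:3, 2:3, 1] <- 1L           # one instance of class 1
  targets <- mk_targets(tg, present = 1L)
  l1 <- federated_hinge_loss(probs, targets)
  expect_equal(unname(l1$pixel_counts[2:3]), c(0, 0))
  # permuting the (sub-dominant) absent-channel predictions: bit-identical
  probs2 <- probs
  probs2[, , 2] <- probs[sample(6), sample(6), 2]
  probs2[, , 3] <- probs[6:1, , 3]
  l2 <- federated_hinge_loss(probs2, targets)
  expect_identical(l1$loss, l2$loss)
  # and a fully masked absent channel never shows up in the counts
  probs3 <- probs; probs3[, , 2] <- 0.99
  expect_equal(unname(federated_hinge_loss(probs3, targets)$pixel_counts[2]), 0)
})

test_that("hand-computed BCE values and the zero-loss case are exact", {
  # single pixel, single nuclei class; prob 0.5 on the true channel is
  # ambiguous and contributes -ln(0.5)
  probs <- array(c(0.5, 0.4, 0.0), c(1, 1, 3))
  tg <- mk_targets(array(c(1, 0, 0), c(1, 1, 3)), present = 1L)
  cfgn <- loss_config(boundary_background_always_present = FALSE)
  l <- federated_hinge_loss(probs, tg, cfgn)
  expect_equal(l$loss, -log(0.5), tolerance = 1e-9)

  # everything confident by margin: zero loss, zero contributing pixels
  probs2 <- array(c(0.95, 0.01, 0.01), c(1, 1, 3))
  l2 <- federated_hinge_loss(probs2, tg, loss_config())
  expect_identical(l2$loss, 0)
  expect_equal(l2$n_contrib, 0)

  expect_error(
    federated_hinge_loss(probs, mk_targets(tg$maps, integer()), cfgn),
    "degenerate")
})

test_that("loss is non-negative and improving a correct pixel never hurts", {
  set.seed(21)
  cfg_sum <- loss_config(aggregation = "sum")
  for (rep in 1:20) {
    nch <- 4L
    probs <- array(runif(4 * 4 * nch), c(4, 4, nch))
    tg <- array(0L, c(4, 4, nch))
    for (i in 1:4) for (j in 1:4) tg[i, j, sample.int(nch, 1)] <- 1L
    targets <- mk_targets(tg, present = 1:2)
    l0 <- federated_hinge_loss(probs, targets, cfg_sum)
    expect_gte(l0$loss, 0)
    if (l0$loss == 0) expect_equal(l0$n_contrib, 0)
    # raising the probability of any correct pixel can only shrink its own
    # BCE and switch hinge masks off, so the total loss never grows
    i <- sample(4, 1); j <- sample(4, 1)
    c <- which(tg[i, j, ] == 1L)
    probs2 <- probs
    probs2[i, j, c] <- probs[i, j, c] + 0.9 * (1 - probs[i, j, c])
    l1 <- federated_hinge_loss(probs2, targets, cfg_sum)
    expect_lte(l1$loss, l0$loss + 1e-12)
  }
})

test_that("absent-class descriptors receive no gradient from a training step", {
  cats <- tiny_cats(3)
  model <- tiny_model(cats, K = 2L, L = 1L)
  set.seed(9)
  S <- 32L
  img <- array(runif(S * S * 3, 0, 255), c(S, S, 3))
  lab <- matrix(0L, S, S); lab[10:20, 8:18] <- 1L
  sc <- nuclei_scene(img, lab, stats::setNames(2L, "1"), cats)  # only class 2
  crop <- list(scene = sc, targets = derive_channel_targets(sc))
  cfg <- train_config(crop_size = S, seed = 1)
  g <- nucleiprompt:::train_step_grads(crop, model, cfg)
  expect_true(all(g$dBank[1, , ] == 0))   # class 1 absent
  expect_true(all(g$dBank[3, , ] == 0))   # class 3 absent
  expect_gt(sum(abs(g$dBank[2, , ])), 0)  # present class learns
  # one optimizer step leaves absent-class tokens bit-identical
  st <- nucleiprompt:::adam_init(list(bank = model$bank$tokens))
  upd <- nucleiprompt:::adam_step(list(bank = model$bank$tokens),
                                  list(bank = g$dBank), st, lr = 1e-3)
  expect_identical(upd$params$bank[1, , ], model$bank$tokens[1, , ])
  expect_false(identical(upd$params$bank[2, , ], model$bank$tokens[2, , ]))
})
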