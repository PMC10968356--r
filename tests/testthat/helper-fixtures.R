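# Shared fixtures: tiny backends/models, toy scenes, and random scored
# instance predictions used by the metric tests.

tiny_cats <- function(n = 2L) category_set(letters[seq_len(n)])

tiny_backend <- function(patch = 8L, d = 16L, blocks = 2L, seed = 7L)
  surrogate_backend(patch_size = patch, embed_dim = d, n_blocks = blocks,
                    seed = seed)

tiny_model <- function(cats = tiny_cats(), patch = 8L, d = 16L, K = 2L,
                       L = 2L, inner = 12L, seed = 3L, adapter = TRUE) {
  be <- tiny_backend(patch = patch, d = d, seed = seed + 4L)
  ad <- if (adapter)
    alignment_adapter(L = L, embed_dim = d, inner_channels = inner,
                      seed = seed + 1L)
  bank <- init_descriptor_bank(cats, K = K, D = d, seed = seed)
  prompt_model(be, bank, ad, cats)
}

# A deterministic scene with rectangular "nuclei" (no simulator involved).
toy_scene <- function(H = 32L, W = 32L, rects, classes,
                      cats = tiny_cats(max(classes))) {
  m <- matrix(0L, H, W)
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    m[r[1]:r[2], r[3]:r[4]] <- i
  }
  img <- array(200, c(H, W, 3))
  for (i in seq_along(rects)) {
    r <- rects[[i]]
    img[r[1]:r[2], r[3]:r[4], ] <- 80 + 10 * classes[i]
  }
  nuclei_scene(img, m, stats::setNames(as.integer(classes),
                                       as.character(seq_along(rects))), cats)
}

# Instance prediction from a label map + class/score vectors.
toy_prediction <- function(m, classes, scores = NULL, cats) {
  ids <- sort(unique(as.integer(m[m > 0])))
  nm <- as.character(ids)
  if (is.null(scores)) scores <- stats::setNames(rep(1, length(ids)), nm)
  instance_prediction(m, stats::setNames(as.integer(classes[nm]), nm),
                      stats::setNames(as.numeric(scores[nm]), nm), cats)
}

# Random scored fixture pair (prediction vs ground truth) with compact,
# well-separated square instances so that each prediction overlaps at most
# one ground-truth instance: the regime where greedy IoU matching is
# provably optimal.
random_fixture <- function(seed, H = 48L, W = 48L, n_cells = 4L,
                           cats = tiny_cats(3L)) {
  set.seed(seed)
  gm <- matrix(0L, H, W)
  pm <- matrix(0L, H, W)
  gcls <- integer(); pcls <- integer(); pscore <- numeric()
  cell <- H %/% 2L  # 2x2 arrangement of disjoint cells
  gid <- 0L; pid <- 0L
  for (ci in 0:1) for (cj in 0:1) {
    if (gid >= n_cells) next
    base_i <- ci * cell + 6L; base_j <- cj * cell + 6L
    sz <- sample(5:9, 1)
    gid <- gid + 1L
    gm[base_i:(base_i + sz), base_j:(base_j + sz)] <- gid
    gcls[gid] <- sample.int(cats$C, 1)
    if (stats::runif(1) < 0.85) {       # matching prediction, jittered
      di <- sample(-3:3, 1); dj <- sample(-3:3, 1)
      pid <- pid + 1L
      ii <- pmax(1, base_i + di):pmin(H, base_i + sz + di)
      jj <- pmax(1, base_j + dj):pmin(W, base_j + dj + sz)
      pm[ii, jj] <- pid
      pcls[pid] <- if (stats::runif(1) < 0.85) gcls[gid]
                   else sample.int(cats$C, 1)
      pscore[pid] <- stats::runif(1)
    }
    if (stats::runif(1) < 0.3) {        # spurious extra prediction
      pid <- pid + 1L
      oi <- ci * cell + 2L; oj <- cj * cell + 18L
      pm[oi:(oi + 3L), oj:(oj + 3L)] <- pid
      pcls[pid] <- sample.int(cats$C, 1)
      pscore[pid] <- stats::runif(1)
    }
  }
  gt <- nuclei_scene(array(128, c(H, W, 3)), gm,
                     stats::setNames(gcls, as.character(seq_len(gid))), cats)
  pr_ids <- sort(unique(as.integer(pm[pm > 0])))
  pred <- instance_prediction(
    pm,
    stats::setNames(pcls[pr_ids], as.character(pr_ids)),
    stats::setNames(pscore[pr_ids], as.character(pr_ids)), cats)
  list(pred = pred, gt = gt)
}
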