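#' Plan sliding-window crops over an image
#'
#' Window starts run `0, step, 2*step, ...` per axis, with a final start
#' clamped to `dim - size` whenever the last regular window misses the
#' image edge. Each window owns a central region; the central regions of
#' the window set partition the image exactly once. For regularly spaced
#' interior windows the central region is the classic
#' `[x0 + size/4, x0 + 3*size/4)` box; boundaries between neighbouring
#' windows sit at the midpoint between their spans (which reduces to that
#' box for step = size/2) and are extended to the image edge for border
#' windows.
#'
#' @param H,W Image height and width; must be at least `size`.
#' @param size Window side (default 256).
#' @param step Step between window starts (default 128).
#' @return A data.frame of crop specs, one row per window: `x0`, `y0`
#'   (0-based top-left), `size`, and the half-open central region
#'   `cx0, cx1, cy0, cy1` (0-based pixel bounds).
#' @export
plan_sliding_windows <- function(H, W, size = 256L, step = 128L) {
  if (H < size || W < size)
    stop_input("image smaller than the window size; pad the input first")
  axis_starts <- function(dim) {
    s <- seq(0L, dim - size, by = step)
    if (max(s) < dim - size) s <- c(s, dim - size)
    unique(s)
  }
  axis_regions <- function(s, dim) {
    n <- length(s)
    lo <- c(0L, (s[-n] + s[-1] + size) %/% 2L)[seq_len(n)]
    hi <- c((s[-n] + s[-1] + size) %/% 2L, dim)
    cbind(lo = lo, hi = hi)
  }
  sx <- axis_starts(W); sy <- axis_starts(H)
  rx <- axis_regions(sx, W); ry <- axis_regions(sy, H)
  grid <- expand.grid(ix = seq_along(sx), iy = seq_along(sy))
  data.frame(
    x0 = sx[grid$ix], y0 = sy[grid$iy], size = size,
    cx0 = rx[grid$ix, "lo"], cx1 = rx[grid$ix, "hi"],
    cy0 = ry[grid$iy, "lo"], cy1 = ry[grid$iy, "hi"]
  )
}

# 8-connected component labeling by iterative minimum-label propagation.
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- mask > 0
  if (!any(fg)) return(lab)
  lab[fg] <- which(fg)
  repeat {
    nxt <- lab
    for (k in seq_len(nrow(NEIGH8))) {
      sh <- shift2d(lab, NEIGH8[k, 1], NEIGH8[k, 2], fill = 0L)
      upd <- fg & sh > 0L & (sh < nxt)
      nxt[upd] <- sh[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  # compact to 1..n in raster (column-major) order of first occurrence
  ids <- unique(lab[fg])
  lab[fg] <- match(lab[fg], sort(ids))
  lab
}

#' Instance prediction container
#'
#' @param instance_map `H x W` integer label matrix (0 = background).
#' @param classes Named integer vector id -> category index.
#' @param scores Named numeric vector id -> confidence in `[0, 1]`.
#' @param categories A [category_set()].
#' @return Object of class `instance_prediction`.
#' @export
instance_prediction <- function(instance_map, classes, scores,
                                categories = category_set()) {
  ids <- sort(unique(as.integer(instance_map[instance_map > 0])))
  if (!setequal(ids, as.integer(names(classes))) ||
      !setequal(ids, as.integer(names(scores))))
    stop_input("classes/scores must cover exactly the map's instance ids")
  structure(list(instance_map = instance_map, classes = classes,
                 scores = scores, categories = categories),
            class = "instance_prediction")
}

#' @export
print.instance_prediction <- function(x, ...) {
  cat("<instance_prediction> ", nrow(x$instance_map), "x",
      ncol(x$instance_map), ", ", length(x$classes), " instances\n", sep = "")
  invisible(x)
}

#' Decode classified instances from per-channel probability maps
#'
#' Per pixel, the winning channel is the argmax over all channels. Pixels
#' won by a nuclei-class channel are candidate nucleus pixels; 8-connected
#' components are computed per class, components below `min_area` pixels
#' are discarded, and each surviving component is then grown into adjacent
#' boundary-channel pixels (geodesic dilation iterated to convergence, ties
#' claimed by the larger component, equal areas by the lower id) so that
#' instances regain the rim the boundary channel carved away. The instance
#' score is the mean probability of its class channel over its pixels.
#'
#' @param pred A `channel_prediction` from [decode_channel_maps()], or a
#'   bare `H x W x (C+2)` probability array.
#' @param categories A [category_set()].
#' @param min_area Minimum component area in pixels (default 10).
#' @return An [instance_prediction()] in crop-local coordinates.
#' @export
decode_instances <- function(pred, categories = category_set(),
                             min_area = 10L) {
  probs <- if (inherits(pred, "channel_prediction")) pred$probs else pred
  if (any(probs < 0) || any(probs > 1)) stop_input("probabilities outside [0,1]")
  H <- dim(probs)[1]; W <- dim(probs)[2]
  C <- categories$C
  P <- flatten_channels(probs)
  arg <- max.col(P, ties.method = "first")
  argm <- matrix(arg, H, W)
  out <- matrix(0L, H, W)
  inst_class <- integer(); inst_area <- integer()
  next_id <- 0L
  for (c in seq_len(C)) {
    comp <- label_components(argm == c)
    if (!any(comp > 0L)) next
    areas <- tabulate(comp[comp > 0L])
    for (k in seq_along(areas)) {
      if (areas[k] < min_area) next
      next_id <- next_id + 1L
      out[comp == k] <- next_id
      inst_class <- c(inst_class, c)
      inst_area <- c(inst_area, areas[k])
    }
  }
  # geodesic dilation of kept instances into boundary-argmax pixels
  bnd_free <- argm == (C + 2L) & out == 0L
  while (any(bnd_free)) {
    best_lab <- matrix(0L, H, W)
    best_rank <- matrix(-Inf, H, W)
    for (k in seq_len(nrow(NEIGH8))) {
      nb <- shift2d(out, NEIGH8[k, 1], NEIGH8[k, 2], fill = 0L)
      idx <- which(bnd_free & nb > 0L)
      if (!length(idx)) next
      # rank by component area, breaking exact area ties toward the lower id
      rank <- inst_area[nb[idx]] - nb[idx] * 1e-9
      better <- rank > best_rank[idx]
      best_lab[idx[better]] <- nb[idx[better]]
      best_rank[idx[better]] <- rank[better]
    }
    newly <- best_lab > 0L
    if (!any(newly)) break
    out[newly] <- best_lab[newly]
    bnd_free <- bnd_free & !newly
  }
  ids <- seq_len(next_id)
  keep <- ids[ids %in% out]
  scores <- vapply(keep, function(id) {
    mean(probs[, , inst_class[id]][out == id])
  }, 0)
  # compact ids
  map2 <- matrix(0L, H, W)
  cls <- integer(length(keep)); names_v <- as.character(seq_along(keep))
  for (i in seq_along(keep)) {
    map2[out == keep[i]] <- i
    cls[i] <- inst_class[keep[i]]
  }
  instance_prediction(map2,
                      stats::setNames(cls, names_v),
                      stats::setNames(scores, names_v),
                      categories)
}

#' Stitch per-crop instance predictions into a full-size map
#'
#' An instance is kept iff its centroid falls inside its own crop's central
#' region; the central regions tile the image, so every nucleus is owned by
#' exactly one crop and neighbouring crops never duplicate it. Kept
#' instances receive fresh sequential ids; where two kept instances overlap
#' on a pixel, the higher-score instance claims it.
#'
#' @param crops List of `list(spec = <one row of plan_sliding_windows>,
#'   pred = <instance_prediction in crop-local coordinates>)`.
#' @param H,W Full-image dimensions.
#' @param categories A [category_set()].
#' @return An [instance_prediction()] over the full image.
#' @export
stitch_predictions <- function(crops, H, W, categories = category_set()) {
  full <- matrix(0L, H, W)
  cls <- integer(); scr <- numeric()
  kept <- list()
  for (cp in crops) {
    spec <- cp$spec; pr <- cp$pred
    cent <- instance_centroids(pr$instance_map)
    if (!nrow(cent)) next
    gx <- cent$x + spec$x0; gy <- cent$y + spec$y0
    keep <- gx >= spec$cx0 & gx < spec$cx1 & gy >= spec$cy0 & gy < spec$cy1
    for (id in cent$id[keep]) {
      kept[[length(kept) + 1L]] <- list(
        spec = spec, pr = pr, id = id,
        score = pr$scores[[as.character(id)]],
        class = pr$classes[[as.character(id)]]
      )
    }
  }
  if (length(kept)) {
    ord <- order(vapply(kept, function(k) k$score, 0))  # high scores last win
    nid <- 0L
    cls <- integer(length(kept)); scr <- numeric(length(kept))
    for (k in kept[ord]) {
      nid <- nid + 1L
      w <- which(k$pr$instance_map == k$id, arr.ind = TRUE)
      rows <- w[, 1] + k$spec$y0
      colsx <- w[, 2] + k$spec$x0
      full[cbind(rows, colsx)] <- nid
      cls[nid] <- k$class; scr[nid] <- k$score
    }
    present <- sort(unique(full[full > 0L]))
    cls <- cls[present]; scr <- scr[present]
    full[full > 0L] <- match(full[full > 0L], present)
    nm <- as.character(seq_along(present))
    return(instance_prediction(full, stats::setNames(cls, nm),
                               stats::setNames(scr, nm), categories))
  }
  instance_prediction(full, stats::setNames(integer(), character()),
                      stats::setNames(numeric(), character()), categories)
}

#' Predict classified nuclei instances for a full image
#'
#' Runs sliding-window inference: plans 256/128 (or configured) windows,
#' encodes each crop through the frozen encoder (with the model's adapter),
#' decodes all channel maps with the descriptor bank, converts them to
#' crop-local instances and stitches the central-region instances into a
#' full-size prediction.
#'
#' @param image `H x W x 3` RGB array, intensities `[0, 255]`.
#' @param model A [prompt_model()].
#' @param window,step Sliding-window geometry (defaults 256/128; the window
#'   is clamped to the image side if the image is smaller in neither axis).
#' @param min_area Minimum instance area, see [decode_instances()].
#' @param points Optional data.frame of interactive prompts with columns
#'   `x`, `y` (0-based image coordinates), `polarity`, `channel`.
#' @return An [instance_prediction()]; attribute `"channel_probs"` of each
#'   crop is not retained.
#' @export
predict_scene <- function(image, model, window = 256L, step = window %/% 2L,
                          min_area = 10L, points = NULL) {
  H <- dim(image)[1]; W <- dim(image)[2]
  plan <- plan_sliding_windows(H, W, size = window, step = step)
  cats <- model$categories
  crops <- vector("list", nrow(plan))
  for (r in seq_len(nrow(plan))) {
    spec <- plan[r, ]
    img <- image[(spec$y0 + 1):(spec$y0 + spec$size),
                 (spec$x0 + 1):(spec$x0 + spec$size), , drop = FALSE]
    pts_by_ch <- NULL
    if (!is.null(points) && nrow(points)) {
      inwin <- points$x >= spec$x0 & points$x < spec$x0 + spec$size &
        points$y >= spec$y0 & points$y < spec$y0 + spec$size
      if (any(inwin)) {
        pts_by_ch <- lapply(seq_len(cats$total_channels), function(ch) {
          p <- points[inwin & points$channel == ch, , drop = FALSE]
          if (!nrow(p)) return(NULL)
          data.frame(x = p$x - spec$x0, y = p$y - spec$y0,
                     polarity = p$polarity)
        })
      }
    }
    enc <- encode_image(img, model$backend, model$adapter)
    pred <- decode_channel_maps(enc, bank_prompts(model$bank, pts_by_ch),
                                model$backend, spec$size)
    crops[[r]] <- list(spec = spec,
                       pred = decode_instances(pred, cats, min_area))
  }
  stitch_predictions(crops, H, W, cats)
}

#' Interactive point-prompt refinement against ground truth
#'
#' Emulates an annotator: per refinement round and per category present in
#' the ground truth, the ground-truth instance whose current prediction has
#' the lowest confidence (undetected instances first) receives one
#' foreground point prompt at its centroid on that category's channel;
#' prediction is then re-run with all accumulated points. Each instance is
#' prompted at most once.
#'
#' @param image `H x W x 3` RGB array.
#' @param model A trained [prompt_model()].
#' @param gt The ground-truth [nuclei_scene()].
#' @param rounds Number of refinement rounds (>= 0).
#' @param window,step,min_area Passed to [predict_scene()].
#' @param iou_threshold Matching threshold used to score the current
#'   prediction.
#' @param current Optional starting [instance_prediction()]; recomputed
#'   when omitted.
#' @return List with `prediction` (final), `points` (all placed points),
#'   `report` (per-round data.frame: round, n_points, mean_f1) and
#'   `matches` (per-round [match_objects()] results, index = round + 1).
#' @export
refine_with_points <- function(image, model, gt, rounds = 4L,
                               window = 256L, step = window %/% 2L,
                               min_area = 10L, iou_threshold = 0.5,
                               current = NULL) {
  if (rounds < 0) stop_input("rounds must be >= 0")
  cats <- model$categories
  if (is.null(current))
    current <- predict_scene(image, model, window, step, min_area)
  pts <- data.frame(x = numeric(), y = numeric(), polarity = character(),
                    channel = integer())
  prompted <- character()
  report <- list()
  matches <- list()
  f1_of <- function(pred, slot) {
    m <- match_objects(pred, gt, iou_threshold = iou_threshold)
    matches[[slot]] <<- m
    object_f1_scores(m, cats)$mean
  }
  report[[1]] <- data.frame(round = 0L, n_points = 0L,
                            mean_f1 = f1_of(current, 1L))
  if (rounds == 0L) {
    return(list(prediction = current, points = pts,
                report = do.call(rbind, report), matches = matches))
  }
  gtc <- instance_centroids(gt$instance_map)
  for (r in seq_len(rounds)) {
    m <- match_objects(current, gt, iou_threshold = iou_threshold)
    matched_score <- stats::setNames(
      current$scores[as.character(m$pairs$pred_id)],
      as.character(m$pairs$gt_id))
    for (c in sort(unique(as.integer(gt$classes)))) {
      gids <- as.integer(names(gt$classes)[gt$classes == c])
      gids <- gids[!(as.character(gids) %in% prompted)]
      if (!length(gids)) next
      sc <- matched_score[as.character(gids)]
      sc[is.na(sc)] <- -Inf                     # undetected first
      pick <- gids[which.min(sc)]
      ctr <- gtc[gtc$id == pick, ]
      pts <- rbind(pts, data.frame(x = round(ctr$x), y = round(ctr$y),
                                   polarity = "foreground", channel = c))
      prompted <- c(prompted, as.character(pick))
    }
    current <- predict_scene(image, model, window, step, min_area,
                             points = pts)
    report[[r + 1L]] <- data.frame(round = r, n_points = nrow(pts),
                                   mean_f1 = f1_of(current, r + 1L))
  }
  list(prediction = current, points = pts, report = do.call(rbind, report),
       matches = matches)
}
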