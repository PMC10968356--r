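#' Training configuration
#'
#' Defaults follow the reference schedule: Adam, learning rate `1e-3` with
#' linear warm-up, step decay to `1e-4` for the last 2 of 20 epochs,
#' 256-pixel crops, repeat factor sampling, and flip/rotation/color-jitter
#' augmentation.
#'
#' @param crop_size Training crop side (must be divisible by the backend
#'   patch size).
#' @param epochs Epochs; one epoch is a pass over the RFS-expanded scene
#'   list.
#' @param lr_start,lr_end Peak and final learning rates.
#' @param warmup_steps Linear warm-up length in steps.
#' @param final_lr_epochs Number of trailing epochs run at `lr_end`.
#' @param rfs_t Repeat-factor-sampling frequency threshold `t`.
#' @param max_steps Hard cap on optimization steps.
#' @param loss A [loss_config()].
#' @param augment Apply random flip/rotation/color jitter.
#' @param boundary_thickness Boundary-channel thickness for the targets.
#' @param seed Seed for sampling, augmentation and RFS rounding.
#' @return A list of class `train_config`.
#' @export
train_config <- function(crop_size = 256L, epochs = 20L,
                         lr_start = 1e-3, lr_end = 1e-4,
                         warmup_steps = 30L, final_lr_epochs = 2L,
                         rfs_t = 0.3, max_steps = Inf,
                         loss = loss_config(), augment = TRUE,
                         boundary_thickness = 1L, seed = 1L) {
  if (lr_end > lr_start || lr_end <= 0) stop_input("need 0 < lr_end <= lr_start")
  structure(list(crop_size = as.integer(crop_size), epochs = as.integer(epochs),
                 lr_start = lr_start, lr_end = lr_end,
                 warmup_steps = as.integer(warmup_steps),
                 final_lr_epochs = as.integer(final_lr_epochs),
                 rfs_t = rfs_t, max_steps = max_steps, loss = loss,
                 augment = augment,
                 boundary_thickness = as.integer(boundary_thickness),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Repeat factor sampling for long-tailed scene lists
#'
#' Category-level factor `r(c) = max(1, sqrt(t / f(c)))` where `f(c)` is the
#' fraction of scenes containing category `c`; the scene-level factor is the
#' maximum over the categories present in the scene (1 for empty scenes).
#' Scenes rich in rare categories are thus oversampled, frequent-only
#' scenes are left at rate 1.
#'
#' @param scenes List of per-scene present-category index vectors, or a list
#'   of [nuclei_scene()] objects.
#' @param t Frequency threshold in `(0, 1]`; categories at least this
#'   frequent are never oversampled.
#' @param class_frequencies Optional named/indexed numeric vector of
#'   per-category scene frequencies in `(0, 1]`; computed from `scenes` when
#'   omitted.
#' @return List with `category_factors` and `scene_factors`.
#' @export
compute_repeat_factors <- function(scenes, t = 0.3, class_frequencies = NULL) {
  if (t <= 0 || t > 1) stop_input("t must lie in (0, 1]")
  present <- lapply(scenes, function(s) {
    if (inherits(s, "nuclei_scene")) sort(unique(as.integer(s$classes)))
    else sort(unique(as.integer(s)))
  })
  all_cats <- sort(unique(unlist(present)))
  if (is.null(class_frequencies)) {
    n <- length(present)
    class_frequencies <- vapply(all_cats, function(c) {
      mean(vapply(present, function(p) c %in% p, TRUE))
    }, 0)
    names(class_frequencies) <- all_cats
  } else {
    if (any(class_frequencies <= 0 | class_frequencies > 1))
      stop_input("class frequencies must lie in (0, 1]")
    if (is.null(names(class_frequencies)))
      names(class_frequencies) <- seq_along(class_frequencies)
  }
  f_of <- function(c) {
    f <- class_frequencies[as.character(c)]
    if (is.na(f) || f <= 0)
      stop_input("zero frequency for present category ", c)
    f
  }
  cat_fac <- vapply(all_cats, function(c) max(1, sqrt(t / f_of(c))), 0)
  names(cat_fac) <- all_cats
  scene_fac <- vapply(present, function(p) {
    if (!length(p)) 1 else max(cat_fac[as.character(p)])
  }, 0)
  list(category_factors = cat_fac, scene_factors = scene_fac)
}

# Stochastic rounding of fractional repeat factors into an epoch's index
# multiset (floor + Bernoulli on the fractional part).
rfs_expand <- function(scene_factors) {
  reps <- floor(scene_factors) +
    (stats::runif(length(scene_factors)) < (scene_factors %% 1))
  rep(seq_along(scene_factors), times = reps)
}

# 90-degree rotations; k in 0:3, counter-clockwise.
rot90_mat <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}
rot90_img <- function(img, k) {
  if (k %% 4L == 0L) return(img)
  out <- NULL
  for (ch in seq_len(dim(img)[3])) {
    r <- rot90_mat(img[, , ch], k)
    if (is.null(out)) out <- array(0, c(dim(r), dim(img)[3]))
    out[, , ch] <- r
  }
  out
}

#' Sample an augmented training crop with aligned targets
#'
#' Extracts a uniformly placed square crop from a scene, applies a random
#' flip, a random multiple-of-90-degree rotation and photometric color
#' jitter (brightness/contrast/saturation), and derives the channel targets
#' from the spatially augmented label map so that image and supervision
#' stay aligned. Photometric jitter never touches the labels. Consumes the
#' caller's RNG stream, so results are deterministic under a seed.
#'
#' @param scene A [nuclei_scene()] at least `size` pixels in each dimension.
#' @param size Crop side in pixels.
#' @param augment Apply the random augmentations (cropping stays random).
#' @param jitter_range Half-width of the brightness/contrast/saturation
#'   jitter factors (factor drawn in `1 +/- jitter_range`).
#' @param boundary_thickness Passed to [derive_channel_targets()].
#' @return List with `scene` (the augmented sub-scene) and `targets`.
#' @export
sample_training_crop <- function(scene, size, augment = TRUE,
                                 jitter_range = 0.2,
                                 boundary_thickness = 1L) {
  H <- nrow(scene$instance_map); W <- ncol(scene$instance_map)
  if (H < size || W < size) stop_input("scene smaller than the crop size")
  y0 <- sample.int(H - size + 1L, 1L)
  x0 <- sample.int(W - size + 1L, 1L)
  img <- scene$image[y0:(y0 + size - 1L), x0:(x0 + size - 1L), , drop = FALSE]
  lab <- scene$instance_map[y0:(y0 + size - 1L), x0:(x0 + size - 1L),
                            drop = FALSE]
  if (augment) {
    fl <- sample(c("none", "h", "v"), 1L)
    if (fl == "h") {
      img <- img[, size:1, , drop = FALSE]; lab <- lab[, size:1, drop = FALSE]
    } else if (fl == "v") {
      img <- img[size:1, , , drop = FALSE]; lab <- lab[size:1, , drop = FALSE]
    }
    k <- sample(0:3, 1L)
    img <- rot90_img(img, k); lab <- rot90_mat(lab, k)
    br <- stats::runif(1, 1 - jitter_range, 1 + jitter_range)
    ct <- stats::runif(1, 1 - jitter_range, 1 + jitter_range)
    st <- stats::runif(1, 1 - jitter_range, 1 + jitter_range)
    img <- (img * br - 128) * ct + 128
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * st
    img[] <- pmin(255, pmax(0, img))
  }
  ids <- sort(unique(as.integer(lab[lab > 0])))
  classes <- scene$classes[as.character(ids)]
  sub <- nuclei_scene(img, lab, classes, scene$categories)
  targets <- derive_channel_targets(sub, thickness = boundary_thickness)
  list(scene = sub, targets = targets)
}

# Build the per-channel prompt list from a descriptor bank.
bank_prompts <- function(bank, points_by_channel = NULL) {
  nch <- dim(bank$tokens)[1]
  lapply(seq_len(nch), function(ch) {
    pts <- if (!is.null(points_by_channel)) points_by_channel[[ch]]
    prompt_set(channel_tokens(bank, ch), pts)
  })
}

# Forward + loss + gradients for one crop. Returns loss, bank gradient
# array and adapter layer gradients (NULL when no adapter).
train_step_grads <- function(crop, model, config) {
  backend <- model$backend
  S <- nrow(crop$scene$instance_map)
  enc <- encode_image(crop$scene$image, backend, model$adapter,
                      want_grad = !is.null(model$adapter))
  pred <- decode_channel_maps(enc, bank_prompts(model$bank), backend, S,
                              want_grad = TRUE)
  fl <- federated_hinge_loss(pred$probs, crop$targets, config$loss)
  nch <- dim(pred$probs)[3]
  dBank <- array(0, dim(model$bank$tokens))
  dZ <- NULL
  for (ch in seq_len(nch)) {
    denom <- switch(config$loss$aggregation,
      channel_mean = max(1, fl$pixel_counts[ch]) * fl$n_active,
      mean = max(1, fl$n_contrib),
      sum = 1)
    dFull <- (pred$probs[, , ch] - crop$targets$maps[, , ch]) *
      fl$contrib_mask[, , ch] / denom
    if (!any(dFull != 0)) next
    dLgrid <- crossprod(pred$Uh, dFull) %*% pred$Uw
    dLsub <- disassemble_subgrid(dLgrid, pred$gh, pred$gw, pred$upF)
    bw <- decode_channel_bwd(dLsub, pred$caches[[ch]]$dec)
    dZ <- if (is.null(dZ)) bw$dZ else dZ + bw$dZ
    K <- model$bank$K
    dTok <- bw$dT0[3:(2 + K), , drop = FALSE]
    # the mask slot is seeded by the descriptor mean: route its gradient
    dTok <- sweep(dTok, 2, bw$dT0[1, ] / K, `+`)
    dBank[ch, , ] <- dBank[ch, , ] + dTok
  }
  dAdapter <- NULL
  if (!is.null(model$adapter) && !is.null(dZ))
    dAdapter <- encode_bwd(dZ, enc$cache, backend, model$adapter)
  if (!is.null(model$adapter) && is.null(dAdapter))
    dAdapter <- rapply(adapter_params(model$adapter),
                       function(a) array(0, dim(a) %||% length(a)),
                       how = "replace")
  list(loss = fl$loss, counts = fl$pixel_counts,
       dBank = dBank, dAdapter = dAdapter)
}

# Mean validation loss over deterministic centre crops.
validation_loss <- function(scenes, model, config) {
  S <- config$crop_size
  losses <- vapply(scenes, function(sc) {
    H <- nrow(sc$instance_map); W <- ncol(sc$instance_map)
    y0 <- (H - S) %/% 2L + 1L; x0 <- (W - S) %/% 2L + 1L
    img <- sc$image[y0:(y0 + S - 1L), x0:(x0 + S - 1L), , drop = FALSE]
    lab <- sc$instance_map[y0:(y0 + S - 1L), x0:(x0 + S - 1L), drop = FALSE]
    ids <- sort(unique(as.integer(lab[lab > 0])))
    sub <- nuclei_scene(img, lab, sc$classes[as.character(ids)], sc$categories)
    tg <- derive_channel_targets(sub, thickness = config$boundary_thickness)
    enc <- encode_image(img, model$backend, model$adapter)
    pr <- decode_channel_maps(enc, bank_prompts(model$bank), model$backend, S)
    federated_hinge_loss(pr$probs, tg, config$loss)$loss
  }, 0)
  mean(losses)
}

#' Train the adapter and descriptor bank
#'
#' Optimizes only the two trainable parts -- the alignment adapter and the
#' descriptor bank -- with Adam under the federated hinge objective; every
#' backend weight stays frozen. Each epoch is one shuffled pass over the
#' repeat-factor-expanded scene list (fractional factors realized by
#' stochastic rounding, reseeded per epoch); each step draws one augmented
#' crop.
#'
#' @param scenes List of training [nuclei_scene()] objects.
#' @param model A [prompt_model()].
#' @param config A [train_config()].
#' @param val_scenes Optional validation scenes; evaluated every epoch, and
#'   the returned model carries the best-validation parameters in
#'   `best_model`.
#' @param checkpoint_path Optional path; final (and best, as
#'   `*_best`) checkpoints are written there.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (final), `best_model`, `history` (per-step
#'   data.frame: step, epoch, lr, loss), `val_history`.
#' @export
train_model <- function(scenes, model, config = train_config(),
                        val_scenes = NULL, checkpoint_path = NULL,
                        verbose = FALSE) {
  if (!length(scenes)) stop_input("empty dataset")
  if (config$crop_size %% model$backend$patch_size != 0L)
    stop_input("crop_size must be divisible by the backend patch size")
  rfs <- compute_repeat_factors(scenes, t = config$rfs_t)
  params <- list(bank = model$bank$tokens)
  if (!is.null(model$adapter)) params$adapter <- adapter_params(model$adapter)
  opt <- adam_init(params)
  step <- 0L
  hist <- list()
  val_hist <- list()
  best_val <- Inf; best_params <- params
  sync_model <- function(par) {
    model$bank$tokens <- par$bank
    if (!is.null(model$adapter))
      model$adapter <- set_adapter_params(model$adapter, par$adapter)
    model
  }
  done <- FALSE
  for (epoch in seq_len(config$epochs)) {
    set.seed(derive_seed(config$seed, epoch))
    expanded <- rfs_expand(rfs$scene_factors)
    order_idx <- expanded[sample.int(length(expanded))]
    lr_epoch <- if (epoch > config$epochs - config$final_lr_epochs)
      config$lr_end else config$lr_start
    for (si in order_idx) {
      step <- step + 1L
      lr <- if (step <= config$warmup_steps)
        lr_epoch * step / config$warmup_steps else lr_epoch
      crop <- sample_training_crop(scenes[[si]], config$crop_size,
                                   augment = config$augment,
                                   boundary_thickness =
                                     config$boundary_thickness)
      model <- sync_model(params)
      g <- train_step_grads(crop, model, config)
      if (!is.finite(g$loss))
        stop("non-finite loss at step ", step, "; aborting training")
      grads <- list(bank = g$dBank)
      if (!is.null(model$adapter)) grads$adapter <- g$dAdapter
      upd <- adam_step(params, grads, opt, lr)
      params <- upd$params; opt <- upd$state
      hist[[step]] <- data.frame(step = step, epoch = epoch, lr = lr,
                                 loss = g$loss)
      if (step >= config$max_steps) { done <- TRUE; break }
    }
    model <- sync_model(params)
    if (!is.null(val_scenes)) {
      vl <- validation_loss(val_scenes, model, config)
      val_hist[[length(val_hist) + 1L]] <-
        data.frame(epoch = epoch, step = step, val_loss = vl)
      if (vl < best_val) { best_val <- vl; best_params <- params }
      if (verbose) message("epoch ", epoch, " step ", step,
                           " val_loss ", signif(vl, 4))
    } else if (verbose) {
      message("epoch ", epoch, " step ", step,
              " loss ", signif(hist[[step]]$loss, 4))
    }
    if (done) break
  }
  model <- sync_model(params)
  best_model <- if (is.null(val_scenes)) model else sync_model(best_params)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path)
    save_checkpoint(best_model, paste0(checkpoint_path, "_best"))
  }
  list(model = model, best_model = best_model,
       history = do.call(rbind, hist),
       val_history = if (length(val_hist)) do.call(rbind, val_hist))
}
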