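# The shared end-to-end training fixture: surrogate backend, 12-layer
# adapter, 32 descriptors per channel, trained once on 40 generated scenes
# (and once more without the adapter as the ablation control), then reused
# by every test that needs a trained model.

.trained_env <- new.env(parent = emptyenv())

e2e_fixture <- function() {
  if (!is.null(.trained_env$fix)) return(.trained_env$fix)
  cats <- category_set()
  simc <- sim_config()
  train <- lapply(1:40, function(i) generate_scene(simc, seed = 1000 + i))
  heldout <- lapply(1:10, function(i) generate_scene(simc, seed = 9000 + i))
  backend <- surrogate_backend(patch_size = 8L, embed_dim = 64L,
                               n_blocks = 2L, seed = 7L)
  bank <- init_descriptor_bank(cats, K = 32L, D = 64L, seed = 2L)
  adapter <- alignment_adapter(L = 12L, embed_dim = 64L,
                               inner_channels = 96L, seed = 3L)
  cfg <- train_config(crop_size = 128L, epochs = 20L, max_steps = 1000L,
                      seed = 1L)
  checksum_before <- backend_checksum(backend)
  fit <- train_model(train, prompt_model(backend, bank, adapter, cats), cfg)
  fit0 <- train_model(train, prompt_model(backend, bank, NULL, cats), cfg)
  preds <- lapply(heldout, function(s)
    predict_scene(s$image, fit$model, window = 128L))
  preds0 <- lapply(heldout, function(s)
    predict_scene(s$image, fit0$model, window = 128L))
  .trained_env$fix <- list(
    cats = cats, simc = simc, train = train, heldout = heldout,
    backend = backend, bank0 = bank, checksum_before = checksum_before,
    fit = fit, fit0 = fit0, preds = preds, preds0 = preds0,
    report = eval_report(preds, heldout, cats),
    report0 = eval_report(preds0, heldout, cats)
  )
  .trained_env$fix
}

# Deterministic held-out refinement scenes guaranteed to contain every
# category at least once across the set.
refinement_scenes <- function(simc, cats, n_min = 4L, seed_base = 20000L) {
  scenes <- list(); have <- integer(); k <- 0L
  while ((length(scenes) < n_min || length(have) < cats$C) && k < 400L) {
    k <- k + 1L
    sc <- generate_scene(simc, seed = seed_base + k)
    new_cats <- setdiff(unique(as.integer(sc$classes)), have)
    if (length(scenes) < n_min || length(new_cats)) {
      scenes[[length(scenes) + 1L]] <- sc
      have <- union(have, unique(as.integer(sc$classes)))
    }
  }
  scenes
}
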