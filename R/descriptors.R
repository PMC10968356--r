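#' Learnable category-descriptor bank
#'
#' One stack of `K` learnable prompt tokens per output channel (each nuclei
#' category plus background and boundary). Fed to the frozen mask decoder as
#' sparse prompt embeddings, each stack elicits the segmentation mask of its
#' channel.
#'
#' @param categories A [category_set()].
#' @param K Descriptors (tokens) per channel, default 32.
#' @param D Token dimension; must equal the backend's embedding width
#'   (256 for a real ViT-B backend, 64 for the default surrogate).
#' @param seed Seed for the small-scale random initialization.
#' @return An object of class `descriptor_bank` with a
#'   `total_channels x K x D` token array.
#' @export
init_descriptor_bank <- function(categories, K = 32L, D = 64L, seed = 1L) {
  if (K < 1 || D < 1) stop_input("K and D must be positive integers")
  ch <- categories$total_channels
  tokens <- with_seed(seed,
    array(stats::rnorm(ch * K * D, 0, 0.1), c(ch, as.integer(K), as.integer(D))))
  structure(list(tokens = tokens, K = as.integer(K), D = as.integer(D),
                 categories = categories),
            class = "descriptor_bank")
}

#' @export
print.descriptor_bank <- function(x, ...) {
  cat("<descriptor_bank> ", dim(x$tokens)[1], " channels x ", x$K,
      " tokens x ", x$D, " dims\n", sep = "")
  invisible(x)
}

# Token stack of one channel as a K x D matrix.
channel_tokens <- function(bank, channel) {
  matrix(bank$tokens[channel, , ], bank$K, bank$D)
}

#' Assemble a prompt model
#'
#' Bundles the frozen backend with the two trainable parts (alignment
#' adapter and descriptor bank) and the category set.
#'
#' @param backend A `seg_backend` from [create_backend()].
#' @param bank A [init_descriptor_bank()]; token dimension must match the
#'   backend embedding width.
#' @param adapter An [alignment_adapter()] or `NULL` (adapter-free model).
#' @param categories A [category_set()].
#' @return An object of class `prompt_model`.
#' @export
prompt_model <- function(backend, bank, adapter = NULL,
                         categories = bank$categories) {
  if (bank$D != backend$embed_dim)
    stop_input("descriptor token dimension must equal the backend width")
  if (!is.null(adapter) && adapter$embed_dim != backend$embed_dim)
    stop_input("adapter width must equal the backend width")
  structure(list(backend = backend, bank = bank, adapter = adapter,
                 categories = categories),
            class = "prompt_model")
}

#' @export
print.prompt_model <- function(x, ...) {
  cat("<prompt_model> backend=", x$backend$name,
      if (is.null(x$adapter)) ", no adapter" else
        paste0(", adapter L=", x$adapter$L),
      ", K=", x$bank$K, ", D=", x$bank$D, "\n", sep = "")
  invisible(x)
}

#' Save / load a trained checkpoint
#'
#' The archive stores only the trainable parts (adapter and descriptor
#' bank) plus the frozen backend's name and parameter checksum; backend
#' weights are never serialized. Loading verifies the checksum against the
#' supplied backend.
#'
#' @param model A [prompt_model()].
#' @param path Checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(bank = model$bank, adapter = model$adapter,
               categories = model$categories,
               backend_name = model$backend$name,
               backend_checksum = backend_checksum(model$backend)),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param backend The frozen backend to attach; must match the checksum
#'   recorded in the checkpoint.
#' @export
load_checkpoint <- function(path, backend) {
  ck <- readRDS(path)
  if (!identical(ck$backend_checksum, backend_checksum(backend)))
    stop_input("checkpoint was trained against a different frozen backend")
  prompt_model(backend, ck$bank, ck$adapter, ck$categories)
}
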