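# Internal helpers shared across modules.

# Shift a matrix by (di, dj), filling vacated cells with `fill`.
shift2d <- function(m, di, dj, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_i <- max(1L, 1L - di):min(h, h - di)
  src_j <- max(1L, 1L - dj):min(w, w - dj)
  if (length(src_i) < 1L || length(src_j) < 1L) return(out)
  out[src_i + di, src_j + dj] <- m[src_i, src_j, drop = FALSE]
  out
}

# The eight king-move offsets.
NEIGH8 <- cbind(di = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dj = c(-1L,  0L,  1L, -1L, 1L, -1L, 0L, 1L))

# Derive a child seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + as.double(k) * 12347L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)
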