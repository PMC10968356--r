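#' Nuclei category set
#'
#' Defines the ordered set of nuclei categories plus the two reserved output
#' channels: background and boundary. Channel layout is fixed as
#' `1..C` nuclei categories, `C+1` background, `C+2` boundary.
#'
#' @param names Character vector of unique category names, ordered.
#' @return An object of class `category_set` with elements `names`, `C`
#'   (number of nuclei categories) and `total_channels` (`C + 2`).
#' @examples
#' cats <- category_set()
#' cats$total_channels  # 8 for the default six categories
#' @export
category_set <- function(names = c("neutrophil", "eosinophil", "plasma",
                                   "connective", "lymphocyte", "epithelial")) {
  if (!is.character(names) || length(names) < 1L)
    stop("`names` must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(names))
    stop("category names must be unique", call. = FALSE)
  structure(
    list(names = names, C = length(names), total_channels = length(names) + 2L),
    class = "category_set"
  )
}

#' @export
print.category_set <- function(x, ...) {
  cat("<category_set> ", x$C, " nuclei categories + background + boundary\n",
      sep = "")
  cat("  ", paste(x$names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Channel index helpers
#'
#' @param categories A [category_set()].
#' @return Integer channel index of the background or boundary channel.
#' @export
background_channel <- function(categories) categories$C + 1L

#' @rdname background_channel
#' @export
boundary_channel <- function(categories) categories$C + 2L
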