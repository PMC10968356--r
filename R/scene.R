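#' Nuclei scene: image, instance-label map and per-instance classes
#'
#' The universal ground-truth/prediction container: an RGB tile, a
#' non-negative integer instance-label map (0 = background tissue) and a
#' mapping from instance id to nuclei category.
#'
#' @param image `H x W x 3` numeric array of intensities in `[0, 255]`.
#' @param instance_map `H x W` integer matrix of instance labels, 0 outside
#'   nuclei. Every nonzero label must have exactly one entry in `classes`.
#' @param classes Named integer vector mapping instance id (name, as
#'   character) to category index in `1..C`.
#' @param categories A [category_set()].
#' @return An object of class `nuclei_scene`.
#' @export
nuclei_scene <- function(image, instance_map, classes, categories = category_set()) {
  scene <- structure(
    list(image = image, instance_map = instance_map,
         classes = classes, categories = categories),
    class = "nuclei_scene"
  )
  validate_scene(scene)
  scene
}

#' Validate the invariants of a nuclei scene
#'
#' Checks the label map is a non-negative integer matrix, that every nonzero
#' instance id carries exactly one class entry (and vice versa), that every
#' instance has at least one pixel, and that class indices lie in `1..C`.
#'
#' @param scene A [nuclei_scene()].
#' @return The scene, invisibly; errors on any violation.
#' @export
validate_scene <- function(scene) {
  img <- scene$image; m <- scene$instance_map
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input("image must be an H x W x 3 array")
  if (!is.matrix(m)) stop_input("instance_map must be a matrix")
  if (any(dim(img)[1:2] != dim(m)))
    stop_input("image and instance_map dimensions disagree")
  if (any(m != round(m)) || any(m < 0))
    stop_input("instance_map labels must be non-negative integers")
  ids <- sort(unique(as.integer(m[m > 0])))
  cl_ids <- suppressWarnings(as.integer(names(scene$classes)))
  if (length(scene$classes) && (anyNA(cl_ids) || anyDuplicated(cl_ids)))
    stop_input("classes must be uniquely named by integer instance ids")
  if (!setequal(ids, cl_ids))
    stop_input("instance ids in map and class table disagree")
  C <- scene$categories$C
  if (length(scene$classes) && (any(scene$classes < 1L) || any(scene$classes > C)))
    stop_input("class index out of range 1..C")
  invisible(scene)
}

#' @export
print.nuclei_scene <- function(x, ...) {
  cat("<nuclei_scene> ", nrow(x$instance_map), "x", ncol(x$instance_map),
      ", ", length(x$classes), " instances\n", sep = "")
  if (length(x$classes)) {
    tab <- table(factor(x$categories$names[x$classes],
                        levels = x$categories$names))
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Derive the boundary map of an instance-label map
#'
#' A pixel is boundary iff it belongs to an instance and lies within
#' `thickness` pixels (8-connectivity erosion depth) of any pixel not
#' belonging to the same instance -- either background, a different instance,
#' or outside the image. Touching instances are therefore marked on both
#' sides of their interface.
#'
#' @param instance_map `H x W` non-negative integer label matrix.
#' @param thickness Positive integer erosion depth (default 1).
#' @return `H x W` binary (0/1) integer matrix.
#' @export
derive_boundary_map <- function(instance_map, thickness = 1L) {
  if (!is.matrix(instance_map) || any(instance_map != round(instance_map)) ||
      any(instance_map < 0))
    stop_input("instance_map must be a non-negative integer matrix")
  if (length(thickness) != 1L || thickness < 1 || thickness != round(thickness))
    stop_input("thickness must be a positive integer")
  m <- instance_map
  fg <- m > 0
  safe <- fg
  for (t in seq_len(thickness)) {
    nxt <- safe
    for (k in seq_len(nrow(NEIGH8))) {
      same <- shift2d(m, NEIGH8[k, 1], NEIGH8[k, 2], fill = -1L) == m
      nsafe <- shift2d(safe, NEIGH8[k, 1], NEIGH8[k, 2], fill = FALSE)
      nxt <- nxt & same & nsafe
    }
    safe <- nxt
  }
  out <- matrix(0L, nrow(m), ncol(m))
  out[fg & !safe] <- 1L
  out
}

#' Derive the (C+2)-channel training targets of a scene
#'
#' Builds the per-channel binary supervision maps: one channel per nuclei
#' category holding the interior pixels (instance pixels minus boundary) of
#' instances of that category, a background channel equal to
#' `instance_map == 0`, and a boundary channel from [derive_boundary_map()].
#'
#' @param scene A [nuclei_scene()].
#' @param categories A [category_set()]; defaults to the scene's.
#' @param thickness Boundary thickness passed to [derive_boundary_map()].
#' @return A list of class `channel_targets` with `maps` (`H x W x (C+2)`
#'   0/1 array) and `present_classes` (integer vector of category indices
#'   with at least one instance).
#' @export
derive_channel_targets <- function(scene, categories = scene$categories,
                                   thickness = 1L) {
  m <- scene$instance_map
  C <- categories$C
  if (length(scene$classes) && max(scene$classes) > C)
    stop_input("scene class index exceeds category count")
  H <- nrow(m); W <- ncol(m)
  maps <- array(0L, c(H, W, C + 2L))
  bnd <- derive_boundary_map(m, thickness)
  interior <- (m > 0) & (bnd == 0L)
  if (length(scene$classes)) {
    class_of <- scene$classes
    for (c in seq_len(C)) {
      ids <- as.integer(names(class_of)[class_of == c])
      if (length(ids)) {
        ch <- matrix(0L, H, W)
        ch[interior & (m %in% ids)] <- 1L
        maps[, , c] <- ch
      }
    }
  }
  bgc <- matrix(0L, H, W); bgc[m == 0] <- 1L
  maps[, , C + 1L] <- bgc
  maps[, , C + 2L] <- bnd
  present <- sort(unique(as.integer(scene$classes)))
  structure(list(maps = maps, present_classes = present),
            class = "channel_targets")
}

#' Write a scene to disk and read it back
#'
#' A scene is stored as three files sharing a stem: `<stem>_image.png`
#' (8-bit RGB), `<stem>_labels.tiff` (16-bit grayscale instance labels) and
#' `<stem>_classes.csv` (`instance_id,category`). The roundtrip is
#' bit-exact; instance ids above 65535 exceed the 16-bit label format.
#'
#' @param scene A [nuclei_scene()].
#' @param stem Path stem (directory must exist).
#' @return `scene_write` returns the stem invisibly; `scene_read` returns
#'   the reconstructed [nuclei_scene()].
#' @export
scene_write <- function(scene, stem) {
  validate_scene(scene)
  if (length(scene$classes) && max(as.integer(names(scene$classes))) > 65535L)
    stop_input("instance id exceeds 16-bit label format capacity")
  png::writePNG(scene$image / 255, paste0(stem, "_image.png"))
  tiff::writeTIFF(scene$instance_map / 65535, paste0(stem, "_labels.tiff"),
                  bits.per.sample = 16L, compression = "none")
  df <- data.frame(
    instance_id = as.integer(names(scene$classes)),
    category = scene$categories$names[scene$classes]
  )
  df <- df[order(df$instance_id), , drop = FALSE]
  utils::write.csv(df, paste0(stem, "_classes.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname scene_write
#' @param categories A [category_set()] used to decode category names.
#' @export
scene_read <- function(stem, categories = category_set()) {
  img <- png::readPNG(paste0(stem, "_image.png"))
  img <- round(img * 255)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  img <- img[, , 1:3, drop = FALSE]
  lab <- tiff::readTIFF(paste0(stem, "_labels.tiff"))
  lab <- matrix(as.integer(round(lab * 65535)), nrow(lab), ncol(lab))
  df <- utils::read.csv(paste0(stem, "_classes.csv"),
                        colClasses = c("integer", "character"))
  idx <- match(df$category, categories$names)
  if (anyNA(idx)) stop_input("unknown category name in class table")
  classes <- stats::setNames(as.integer(idx), as.character(df$instance_id))
  nuclei_scene(img, lab, classes, categories)
}

# Instance centroids in 0-based (x, y) pixel coordinates.
instance_centroids <- function(instance_map) {
  ids <- sort(unique(as.integer(instance_map[instance_map > 0])))
  if (!length(ids))
    return(data.frame(id = integer(), x = numeric(), y = numeric()))
  w <- which(instance_map > 0, arr.ind = TRUE)
  lab <- instance_map[w]
  xs <- tapply(w[, 2] - 1, lab, mean)
  ys <- tapply(w[, 1] - 1, lab, mean)
  data.frame(id = as.integer(names(xs)), x = as.numeric(xs), y = as.numeric(ys))
}
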