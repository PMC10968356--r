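# COCO-JSON interop: export of ground truth and scored detections with
# uncompressed RLE masks (COCO column-major run-length order).

rle_counts <- function(mask) {
  v <- as.integer(mask > 0)            # R matrices are column-major = COCO order
  r <- rle(v)
  counts <- r$lengths
  if (r$values[1] == 1L) counts <- c(0L, counts)
  as.integer(counts)
}

mask_bbox <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (!nrow(w)) return(c(0, 0, 0, 0))
  c(min(w[, 2]) - 1L, min(w[, 1]) - 1L,
    max(w[, 2]) - min(w[, 2]) + 1L, max(w[, 1]) - min(w[, 1]) + 1L)
}

#' Export scenes / predictions to COCO-JSON
#'
#' Writes ground-truth instances (`coco_export_gt`) or scored detections
#' (`coco_export_detections`) in the standard COCO instance-segmentation
#' JSON layout with uncompressed RLE segmentation masks, for interop with
#' external COCO evaluators.
#'
#' @param scenes List of [nuclei_scene()] objects.
#' @param path Output JSON file.
#' @param categories A [category_set()].
#' @return `path`, invisibly.
#' @export
coco_export_gt <- function(scenes, path, categories = category_set()) {
  anns <- list(); aid <- 0L
  images <- lapply(seq_along(scenes), function(i) {
    m <- scenes[[i]]$instance_map
    list(id = i, height = nrow(m), width = ncol(m),
         file_name = sprintf("scene_%04d.png", i))
  })
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    for (id in as.integer(names(sc$classes))) {
      aid <- aid + 1L
      mask <- sc$instance_map == id
      anns[[aid]] <- list(
        id = aid, image_id = i,
        category_id = as.integer(sc$classes[[as.character(id)]]),
        segmentation = list(size = dim(mask), counts = rle_counts(mask)),
        area = sum(mask), bbox = mask_bbox(mask), iscrowd = 0L
      )
    }
  }
  cats <- lapply(seq_len(categories$C), function(c)
    list(id = c, name = categories$names[c]))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname coco_export_gt
#' @param preds List of [instance_prediction()] objects.
#' @export
coco_export_detections <- function(preds, path, categories = category_set()) {
  dets <- list(); k <- 0L
  for (i in seq_along(preds)) {
    pr <- preds[[i]]
    for (id in as.integer(names(pr$classes))) {
      k <- k + 1L
      mask <- pr$instance_map == id
      dets[[k]] <- list(
        image_id = i,
        category_id = as.integer(pr$classes[[as.character(id)]]),
        segmentation = list(size = dim(mask), counts = rle_counts(mask)),
        score = as.numeric(pr$scores[[as.character(id)]]),
        bbox = mask_bbox(mask)
      )
    }
  }
  jsonlite::write_json(dets, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read an instance prediction in the package label formats
#'
#' Stores the instance map as 16-bit TIFF and the class/score table as CSV
#' (`instance_id,category,score`).
#'
#' @param pred An [instance_prediction()].
#' @param stem File stem, as in [scene_write()].
#' @export
prediction_write <- function(pred, stem) {
  tiff::writeTIFF(pred$instance_map / 65535, paste0(stem, "_labels.tiff"),
                  bits.per.sample = 16L, compression = "none")
  ids <- as.integer(names(pred$classes))
  df <- data.frame(instance_id = ids,
                   category = pred$categories$names[pred$classes],
                   score = as.numeric(pred$scores))
  utils::write.csv(df[order(df$instance_id), , drop = FALSE],
                   paste0(stem, "_classes.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname prediction_write
#' @param categories A [category_set()].
#' @export
prediction_read <- function(stem, categories = category_set()) {
  lab <- tiff::readTIFF(paste0(stem, "_labels.tiff"))
  lab <- matrix(as.integer(round(lab * 65535)), nrow(lab), ncol(lab))
  df <- utils::read.csv(paste0(stem, "_classes.csv"))
  idx <- match(df$category, categories$names)
  nm <- as.character(df$instance_id)
  instance_prediction(lab, stats::setNames(as.integer(idx), nm),
                      stats::setNames(as.numeric(df$score %||% 1), nm),
                      categories)
}
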