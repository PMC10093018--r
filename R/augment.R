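#' Rotate an image by a multiple of 90 degrees (clockwise)
#'
#' Lossless: pixels are permuted, never resampled; non-square images swap
#' height and width for 90/270 degrees.
#'
#' @param img an [intensity_image()].
#' @param degrees one of 0, 90, 180, 270.
#' @return an [intensity_image()].
#' @export
rotate90 <- function(img, degrees) {
  if (!(degrees %in% c(0, 90, 180, 270))) stop("degrees must be 0/90/180/270")
  a <- im_array_any(img)
  rot_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(degrees / 90)) {
    d <- dim(a)
    out <- array(0, c(d[2], d[1], d[3]))
    for (c in seq_len(d[3])) out[, , c] <- rot_cw(a[, , c])
    a <- out
  }
  intensity_image(a)
}

#' Flip an image left-right
#'
#' @param img an [intensity_image()].
#' @return an [intensity_image()].
#' @export
flip_lr <- function(img) {
  a <- im_array_any(img)
  intensity_image(a[, ncol(a[, , 1L]):1, , drop = FALSE])
}

#' Eightfold rotation/flip augmentation of one image
#'
#' Returns the four rotations (0, 90, 180, 270 degrees) of the input plus
#' the left-right flip of each rotation: exactly 8 images, each a pure
#' pixel permutation of the source.
#'
#' @param image an [intensity_image()].
#' @return a list of 8 [intensity_image()]s with attributes `rotation` and
#'   `flipped` recorded in the parallel `provenance` attribute
#'   (a data.frame with columns rotation, flipped).
#' @export
augment_image <- function(image) {
  img <- intensity_image(im_array_any(image))
  rots <- c(0, 90, 180, 270)
  out <- vector("list", 8L)
  prov <- data.frame(rotation = rep(rots, 2L),
                     flipped = rep(c(FALSE, TRUE), each = 4L))
  for (i in seq_along(rots)) {
    r <- rotate90(img, rots[i])
    out[[i]] <- r
    out[[i + 4L]] <- flip_lr(r)
  }
  attr(out, "provenance") <- prov
  out
}

#' Augment a labelled image set eightfold
#'
#' Applies [augment_image()] to every source image; every augmented image
#' carries its source's label and full provenance (source index, rotation,
#' flip). Output size is exactly 8x the input size (plus the originals when
#' `include_originals` is set, recorded with rotation NA).
#'
#' @param images list of [intensity_image()]s.
#' @param labels vector of class labels, one per image.
#' @param include_originals also append the untouched source images.
#' @return a list of class `augmented_set` with elements `images` (list),
#'   `labels` (vector) and `provenance` (data.frame with columns
#'   source_index, rotation, flipped, label).
#' @export
augment_dataset <- function(images, labels, include_originals = FALSE) {
  if (length(images) != length(labels))
    stop("images and labels must have the same length")
  out_images <- list()
  prov <- NULL
  for (i in seq_along(images)) {
    aug <- augment_image(images[[i]])
    p <- attr(aug, "provenance")
    p$source_index <- i
    p$label <- labels[i]
    out_images <- c(out_images, aug)
    prov <- rbind(prov, p)
  }
  if (include_originals && length(images)) {
    out_images <- c(out_images, images)
    prov <- rbind(prov, data.frame(
      rotation = NA_real_, flipped = NA,
      source_index = seq_along(images), label = labels))
  }
  if (is.null(prov))
    prov <- data.frame(rotation = numeric(), flipped = logical(),
                       source_index = integer(), label = labels[0])
  structure(list(images = out_images,
                 labels = prov$label,
                 provenance = prov[, c("source_index", "rotation", "flipped", "label")]),
            class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("<augmented_set: %d images, %d classes>\n",
              length(x$images), length(unique(x$labels))))
  invisible(x)
}
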