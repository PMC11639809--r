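#' Filter instance detections by certainty score
#'
#' Keeps instances whose detector certainty is strictly above the threshold
#' ("above 0.75" is read as a strict comparison, so 0.75 itself is dropped).
#' Order is preserved; an empty result is allowed.
#'
#' @param instances list of [instance_mask] objects.
#' @param min_certainty retention threshold, default 0.75.
#' @return The retained sub-list.
#' @export
filter_detections <- function(instances, min_certainty = 0.75) {
  keep <- vapply(instances, function(m) m$certainty > min_certainty, logical(1))
  if (length(instances) > 0L && !any(keep)) {
    message("filter_detections: no instance above certainty ", min_certainty)
  }
  instances[keep]
}

#' Segmentation quality score
#'
#' @param iou_bbox,iou_mask,certainty values in `[0, 1]`.
#' @return An object of class `segmentation_score`.
#' @export
segmentation_score <- function(iou_bbox, iou_mask = NA_real_, certainty = NA_real_) {
  vals <- c(iou_bbox = iou_bbox, iou_mask = iou_mask, certainty = certainty)
  ok <- is.na(vals) | (vals >= 0 & vals <= 1)
  if (!all(ok)) stop_input("segmentation scores must lie in [0, 1]",
                           "ovirr_parameter_error")
  structure(as.list(vals), class = "segmentation_score")
}

#' Intersection over union (Jaccard index)
#'
#' `iou = |A intersect B| / |A union B|` for two binary masks of identical
#' dimensions, or for two axis-aligned boxes given as `c(x0, y0, x1, y1)` in
#' half-open pixel coordinates `[x0, x1) x [y0, y1)`.
#'
#' @param a,b binary matrices, [instance_mask]s, or length-4 box vectors
#'   (both arguments of the same kind).
#' @return The IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (inherits(a, "instance_mask")) a <- a$mask
  if (inherits(b, "instance_mask")) b <- b$mask
  if (is.matrix(a) && is.matrix(b)) {
    if (!all(dim(a) == dim(b))) {
      stop_input("masks must have identical dimensions", "ovirr_format_error")
    }
    af <- a != 0; bf <- b != 0
    uni <- sum(af | bf)
    if (uni == 0L) stop_input("IoU undefined: both masks empty",
                              "ovirr_undefined_input")
    return(sum(af & bf) / uni)
  }
  if (length(a) == 4L && length(b) == 4L) {
    area <- function(bx) max(0, bx[3] - bx[1]) * max(0, bx[4] - bx[2])
    ia <- area(a); ib <- area(b)
    if (ia == 0 && ib == 0) stop_input("IoU undefined: both boxes empty",
                                       "ovirr_undefined_input")
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    return(inter / (ia + ib - inter))
  }
  stop_input("iou expects two masks or two boxes of the same kind",
             "ovirr_format_error")
}

#' Is a detection valid by bounding-box IoU?
#'
#' A detection counts as a valid ROI when its bounding-box IoU against the
#' annotation is strictly above the threshold (default 80%).
#'
#' @param score a [segmentation_score] (or a plain number taken as the
#'   bounding-box IoU).
#' @param iou_threshold default 0.80.
#' @return Logical.
#' @export
valid_detection <- function(score, iou_threshold = 0.80) {
  v <- if (inherits(score, "segmentation_score")) score$iou_bbox else score
  isTRUE(v > iou_threshold)
}

#' Multiply a frame by a binary mask
#'
#' Returns the frame where the mask is nonzero and 0 elsewhere, confining
#' all later processing to the segmented thorax.
#'
#' @param frame grayscale matrix or RGB array.
#' @param mask binary matrix (or [instance_mask]) of the same height/width.
#' @return The masked frame.
#' @export
apply_mask <- function(frame, mask) {
  if (inherits(mask, "instance_mask")) mask <- mask$mask
  d <- dim(frame)
  if (!all(d[1:2] == dim(mask))) {
    stop_input("frame and mask dimensions differ", "ovirr_format_error")
  }
  if (length(d) == 3L) {
    for (k in seq_len(d[3])) frame[, , k] <- frame[, , k] * (mask != 0)
    frame
  } else {
    frame * (mask != 0)
  }
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Balances gray levels within an `tile[1] x tile[2]` grid of blocks so that
#' corners, edges and wool texture become trackable in both bright RGB and
#' dim NIR footage. Thin wrapper over `EBImage::clahe()`; deterministic,
#' output clipped to `[0, 255]`.
#'
#' @param frame 8-bit grayscale matrix.
#' @param tile number of blocks (nx, ny); default `c(8, 8)`.
#' @param clip contrast limiting factor; default 2.
#' @return The enhanced matrix, same dimensions, values in `[0, 255]`.
#' @export
enhance <- function(frame, tile = c(8, 8), clip = 2.0) {
  if (!is.matrix(frame)) frame <- as_gray(frame)
  if (ncol(frame) < 2 * tile[1] || nrow(frame) < 2 * tile[2]) {
    stop_input("tile grid too fine for this image", "ovirr_parameter_error")
  }
  img <- EBImage::Image(t(frame) / 255)
  out <- EBImage::clahe(img, nx = tile[1], ny = tile[2], limit = clip)
  res <- t(EBImage::imageData(out)) * 255
  pmin(pmax(res, 0), 255)
}

#' Split a thorax mask into three regions along its long axis
#'
#' The mask's axis-aligned bounding box is cut perpendicular to its longer
#' side into three equal-width bands: R1 is the deepest abdominal band, R2
#' the middle, R3 the band nearest the head. Which end is abdominal is a
#' caller decision (`orientation`), default `"r1_left"` (top when the long
#' axis is vertical). The three bands partition the mask exactly.
#'
#' @param mask binary matrix or [instance_mask].
#' @param orientation `"r1_left"` or `"r1_right"`.
#' @return A named list of `region_spec` objects: `total`, `r1`, `r2`, `r3`.
#' @export
split_regions <- function(mask, orientation = c("r1_left", "r1_right")) {
  orientation <- match.arg(orientation)
  m <- if (inherits(mask, "instance_mask")) mask$mask else (mask != 0) * 1L
  if (sum(m) == 0L) stop_input("mask has no foreground", "ovirr_parameter_error")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  height <- rows[2] - rows[1] + 1L
  width <- cols[2] - cols[1] + 1L
  along_x <- width >= height
  extent <- if (along_x) width else height
  if (extent < 3L) stop_input("mask thinner than 3 pixels along its long axis",
                              "ovirr_parameter_error")
  lo <- if (along_x) cols[1] else rows[1]
  cut1 <- lo + floor(extent / 3) - 1L
  cut2 <- lo + floor(2 * extent / 3) - 1L
  band_of <- function(i1, i2) {
    bm <- matrix(0L, nrow(m), ncol(m))
    if (along_x) bm[, i1:i2] <- 1L else bm[i1:i2, ] <- 1L
    bm * m
  }
  bands <- list(band_of(lo, cut1), band_of(cut1 + 1L, cut2),
                band_of(cut2 + 1L, lo + extent - 1L))
  if (orientation == "r1_right") bands <- rev(bands)
  region <- function(name, bm) structure(list(name = name, mask = bm),
                                         class = "region_spec")
  list(total = region("total", m), r1 = region("r1", bands[[1]]),
       r2 = region("r2", bands[[2]]), r3 = region("r3", bands[[3]]))
}
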