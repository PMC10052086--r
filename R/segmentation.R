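#' Coerce to a binary segmentation mask
#'
#' A `seg_mask` is a logical matrix (`TRUE` = lettuce, `FALSE` = background)
#' with a provenance tag (`"classical"`, `"external"` or `"ground-truth"`).
#' Numeric input is thresholded at > 0 (the 0/255 PNG convention).
#'
#' @param x logical or numeric matrix.
#' @param provenance provenance tag to attach (kept if already present).
#' @return A `seg_mask`.
#' @export
as_seg_mask <- function(x, provenance = NULL) {
  if (inherits(x, "seg_mask") && is.null(provenance)) return(x)
  stopifnot(is.matrix(x))
  prov <- provenance %||% attr(x, "provenance") %||% "external"
  m <- if (is.logical(x)) x else x > 0
  structure(m, class = c("seg_mask", "matrix"), provenance = prov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Excess-green canopy segmentation
#'
#' A classical colour-index segmenter used as the package's built-in
#' baseline: a pixel is lettuce when its excess-green index `2G - R - B`
#' (8-bit channel scale) exceeds a threshold. The fixed default of 20
#' separates green canopy from grey/soil background; `threshold = "otsu"`
#' instead picks the threshold automatically from the bimodal index
#' histogram. Masks from any external (e.g. learned) segmenter can be used
#' everywhere downstream instead -- see [read_mask()].
#'
#' @param rgb numeric array `rows x cols x 3`, channels 0..255 (values in
#'   0..1 are auto-scaled by 255).
#' @param threshold numeric index threshold (default 20) or `"otsu"`.
#' @return A `seg_mask` with provenance `"classical"` and the threshold
#'   used stored as attribute `threshold`.
#' @export
exg_segment <- function(rgb, threshold = 20) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("exg_segment needs a 3-channel RGB image")
  if (max(rgb, na.rm = TRUE) <= 1) rgb <- rgb * 255
  exg <- 2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
  if (identical(threshold, "otsu")) {
    # rescale the index to [0,1] for EBImage's Otsu, then map back
    rng <- range(exg)
    if (diff(rng) < .Machine$double.eps) {
      threshold <- rng[1]  # flat image: single class
    } else {
      t01 <- EBImage::otsu(EBImage::Image((exg - rng[1]) / diff(rng)),
                           range = c(0, 1))
      threshold <- rng[1] + t01 * diff(rng)
    }
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  m <- as_seg_mask(exg > threshold, provenance = "classical")
  attr(m, "threshold") <- threshold
  m
}

#' Canopy coverage of a mask
#'
#' The percentage of the imaged ground area covered by lettuce: the number
#' of lettuce pixels divided by the total number of pixels, times 100.
#'
#' @param mask a [as_seg_mask()]-coercible binary mask.
#' @return Coverage in percent (0--100).
#' @export
coverage <- function(mask) {
  mask <- as_seg_mask(mask)
  if (length(mask) == 0) stop("empty mask has no coverage")
  100 * sum(mask) / length(mask)
}

#' Mean intersection-over-union of two masks
#'
#' The mean of the per-class IoU of the lettuce class and the background
#' class. A class absent from both prediction and ground truth contributes
#' IoU 1 (the 0/0 case is taken as perfect agreement, which makes the
#' metric total and keeps `miou(x, x) == 1` for any mask).
#'
#' @param pred,gt binary masks of identical size.
#' @return mIoU as a fraction in `[0, 1]`; multiply by 100 for the percent
#'   scale.
#' @export
miou <- function(pred, gt) {
  pred <- as_seg_mask(pred)
  gt <- as_seg_mask(gt)
  if (!all(dim(pred) == dim(gt)))
    stop("prediction and ground truth must have identical shapes")
  iou_class <- function(p, g) {
    uni <- sum(p | g)
    if (uni == 0) 1 else sum(p & g) / uni
  }
  (iou_class(pred, gt) + iou_class(!pred, !gt)) / 2
}
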