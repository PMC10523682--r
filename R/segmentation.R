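#' Build the watershed relief of a calibrated image
#'
#' Brightfield: the RGB image is converted to grayscale luminance and a 3x3
#' morphological gradient (dilation minus erosion, box structuring element)
#' is taken, so that the pale boundary network between the reddish myocytes
#' becomes a ridge system. An optional Gaussian pre-blur can suppress pixel
#' noise before the gradient; it is off by default.
#'
#' Fluorescence: the membrane (WGA) channel is already a ridge image -- cell
#' outlines are bright -- and is passed through unchanged.
#'
#' @param image A [calibrated_image()].
#' @param blur_sigma Optional Gaussian sigma in pixels applied before the
#'   gradient (brightfield only); `0` disables it.
#' @return Non-negative numeric matrix, same size as the image.
#' @export
build_relief <- function(image, blur_sigma = 0) {
  stopifnot(inherits(image, "calibrated_image"))
  if (image$height_px < 1 || image$width_px < 1) stop("empty image")
  if (image$modality == "fluorescence") {
    return(image$pixels[["membrane"]])
  }
  g <- luminance(image)
  if (blur_sigma > 0) {
    img <- EBImage::gblur(EBImage::Image(t(g) / 255), sigma = blur_sigma)
    g <- t(as.matrix(img)) * 255
  }
  cpp_morph_gradient3(g)
}

#' Tolerance-controlled watershed segmentation
#'
#' Seeds are the h-minima of the relief with dynamic `h = tolerance`:
#' regional minima whose depth below their lowest saddle exceeds the
#' tolerance survive as markers, shallower minima are merged (computed by
#' morphological reconstruction by erosion of `relief + tolerance` above
#' `relief`). A marker-controlled flood (Meyer's algorithm, 4-connected
#' basins, FIFO order among equal relief values so the result is
#' deterministic) then grows one basin per marker; pixels reached
#' simultaneously by two basins become watershed-line pixels with label 0.
#' Labels are renumbered 1..n in raster order of each basin's first pixel.
#'
#' Raising the tolerance can only merge basins, so the number of labels is
#' non-increasing in `tolerance`. A flat relief yields a single region.
#'
#' @param relief Non-negative numeric matrix (no NAs).
#' @param tolerance Non-negative dynamic in relief intensity units.
#' @return Integer label matrix (class `label_map`): 0 = watershed line,
#'   positive labels are consecutive from 1. Attribute `n_labels` holds the
#'   region count.
#' @export
watershed_segment <- function(relief, tolerance = 0) {
  if (!is.matrix(relief)) relief <- as.matrix(relief)
  if (anyNA(relief)) stop("relief contains NA/NaN")
  if (length(relief) == 0) stop("empty relief")
  if (tolerance < 0) stop("tolerance must be >= 0")
  hmin <- if (tolerance > 0) {
    cpp_reconstruct_erosion(relief + tolerance, relief, 4L)
  } else {
    relief
  }
  seeds <- cpp_regional_minima(hmin, 4L)
  lab <- cpp_ws_flood(hmin, seeds)
  lab <- cpp_relabel_raster(lab)
  structure(lab, n_labels = max(lab), class = c("label_map", class(lab)))
}

#' Number of labels in a label map
#' @param labels Label matrix.
#' @return Integer count of distinct positive labels.
#' @export
n_labels <- function(labels) {
  nl <- attr(labels, "n_labels")
  if (is.null(nl)) nl <- length(setdiff(unique(as.vector(labels)), 0L))
  as.integer(nl)
}

#' Merge user-supplied correction lines into a segmentation
#'
#' Missing boundaries can be painted by the analyst as a binary line mask
#' (same size as the image; in files, white = line). The relief is raised
#' above its maximum value (by the tolerance plus one intensity unit) along
#' the mask and the watershed is re-run with the same tolerance, so a line
#' that fully bisects a basin always splits it in two; an incomplete cut
#' leaves the region count unchanged.
#'
#' @param labels Previous label map (only used for dimension checking).
#' @param relief The relief the labels were computed from.
#' @param line_mask Logical/0-1 matrix of manual line pixels.
#' @param tolerance Watershed tolerance to re-apply.
#' @return New label map from [watershed_segment()].
#' @export
merge_manual_lines <- function(labels, relief, line_mask, tolerance) {
  if (!all(dim(labels) == dim(line_mask)) ||
      !all(dim(relief) == dim(line_mask)))
    stop("line_mask dimensions differ from labels/relief")
  r2 <- relief
  # strictly above the global maximum plus the tolerance, so a complete
  # cut always forms a barrier whatever the dynamic
  r2[line_mask > 0] <- max(relief) + tolerance + 1
  watershed_segment(r2, tolerance)
}

#' Suggest a watershed tolerance by sweeping the dynamic
#'
#' Reports the number of segmented regions for each candidate tolerance so
#' the analyst can pick a plateau. This keeps tolerance an explicit,
#' user-owned choice while making the choice informed.
#'
#' @param relief Relief matrix.
#' @param tolerances Numeric vector of candidate dynamics.
#' @return Data frame with columns `tolerance`, `n_labels`.
#' @export
suggest_tolerance <- function(relief, tolerances = seq(0, 100, by = 10)) {
  data.frame(
    tolerance = tolerances,
    n_labels = vapply(tolerances,
                      function(h) n_labels(watershed_segment(relief, h)), 0L)
  )
}
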