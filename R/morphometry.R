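#' Calibrated instance area
#'
#' Area is pixel count times the square of the calibration. Threshold
#' comparisons elsewhere in the pipeline are inclusive, so e.g. 240 pixels
#' at 0.5 um/px give exactly 60 um^2 and pass a 60 um^2 minimum.
#'
#' @param labels Label matrix.
#' @param instance_id Positive label.
#' @param microns_per_pixel Positive calibration.
#' @return Area in um^2.
#' @export
measure_area <- function(labels, instance_id, microns_per_pixel) {
  stopifnot(microns_per_pixel > 0)
  n <- sum(labels == instance_id)
  if (n == 0) stop("unknown instance: ", instance_id)
  n * microns_per_pixel^2
}

# Corner points (x, y) of the unit squares of a set of pixels given as
# (row, col) 1-based matrix indices; 0-based geometry, y downward.
.pixel_corners <- function(rc) {
  x <- rc[, 2] - 1; y <- rc[, 1] - 1
  cbind(x = c(x, x + 1, x, x + 1), y = c(y, y, y + 1, y + 1))
}

# Rotating-calipers Feret diameters of a point set (already in um or px).
# Returns c(max, min, angle_deg_of_min_width_direction).
.feret_of_points <- function(pts) {
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE] # counter-clockwise in plot coords
  n <- nrow(hp)
  if (n == 1) return(c(0, 0, 0))
  d <- as.matrix(stats::dist(hp))
  fmax <- max(d)
  if (n == 2) return(c(fmax, 0, 0))
  # min over hull edges of the width perpendicular to the edge
  nx <- hp[c(2:n, 1), 1] - hp[, 1]
  ny <- hp[c(2:n, 1), 2] - hp[, 2]
  len <- sqrt(nx^2 + ny^2)
  ok <- len > 0
  fmin <- Inf; angle <- 0
  for (i in which(ok)) {
    ux <- -ny[i] / len[i]; uy <- nx[i] / len[i] # unit normal to edge i
    proj <- hp[, 1] * ux + hp[, 2] * uy
    w <- max(proj) - min(proj)
    if (w < fmin) {
      fmin <- w
      angle <- (atan2(ny[i], nx[i]) * 180 / pi) %% 180
    }
  }
  c(fmax, fmin, angle)
}

#' Feret diameters of an instance
#'
#' Pixels are modelled as unit squares; the convex hull of all pixel corner
#' points is computed, the maximum Feret diameter is the largest pairwise
#' hull-vertex distance and the minimum Feret diameter (MinFeret) is found
#' by rotating calipers: the smallest width over directions perpendicular to
#' hull edges. The unit-square model means a single pixel has MinFeret 1 px
#' and MaxFeret sqrt(2) px, and no instance ever has zero width. MinFeret is
#' the preferred size measure for cardiomyocytes because, unlike area, it is
#' largely independent of the angle at which an elongated cell is cut.
#'
#' @param labels Label matrix.
#' @param instance_id Positive label.
#' @param microns_per_pixel Positive calibration.
#' @return Named numeric vector `feret_max_um`, `feret_min_um`,
#'   `min_feret_angle_deg` (direction of the object's long axis at minimal
#'   width, degrees in [0, 180)).
#' @export
feret_diameters <- function(labels, instance_id, microns_per_pixel) {
  stopifnot(microns_per_pixel > 0)
  rc <- which(labels == instance_id, arr.ind = TRUE)
  if (nrow(rc) == 0) stop("unknown instance: ", instance_id)
  f <- .feret_of_points(.pixel_corners(rc))
  c(feret_max_um = f[1] * microns_per_pixel,
    feret_min_um = f[2] * microns_per_pixel,
    min_feret_angle_deg = f[3])
}

#' Does an instance touch the image border?
#'
#' True iff any pixel of the instance lies in the first/last row or column.
#' Diagonal adjacency to a border pixel does not count; the rule is pixel
#' membership.
#'
#' @param labels Label matrix.
#' @param instance_id Positive label.
#' @return Logical.
#' @export
touches_border <- function(labels, instance_id) {
  rc <- which(labels == instance_id, arr.ind = TRUE)
  if (nrow(rc) == 0) stop("unknown instance: ", instance_id)
  any(rc[, 1] == 1L | rc[, 1] == nrow(labels) |
      rc[, 2] == 1L | rc[, 2] == ncol(labels))
}

#' Measure all instances of a label map
#'
#' Computes the full calibrated record for every positive label: area,
#' max/min Feret diameter, centroid (unweighted mean of pixel centres, um,
#' origin at the top-left pixel centre, y downward), border contact and
#' pixel count.
#'
#' @param labels Label matrix.
#' @param microns_per_pixel Positive calibration.
#' @return Data frame with one row per instance, ordered by `instance_id`.
#' @export
measure_instances <- function(labels, microns_per_pixel) {
  stopifnot(microns_per_pixel > 0)
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  bylab <- split(seq_along(idx), lab)
  mpp <- microns_per_pixel
  recs <- lapply(ids, function(id) {
    sel <- bylab[[as.character(id)]]
    r <- rows[sel]; cc <- cols[sel]
    f <- .feret_of_points(.pixel_corners(cbind(r, cc)))
    data.frame(
      instance_id = id,
      area_um2 = length(sel) * mpp^2,
      feret_max_um = f[1] * mpp,
      feret_min_um = f[2] * mpp,
      min_feret_angle_deg = f[3],
      centroid_x_um = mean(cc - 1) * mpp,
      centroid_y_um = mean(r - 1) * mpp,
      touches_border = any(r == 1L | r == nr | cc == 1L | cc == nc),
      pixel_count = length(sel)
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
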