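#' Convert RGB components to hue/saturation/brightness
#'
#' Standard hexcone HSB: hue in degrees [0, 360), saturation and brightness
#' in percent. Achromatic pixels get hue 0 with saturation 0. Vectorised.
#'
#' @param r,g,b Numeric vectors in [0, 255].
#' @return Data frame with columns `hue`, `saturation`, `brightness`.
#' @export
rgb_to_hsb <- function(r, g, b) {
  if (any(c(r, g, b) < 0) || any(c(r, g, b) > 255))
    stop("RGB components must lie in [0, 255]")
  r1 <- r / 255; g1 <- g / 255; b1 <- b / 255
  mx <- pmax(r1, g1, b1); mn <- pmin(r1, g1, b1)
  delta <- mx - mn
  hue <- numeric(length(mx))
  nz <- delta > 0
  i_r <- nz & mx == r1
  i_g <- nz & mx == g1 & !i_r
  i_b <- nz & mx == b1 & !i_r & !i_g
  hue[i_r] <- 60 * (((g1[i_r] - b1[i_r]) / delta[i_r]) %% 6)
  hue[i_g] <- 60 * ((b1[i_g] - r1[i_g]) / delta[i_g] + 2)
  hue[i_b] <- 60 * ((r1[i_b] - g1[i_b]) / delta[i_b] + 4)
  sat <- ifelse(mx > 0, delta / mx, 0) * 100
  data.frame(hue = hue %% 360, saturation = sat, brightness = mx * 100)
}

#' Does an instance's colour fall in the HSB window?
#'
#' The instance's colour is summarised by the per-channel medians of hue,
#' saturation and brightness over its pixels (medians are robust to the
#' darker nucleus pixels inside a myocyte); the match requires all three
#' medians inside the window. The hue window is treated as non-wrapping:
#' with the default 240-360 degree window, a pure red hue of 0 does not
#' match, even though visually "reddish" -- tissue hues sit in the
#' magenta-to-red range just below 360.
#'
#' @param image Brightfield [calibrated_image()].
#' @param labels Label matrix.
#' @param instance_id Positive label.
#' @param hsb_range Length-6 vector as in [analysis_config()].
#' @return Logical.
#' @export
instance_color_match <- function(image, labels, instance_id, hsb_range) {
  idx <- which(labels == instance_id)
  if (!length(idx)) stop("empty instance: ", instance_id)
  np <- image$height_px * image$width_px
  hsb <- rgb_to_hsb(image$pixels[idx], image$pixels[idx + np],
                    image$pixels[idx + 2 * np])
  h <- median(hsb$hue); s <- median(hsb$saturation); b <- median(hsb$brightness)
  h >= hsb_range[1] && h <= hsb_range[2] &&
    s >= hsb_range[3] && s <= hsb_range[4] &&
    b >= hsb_range[5] && b <= hsb_range[6]
}

# filled footprint label matrix of the given CM ids (holes such as nuclei
# become part of the footprint)
.cm_footprints <- function(labels, cm_ids) {
  fp <- labels
  fp[!(fp %in% cm_ids)] <- 0L
  m <- EBImage::fillHull(t(fp))
  t(as.matrix(m))
}

#' Classify watershed instances of a Gomori silver image
#'
#' Applies the rule cascade of the brightfield pipeline, with every
#' instance receiving exactly one class:
#' \enumerate{
#'   \item \strong{cardiomyocyte}: colour medians inside the HSB window,
#'     area at least `cm_min_area_um2` (inclusive), and -- when
#'     `exclude_border_cm` -- not touching the image border.
#'   \item \strong{cm_nucleus}: a non-CM instance with at least half of its
#'     pixels inside the hole-filled footprint of a single cardiomyocyte and
#'     area within the nucleus window (6-100 um^2 by default).
#'   \item \strong{capillary}: an unstained instance (colour medians
#'     outside the HSB window -- capillary lumens carry no silver stain, so
#'     a stained fragment can never be a capillary, however small) outside
#'     all cardiomyocytes (zero overlap of the candidate's 1-px dilation
#'     with any filled CM footprint, so shared watershed-line borders do
#'     not count as overlap) with area within the capillary window
#'     (1.5-100 um^2 by default).
#'   \item \strong{removed}: everything else, with the failed rule recorded.
#' }
#'
#' @param image Brightfield [calibrated_image()].
#' @param labels Label matrix from [watershed_segment()].
#' @param config An [analysis_config()].
#' @return Data frame `instance_id`, `class`, `reason` covering every
#'   positive label exactly once.
#' @export
classify_gomori <- function(image, labels, config) {
  stopifnot(inherits(image, "calibrated_image"),
            image$modality == "brightfield",
            inherits(config, "analysis_config"))
  if (is.null(image$microns_per_pixel)) stop("calibration missing")
  meas <- measure_instances(labels, image$microns_per_pixel)
  ids <- meas$instance_id
  # per-instance colour medians, computed in one pass over the image
  np <- image$height_px * image$width_px
  idx_all <- which(labels > 0)
  lf <- factor(labels[idx_all], levels = ids)
  hsb <- rgb_to_hsb(image$pixels[idx_all], image$pixels[idx_all + np],
                    image$pixels[idx_all + 2 * np])
  medh <- vapply(split(hsb$hue, lf), median, 0)
  meds <- vapply(split(hsb$saturation, lf), median, 0)
  medb <- vapply(split(hsb$brightness, lf), median, 0)
  rg <- config$hsb_range
  cmatch <- medh >= rg[1] & medh <= rg[2] & meds >= rg[3] & meds <= rg[4] &
    medb >= rg[5] & medb <= rg[6]
  bylab <- split(idx_all, lf)
  big <- meas$area_um2 >= config$cm_min_area_um2
  interior <- if (config$exclude_border_cm) !meas$touches_border else TRUE
  is_cm <- cmatch & big & interior

  cls <- rep(NA_character_, length(ids))
  reason <- character(length(ids))
  cls[is_cm] <- "cardiomyocyte"
  reason[is_cm] <- "colour match, area >= minimum, interior"

  fp <- .cm_footprints(labels, ids[is_cm])
  nwin <- config$nucleus_area_um2
  cwin <- config$capillary_area_um2
  nr <- nrow(labels); nc <- ncol(labels)
  for (i in which(!is_cm)) {
    id <- ids[i]
    a <- meas$area_um2[i]
    idx <- bylab[[i]]
    fpl <- fp[idx]
    inside <- fpl[fpl > 0]
    frac_in <- if (length(inside)) max(table(inside)) / length(idx) else 0
    if (frac_in >= 0.5 && a >= nwin[1] && a <= nwin[2]) {
      cls[i] <- "cm_nucleus"
      reason[i] <- "within a cardiomyocyte, nucleus size window"
      next
    }
    # dilate candidate by 1 px (8-neighbourhood) before the overlap test
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    dr <- rep(rows, each = 9) + rep(c(-1L, 0L, 1L), times = 3)
    dc <- rep(cols, each = 9) + rep(c(-1L, 0L, 1L), each = 3)
    ok <- dr >= 1L & dr <= nr & dc >= 1L & dc <= nc
    didx <- unique((dc[ok] - 1L) * nr + dr[ok])
    outside <- !any(fp[didx] > 0)
    if (!cmatch[i] && outside && a >= cwin[1] && a <= cwin[2]) {
      cls[i] <- "capillary"
      reason[i] <- "unstained, outside all cardiomyocytes, capillary size window"
      next
    }
    cls[i] <- "removed"
    reason[i] <- if (cmatch[i] && big[i] && !interior[i]) {
      "cardiomyocyte at image border"
    } else if (cmatch[i] && !big[i]) {
      sprintf("stained but below %g um^2 cardiomyocyte minimum",
              config$cm_min_area_um2)
    } else if (frac_in >= 0.5) {
      "within a cardiomyocyte but outside nucleus size window"
    } else if (outside) {
      "outside cardiomyocytes but outside capillary size window"
    } else {
      "straddles a cardiomyocyte boundary; no class applies"
    }
  }
  data.frame(instance_id = ids, class = cls, reason = reason)
}
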