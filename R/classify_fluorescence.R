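#' Bundle fluorescence channels
#'
#' @param membrane WGA membrane intensity matrix (drives the watershed).
#' @param nuclei DAPI intensity matrix.
#' @param marker Optional third channel: CD31 (endothelium) or an
#'   intracellular expression marker such as pro-ANP.
#' @param marker_role `"endothelium"` or `"intracellular_expression"`;
#'   required when `marker` is present.
#' @param microns_per_pixel Positive calibration.
#' @return A `channel_set`.
#' @export
channel_set <- function(membrane, nuclei = NULL, marker = NULL,
                        marker_role = c("endothelium",
                                        "intracellular_expression"),
                        microns_per_pixel = 1) {
  if (!is.null(marker)) marker_role <- match.arg(marker_role)
  else marker_role <- NA_character_
  mats <- Filter(Negate(is.null),
                 list(membrane = membrane, nuclei = nuclei, marker = marker))
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("channel dimensions differ")
  stopifnot(microns_per_pixel > 0)
  structure(list(membrane = membrane, nuclei = nuclei, marker = marker,
                 marker_role = marker_role,
                 microns_per_pixel = microns_per_pixel),
            class = "channel_set")
}

#' Convert a fluorescence calibrated image to a channel set
#' @param image A fluorescence [calibrated_image()] whose channels include
#'   `membrane` and optionally `nuclei` and `marker`.
#' @param marker_role Role of the marker channel, if present.
#' @return A [channel_set()].
#' @export
as_channel_set <- function(image, marker_role = "endothelium") {
  stopifnot(inherits(image, "calibrated_image"),
            image$modality == "fluorescence")
  channel_set(image$pixels[["membrane"]], image$pixels[["nuclei"]],
              image$pixels[["marker"]], marker_role,
              image$microns_per_pixel)
}

#' Global automatic threshold of an intensity channel
#'
#' `"otsu"` (default) maximises the between-class variance over a 256-bin
#' histogram; `"isodata"` iterates the threshold to the midpoint of the two
#' class means (the classic ImageJ default method). Both return a global
#' threshold; pixels strictly above it form the foreground.
#'
#' @param channel Numeric matrix (any range; internally scaled to [0, 1]).
#' @param method `"otsu"` or `"isodata"`.
#' @return Logical foreground mask with attribute `"threshold"` (on the
#'   original intensity scale).
#' @export
auto_threshold <- function(channel, method = c("otsu", "isodata")) {
  method <- match.arg(method)
  rng <- range(channel)
  if (!is.finite(diff(rng)) || diff(rng) == 0)
    stop("no contrast: channel is constant")
  x <- (channel - rng[1]) / diff(rng)
  if (method == "otsu") {
    th <- EBImage::otsu(EBImage::Image(t(x)), range = c(0, 1), levels = 256)
  } else {
    # IsoData: t <- mean of class means until stable, on the 256-bin scale
    h <- tabulate(pmin(255L, as.integer(x * 256)) + 1L, nbins = 256L)
    mids <- (0:255 + 0.5) / 256
    t0 <- sum(h * mids) / sum(h)
    repeat {
      lo <- mids <= t0
      m1 <- sum(h[lo] * mids[lo]) / max(sum(h[lo]), 1)
      m2 <- sum(h[!lo] * mids[!lo]) / max(sum(h[!lo]), 1)
      t1 <- (m1 + m2) / 2
      if (abs(t1 - t0) < 1e-7) break
      t0 <- t1
    }
    th <- t0
  }
  mask <- x > th
  attr(mask, "threshold") <- rng[1] + th * diff(rng)
  mask
}

#' Classify instances of a WGA-segmented fluorescence image
#'
#' Cardiomyocytes carry no specific stain in this modality, so watershed
#' instances of the membrane channel are classified as cardiomyocytes by
#' size only (area at least `cm_min_area_um2`, not touching the border when
#' `exclude_border_cm`); no upper size bound is applied. Nuclei are
#' 8-connected components of the auto-thresholded DAPI channel retained when
#' at least half their pixels fall inside a (hole-filled) cardiomyocyte
#' footprint and their area is within the nucleus window. With an
#' endothelium marker (CD31), capillaries are 8-connected components of the
#' auto-thresholded marker after zeroing every CM footprint pixel, within
#' the capillary size window -- so capillary masks and CM footprints are
#' pixel-disjoint by construction. With an intracellular expression marker,
#' the thresholded mask is returned for [expression_per_cm()] and no
#' capillary class is produced.
#'
#' Nucleus and capillary components are appended to the instance table with
#' fresh ids above the watershed labels; `$labels` maps every retained
#' instance id to its pixels (nuclei drawn over their host CM).
#'
#' @param channels A [channel_set()].
#' @param labels Label matrix from the membrane-channel watershed.
#' @param config An [analysis_config()].
#' @return List: `classification` (instance_id, class, reason), `records`
#'   (measured instances), `labels` (combined instance label matrix),
#'   `cm_labels` (watershed labels), `masks` (nuclei/marker masks),
#'   `thresholds` (provenance).
#' @export
classify_fluo <- function(channels, labels, config) {
  stopifnot(inherits(channels, "channel_set"),
            inherits(config, "analysis_config"))
  mpp <- channels$microns_per_pixel
  meas <- measure_instances(labels, mpp)
  interior <- if (config$exclude_border_cm) !meas$touches_border else TRUE
  is_cm <- meas$area_um2 >= config$cm_min_area_um2 & interior
  cls <- ifelse(is_cm, "cardiomyocyte", "removed")
  reason <- ifelse(is_cm, "size at least minimum, interior",
            ifelse(meas$area_um2 < config$cm_min_area_um2,
                   sprintf("below %g um^2 cardiomyocyte minimum",
                           config$cm_min_area_um2),
                   "cardiomyocyte at image border"))
  cm_ids <- meas$instance_id[is_cm]
  fp <- .cm_footprints(labels, cm_ids)

  out_cls <- data.frame(instance_id = meas$instance_id, class = cls,
                        reason = reason)
  records <- cbind(meas, class = cls)
  combined <- labels
  combined[!(combined %in% cm_ids)] <- 0L
  thresholds <- list()
  masks <- list(nuclei = NULL, marker = NULL)
  next_id <- max(meas$instance_id, 0L)

  nwin <- config$nucleus_area_um2
  if (!is.null(channels$nuclei)) {
    nmask <- auto_threshold(channels$nuclei, config$autothreshold_method)
    thresholds$nuclei <- attr(nmask, "threshold")
    masks$nuclei <- nmask
    comps <- cpp_cc_label(nmask, 8L)
    if (max(comps) > 0) {
      cm <- measure_instances(comps, mpp)
      for (i in seq_len(nrow(cm))) {
        idx <- which(comps == cm$instance_id[i])
        frac_in <- {
          fl <- fp[idx]; fl <- fl[fl > 0]
          if (length(fl)) max(table(fl)) / length(idx) else 0
        }
        ok <- frac_in >= 0.5 && cm$area_um2[i] >= nwin[1] &&
          cm$area_um2[i] <= nwin[2]
        next_id <- next_id + 1L
        rec <- cm[i, ]; rec$instance_id <- next_id
        if (ok) {
          combined[idx] <- next_id
          records <- rbind(records, cbind(rec, class = "cm_nucleus"))
          out_cls <- rbind(out_cls, data.frame(
            instance_id = next_id, class = "cm_nucleus",
            reason = "DAPI component within a cardiomyocyte, size window"))
        } else {
          records <- rbind(records, cbind(rec, class = "removed"))
          out_cls <- rbind(out_cls, data.frame(
            instance_id = next_id, class = "removed",
            reason = if (frac_in < 0.5) "nucleus outside cardiomyocytes"
                     else "nucleus outside size window"))
        }
      }
    }
  }

  cwin <- config$capillary_area_um2
  if (!is.null(channels$marker)) {
    if (is.na(channels$marker_role)) stop("marker_role missing")
    mmask <- auto_threshold(channels$marker, config$autothreshold_method)
    thresholds$marker <- attr(mmask, "threshold")
    if (channels$marker_role == "endothelium") {
      capm <- mmask & fp == 0 # exclude area belonging to cardiomyocytes
      masks$marker <- capm
      comps <- cpp_cc_label(capm, 8L)
      if (max(comps) > 0) {
        cm <- measure_instances(comps, mpp)
        for (i in seq_len(nrow(cm))) {
          idx <- which(comps == cm$instance_id[i])
          ok <- cm$area_um2[i] >= cwin[1] && cm$area_um2[i] <= cwin[2]
          next_id <- next_id + 1L
          rec <- cm[i, ]; rec$instance_id <- next_id
          if (ok) {
            combined[idx] <- next_id
            records <- rbind(records, cbind(rec, class = "capillary"))
            out_cls <- rbind(out_cls, data.frame(
              instance_id = next_id, class = "capillary",
              reason = "endothelial component outside cardiomyocytes"))
          } else {
            records <- rbind(records, cbind(rec, class = "removed"))
            out_cls <- rbind(out_cls, data.frame(
              instance_id = next_id, class = "removed",
              reason = "endothelial component outside size window"))
          }
        }
      }
    } else {
      masks$marker <- mmask # retained for expression_per_cm()
    }
  }
  rownames(records) <- NULL
  list(classification = out_cls, records = records, labels = combined,
       cm_labels = labels, masks = masks, thresholds = thresholds)
}
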