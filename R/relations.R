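#' Count capillary contacts per cardiomyocyte
#'
#' A capillary counts as a contact of a cardiomyocyte when the minimum
#' Euclidean distance between any capillary pixel centre and any CM pixel
#' centre is at most `max_distance_um` (default 2 um -- only capillaries
#' directly bordering the cell). Distances are edge-to-edge between pixel
#' centres, so a capillary separated from a CM by a single 1-px watershed
#' line at 0.5 um/px is at 0.5 um and counts. One capillary may contact
#' several cardiomyocytes and contributes to each of their counts.
#'
#' The implementation evaluates, per capillary, all pixel pairs against CM
#' pixels inside the capillary's bounding box expanded by the contact
#' radius; this is exactly the brute-force all-pairs minimum restricted to
#' the only region where it can fall below the bound.
#'
#' @param cm_ids Integer vector of cardiomyocyte labels.
#' @param capillary_ids Integer vector of capillary labels (may be empty).
#' @param labels Label matrix containing both sets of labels.
#' @param max_distance_um Positive contact bound in um.
#' @param microns_per_pixel Positive calibration.
#' @param cm_labels Optional separate label matrix for the CM ids (used in
#'   fluorescence mode where capillaries live in their own component map).
#' @return Data frame `cm_id`, `n_contacts`, `cc_per_area` (contacts per
#'   um^2 of that CM's area).
#' @export
count_capillary_contacts <- function(cm_ids, capillary_ids, labels,
                                     max_distance_um, microns_per_pixel,
                                     cm_labels = labels) {
  if (max_distance_um <= 0) stop("max_distance_um must be positive")
  stopifnot(microns_per_pixel > 0)
  nr <- nrow(labels); nc <- ncol(labels)
  rad_px <- max_distance_um / microns_per_pixel
  counts <- setNames(integer(length(cm_ids)), cm_ids)
  for (cap in capillary_ids) {
    rc <- which(labels == cap, arr.ind = TRUE)
    if (!nrow(rc)) next
    r0 <- max(1L, min(rc[, 1]) - ceiling(rad_px))
    r1 <- min(nr, max(rc[, 1]) + ceiling(rad_px))
    c0 <- max(1L, min(rc[, 2]) - ceiling(rad_px))
    c1 <- min(nc, max(rc[, 2]) + ceiling(rad_px))
    sub <- cm_labels[r0:r1, c0:c1, drop = FALSE]
    tgt <- which(matrix(sub %in% cm_ids, nrow(sub)), arr.ind = TRUE)
    if (!nrow(tgt)) next
    tl <- sub[tgt]
    # squared pixel distances capillary x candidate-CM pixels
    dy <- outer(rc[, 1], tgt[, 1] + r0 - 1L, "-")
    dx <- outer(rc[, 2], tgt[, 2] + c0 - 1L, "-")
    d2 <- dy * dy + dx * dx
    mind <- tapply(apply(d2, 2, min), tl, min)
    hit <- as.integer(names(mind))[sqrt(mind) <= rad_px]
    counts[as.character(hit)] <- counts[as.character(hit)] + 1L
  }
  areas <- vapply(cm_ids, function(id)
    sum(cm_labels == id) * microns_per_pixel^2, 0)
  data.frame(cm_id = as.integer(cm_ids),
             n_contacts = as.integer(counts),
             cc_per_area = ifelse(areas > 0, counts / areas, 0))
}

#' Percent marker-positive area per cardiomyocyte
#'
#' For each cardiomyocyte, the percentage of its pixels covered by the
#' thresholded marker mask (e.g. pro-ANP), the per-cell expression readout
#' of the fluorescence pipeline.
#'
#' @param cm_ids Integer vector of cardiomyocyte labels.
#' @param labels Label matrix holding those labels.
#' @param marker_mask Logical/0-1 matrix, same size as `labels`.
#' @return Data frame `cm_id`, `positive_pct` in [0, 100].
#' @export
expression_per_cm <- function(cm_ids, labels, marker_mask) {
  if (!all(dim(labels) == dim(marker_mask)))
    stop("marker_mask dimensions differ from labels")
  pos <- marker_mask > 0
  data.frame(
    cm_id = as.integer(cm_ids),
    positive_pct = vapply(cm_ids, function(id) {
      px <- labels == id
      n <- sum(px)
      if (n == 0) 0 else 100 * sum(pos & px) / n
    }, 0)
  )
}

#' Build the per-image report
#'
#' Aggregates classified, measured instances into an `image_report`: the
#' per-instance table (with contact and expression columns merged onto
#' cardiomyocyte rows) and a per-class summary with count, mean and SD
#' (n-1 denominator) of area and MinFeret, plus mean contacts, mean
#' contacts-per-area and mean expression where applicable. A class with a
#' single instance reports `NA` for its SDs rather than zero; empty classes
#' appear with n = 0.
#'
#' @param records Data frame of measured instances with a `class` column
#'   (rows with class `"removed"` are dropped from the report).
#' @param contacts Optional data frame from [count_capillary_contacts()].
#' @param expressions Optional data frame from [expression_per_cm()].
#' @param config Optional [analysis_config()] snapshot stored in the report.
#' @param image_id Identifier stored in the report.
#' @return An object of class `image_report`.
#' @export
summarize_image <- function(records, contacts = NULL, expressions = NULL,
                            config = NULL, image_id = "") {
  keep <- records[records$class != "removed", , drop = FALSE]
  if (!is.null(contacts) && nrow(contacts)) {
    stopifnot(all(contacts$cm_id %in%
                    keep$instance_id[keep$class == "cardiomyocyte"]))
    keep$capillary_contacts <-
      contacts$n_contacts[match(keep$instance_id, contacts$cm_id)]
    keep$cc_per_area_um2 <-
      contacts$cc_per_area[match(keep$instance_id, contacts$cm_id)]
  }
  if (!is.null(expressions) && nrow(expressions)) {
    stopifnot(all(expressions$cm_id %in%
                    keep$instance_id[keep$class == "cardiomyocyte"]))
    keep$expression_pct <-
      expressions$positive_pct[match(keep$instance_id, expressions$cm_id)]
  }
  classes <- c("cardiomyocyte", "cm_nucleus", "capillary")
  sd1 <- function(x) if (length(x) >= 2) sd(x) else NA_real_
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  summ <- do.call(rbind, lapply(classes, function(cl) {
    sub <- keep[keep$class == cl, , drop = FALSE]
    data.frame(
      class = cl,
      n = nrow(sub),
      mean_area_um2 = mean_or_na(sub$area_um2),
      sd_area_um2 = sd1(sub$area_um2),
      mean_feret_min_um = mean_or_na(sub$feret_min_um),
      sd_feret_min_um = sd1(sub$feret_min_um),
      mean_capillary_contacts =
        if (cl == "cardiomyocyte" && !is.null(sub$capillary_contacts))
          mean_or_na(sub$capillary_contacts) else NA_real_,
      mean_cc_per_area_um2 =
        if (cl == "cardiomyocyte" && !is.null(sub$cc_per_area_um2))
          mean_or_na(sub$cc_per_area_um2) else NA_real_,
      mean_expression_pct =
        if (cl == "cardiomyocyte" && !is.null(sub$expression_pct))
          mean_or_na(sub$expression_pct) else NA_real_
    )
  }))
  rownames(keep) <- NULL
  structure(list(image_id = image_id, records = keep, class_summaries = summ,
                 relations = list(contacts = contacts,
                                  expressions = expressions),
                 config_snapshot = config),
            class = "image_report")
}

#' @export
print.image_report <- function(x, ...) {
  cat("image_report:", x$image_id, "\n")
  print(x$class_summaries, row.names = FALSE)
  invisible(x)
}
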