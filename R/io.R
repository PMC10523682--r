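#' Construct a calibrated image
#'
#' A `calibrated_image` couples pixel data with an isotropic physical
#' calibration in microns per pixel. Brightfield images store an RGB array
#' (`height x width x 3`, values 0-255); fluorescence images store a named
#' list of single-channel intensity matrices on a common [0, 1] scale, one of
#' which must be called `"membrane"` (the WGA channel used for segmentation).
#'
#' @param pixels RGB array (brightfield) or named list of matrices
#'   (fluorescence).
#' @param microns_per_pixel Positive scalar, um per pixel.
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @return A `calibrated_image`.
#' @export
calibrated_image <- function(pixels, microns_per_pixel,
                             modality = c("brightfield", "fluorescence")) {
  modality <- match.arg(modality)
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1 ||
      is.na(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be a positive number")
  if (modality == "brightfield") {
    if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
      stop("brightfield pixels must be a height x width x 3 array")
    if (min(pixels) < 0 || max(pixels) > 255)
      stop("brightfield components must lie in [0, 255]")
    h <- dim(pixels)[1]; w <- dim(pixels)[2]
  } else {
    if (!is.list(pixels) || is.null(names(pixels)) || length(pixels) < 1)
      stop("fluorescence pixels must be a named list of channel matrices")
    dims <- lapply(pixels, dim)
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
      stop("all fluorescence channels must share identical dimensions")
    h <- dims[[1]][1]; w <- dims[[1]][2]
  }
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 modality = modality, width_px = w, height_px = h),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat("calibrated_image: ", x$width_px, " x ", x$height_px, " px (",
      round(x$width_px * x$microns_per_pixel, 1), " x ",
      round(x$height_px * x$microns_per_pixel, 1), " um), ",
      x$modality, ", ", x$microns_per_pixel, " um/px\n", sep = "")
  if (x$modality == "fluorescence")
    cat("  channels:", paste(names(x$pixels), collapse = ", "), "\n")
  invisible(x)
}

#' Read an image file with explicit calibration
#'
#' Calibration is always supplied by the caller, never inferred from file
#' metadata: the exported field images this pipeline targets (JPEG/PNG
#' regions cut from whole-slide scans) carry no trustworthy physical
#' metadata. Standard formats (PNG, JPEG, TIFF, BMP, GIF) are read through
#' EBImage.
#'
#' For fluorescence, `channel_map` names the channels and locates each one
#' either as a frame index into a multi-page/multi-channel file (e.g.
#' `list(membrane = 1, marker = 2, nuclei = 3)`) or as a separate file path
#' per channel. Channel intensities are kept on the [0, 1] scale implied by
#' the file bit depth (8- or 16-bit full range maps to [0, 1]); this linear
#' normalisation is recorded in the returned object.
#'
#' @param path Image file (ignored when `channel_map` gives per-channel
#'   paths).
#' @param microns_per_pixel Positive scalar calibration.
#' @param modality `"brightfield"` or `"fluorescence"`.
#' @param channel_map Named list for fluorescence; must contain a
#'   `"membrane"` entry.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, microns_per_pixel,
                       modality = c("brightfield", "fluorescence"),
                       channel_map = NULL) {
  modality <- match.arg(modality)
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be positive")
  if (modality == "brightfield") {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- EBImage::readImage(path)
    d <- dim(img)
    if (length(d) == 2) { # grayscale: replicate to RGB
      arr <- array(rep(t(img), 3L), dim = c(d[2], d[1], 3))
    } else {
      if (d[3] < 3) stop("brightfield image must have 3 colour channels")
      arr <- array(0, dim = c(d[2], d[1], 3))
      for (k in 1:3) arr[, , k] <- t(img[, , k])
    }
    return(calibrated_image(round(arr * 255), microns_per_pixel,
                            "brightfield"))
  }
  # fluorescence
  if (is.null(channel_map) || is.null(names(channel_map)))
    stop("fluorescence images require a named channel_map")
  if (!"membrane" %in% names(channel_map))
    stop("channel_map must designate a 'membrane' (WGA) channel")
  by_path <- all(vapply(channel_map, is.character, TRUE))
  chans <- list()
  if (by_path) {
    for (nm in names(channel_map)) {
      f <- channel_map[[nm]]
      if (!file.exists(f)) stop("file not found: ", f)
      im <- EBImage::readImage(f)
      if (length(dim(im)) > 2) im <- im[, , 1]
      chans[[nm]] <- t(as.matrix(im))
    }
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    img <- EBImage::readImage(path, all = TRUE)
    d <- dim(img)
    nframes <- if (length(d) == 2) 1L else prod(d[-(1:2)])
    flat <- array(img, dim = c(d[1], d[2], nframes))
    for (nm in names(channel_map)) {
      k <- as.integer(channel_map[[nm]])
      if (k < 1 || k > nframes)
        stop("channel index ", k, " out of range for ", nm)
      chans[[nm]] <- t(flat[, , k])
    }
  }
  dims <- vapply(chans, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("fluorescence channels have mismatched dimensions")
  img <- calibrated_image(chans, microns_per_pixel, "fluorescence")
  img$normalization <- "linear full-range of file bit depth to [0,1]"
  img
}

#' Extract the luminance matrix of a brightfield image
#'
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B), the conversion used by
#' ImageJ for RGB-to-8-bit, on the 0-255 scale.
#' @param image A brightfield [calibrated_image()].
#' @return Numeric matrix, 0-255.
#' @export
luminance <- function(image) {
  stopifnot(inherits(image, "calibrated_image"),
            image$modality == "brightfield")
  0.299 * image$pixels[, , 1] + 0.587 * image$pixels[, , 2] +
    0.114 * image$pixels[, , 3]
}

# Column order of the per-instance table; relation columns are CM-only.
.instance_cols <- c("instance_id", "class", "area_um2", "feret_max_um",
                    "feret_min_um", "centroid_x_um", "centroid_y_um",
                    "touches_border", "pixel_count", "capillary_contacts",
                    "cc_per_area_um2", "expression_pct")

#' Write an image report to CSV files
#'
#' Writes `<path_prefix>_instances.csv` (one row per retained instance) and
#' `<path_prefix>_summary.csv` (per-class counts, mean/SD area and MinFeret,
#' and mean contact/expression statistics where present). Files are RFC-4180
#' CSV, UTF-8, dot decimal separator. CSV is the canonical output format of
#' the package.
#'
#' @param report An `image_report` from [summarize_image()].
#' @param path_prefix Output path prefix (directories must exist).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "image_report"))
  inst <- report$records
  for (cc in setdiff(.instance_cols, names(inst)))
    inst[[cc]] <- rep(NA, nrow(inst))
  inst <- inst[, .instance_cols, drop = FALSE]
  f1 <- paste0(path_prefix, "_instances.csv")
  f2 <- paste0(path_prefix, "_summary.csv")
  ok <- tryCatch({
    write.csv(inst, f1, row.names = FALSE, fileEncoding = "UTF-8")
    write.csv(report$class_summaries, f2, row.names = FALSE,
              fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write report: ", conditionMessage(e)))
  invisible(c(instances = f1, summary = f2))
}

#' Read back a per-instance table written by [write_report()]
#' @param path Path to an `*_instances.csv` file.
#' @return A data frame of instance records.
#' @export
read_instance_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("touches_border" %in% names(df))
    df$touches_border <- as.logical(df$touches_border)
  df
}

# fixed class colours (RGB 0-255) used in every overlay
.class_colors <- list(
  cardiomyocyte = c(230, 60, 60),
  cm_nucleus    = c(60, 90, 230),
  capillary     = c(60, 200, 90)
)

#' Render a colour-coded overlay of retained instances
#'
#' Each retained instance's pixels are tinted with a fixed class colour
#' (cardiomyocyte red, nucleus blue, capillary green) blended over the base
#' rendering; excluded or removed instances are left untouched. Instance ids
#' are stamped as small digit glyphs clipped to the instance's own pixels,
#' so no pixel outside a retained instance is ever modified. A legend data
#' frame (id, class, centroid in px) is attached as attribute `"legend"` and
#' written to `<legend_path>` when given, so every id can be located even
#' when glyphs overlap or do not fit.
#'
#' @param image A [calibrated_image()].
#' @param labels Integer label matrix from [watershed_segment()].
#' @param records Data frame of retained instances (needs `instance_id`,
#'   `class`; classes outside cardiomyocyte/cm_nucleus/capillary are skipped).
#' @param legend_path Optional CSV path for the legend.
#' @param annotate Stamp instance ids into the image (default `TRUE`).
#' @return RGB array (`height x width x 3`, 0-255) with attribute `legend`.
#' @export
render_overlay <- function(image, labels, records, legend_path = NULL,
                           annotate = TRUE) {
  stopifnot(inherits(image, "calibrated_image"))
  if (image$height_px != nrow(labels) || image$width_px != ncol(labels))
    stop("labels and image dimensions differ")
  base <- if (image$modality == "brightfield") {
    image$pixels
  } else {
    # compose fluorescence channels into an RGB rendering
    g <- image$pixels[["membrane"]]
    arr <- array(0, dim = c(nrow(g), ncol(g), 3))
    arr[, , 2] <- g * 255
    if (!is.null(image$pixels[["nuclei"]]))
      arr[, , 3] <- image$pixels[["nuclei"]] * 255
    if (!is.null(image$pixels[["marker"]]))
      arr[, , 1] <- image$pixels[["marker"]] * 255
    arr
  }
  out <- base
  keep <- records[records$class %in% names(.class_colors), , drop = FALSE]
  alpha <- 0.45
  for (i in seq_len(nrow(keep))) {
    id <- keep$instance_id[i]
    col <- .class_colors[[keep$class[i]]]
    mask <- labels == id
    for (k in 1:3) {
      ch <- out[, , k]
      ch[mask] <- (1 - alpha) * ch[mask] + alpha * col[k]
      out[, , k] <- ch
    }
    if (annotate) out <- .stamp_id(out, mask, id)
  }
  legend <- data.frame(
    instance_id = keep$instance_id,
    class = keep$class,
    centroid_x_px = vapply(keep$instance_id, function(id) {
      mean(which(labels == id, arr.ind = TRUE)[, 2]) - 1
    }, 0),
    centroid_y_px = vapply(keep$instance_id, function(id) {
      mean(which(labels == id, arr.ind = TRUE)[, 1]) - 1
    }, 0)
  )
  if (anyDuplicated(legend$instance_id))
    stop("duplicate instance ids in records")
  if (!is.null(legend_path))
    write.csv(legend, legend_path, row.names = FALSE)
  attr(out, "legend") <- legend
  out
}

# 3x5 digit glyphs, row-wise bits
.digit_font <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1)
)

# stamp the decimal id at the instance centroid, clipped to the mask
.stamp_id <- function(arr, mask, id) {
  px <- which(mask, arr.ind = TRUE)
  cy <- round(mean(px[, 1])); cx <- round(mean(px[, 2]))
  digits <- strsplit(as.character(id), "")[[1]]
  wtot <- 4 * length(digits) - 1
  x0 <- cx - floor(wtot / 2); y0 <- cy - 2
  nr <- dim(arr)[1]; nc <- dim(arr)[2]
  for (d in seq_along(digits)) {
    bits <- .digit_font[[digits[d]]]
    for (ry in 0:4) for (rx in 0:2) {
      if (!bits[ry * 3 + rx + 1]) next
      y <- y0 + ry; x <- x0 + (d - 1) * 4 + rx
      if (y < 1 || y > nr || x < 1 || x > nc || !mask[y, x]) next
      arr[y, x, ] <- c(20, 20, 20)
    }
  }
  arr
}

#' Write an RGB array (0-255) to a PNG file
#' @param arr `height x width x 3` array.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rgb_png <- function(arr, path) {
  img <- EBImage::Image(aperm(arr / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

#' Apply a manual exclusion list to instance records
#'
#' Realizes the manual-correction loop: the analyst inspects the overlay,
#' notes the ids of incorrectly segmented structures, and the records are
#' filtered accordingly. Unknown ids produce a warning (manual lists may be
#' stale), never an error. The unfiltered records are retained in the
#' `"audit"` attribute of the result. The operation is idempotent and
#' order-independent in the exclusion ids.
#'
#' @param records Data frame with an `instance_id` column.
#' @param exclusion_ids Integer vector of ids to drop.
#' @return Filtered data frame with attribute `audit` (original records) and
#'   `excluded` (the ids actually removed).
#' @export
apply_exclusions <- function(records, exclusion_ids) {
  exclusion_ids <- unique(as.integer(exclusion_ids))
  unknown <- setdiff(exclusion_ids, records$instance_id)
  if (length(unknown))
    warning("exclusion ids not present in records: ",
            paste(unknown, collapse = ", "))
  keep <- !(records$instance_id %in% exclusion_ids)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  audit <- attr(records, "audit")
  attr(out, "audit") <- if (is.null(audit)) records else audit
  attr(out, "excluded") <- intersect(exclusion_ids, records$instance_id)
  out
}

#' Read an exclusion list file (one instance id per line)
#' @param path Text file; blank lines and `#` comments ignored.
#' @return Integer vector of ids.
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path)) stop("exclusions file not found: ", path)
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(integer(0))
  ids <- suppressWarnings(as.integer(ln))
  if (anyNA(ids)) stop("non-integer entries in exclusions file")
  ids
}
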