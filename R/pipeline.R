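#' Run the full brightfield (Gomori silver) analysis on one image
#'
#' Relief construction, tolerance-controlled watershed, optional manual
#' line merge, classification, morphometry, capillary-contact counting and
#' summary -- the complete single-image pipeline.
#'
#' @param image Brightfield [calibrated_image()].
#' @param config [analysis_config()]; its `watershed_tolerance` is used.
#' @param line_mask Optional manual correction line mask.
#' @param exclusion_ids Optional instance ids to exclude (manual
#'   correction).
#' @param image_id Identifier for the report.
#' @return List: `report` ([summarize_image()] result), `labels`,
#'   `classification`, `relief`.
#' @export
analyze_gomori <- function(image, config, line_mask = NULL,
                           exclusion_ids = NULL, image_id = "") {
  relief <- build_relief(image)
  labels <- watershed_segment(relief, config$watershed_tolerance)
  if (!is.null(line_mask))
    labels <- merge_manual_lines(labels, relief, line_mask,
                                 config$watershed_tolerance)
  cls <- classify_gomori(image, labels, config)
  meas <- measure_instances(labels, image$microns_per_pixel)
  records <- merge(meas, cls, by = "instance_id", sort = TRUE)
  if (!is.null(exclusion_ids) && length(exclusion_ids))
    records <- apply_exclusions(records, exclusion_ids)
  cm_ids <- records$instance_id[records$class == "cardiomyocyte"]
  cap_ids <- records$instance_id[records$class == "capillary"]
  contacts <- count_capillary_contacts(cm_ids, cap_ids, labels,
                                       config$contact_max_distance_um,
                                       image$microns_per_pixel)
  report <- summarize_image(records, contacts, NULL, config, image_id)
  list(report = report, labels = labels,
       classification = cls, relief = relief)
}

#' Run the full fluorescence analysis on one channel set
#'
#' Membrane-channel watershed, size-only cardiomyocyte classification,
#' auto-thresholded nuclei and capillaries (endothelium role) or per-cell
#' expression quantification (intracellular role), contacts and summary.
#'
#' @param channels A [channel_set()].
#' @param config [analysis_config()].
#' @param line_mask Optional manual correction line mask.
#' @param exclusion_ids Optional instance ids to exclude.
#' @param image_id Identifier for the report.
#' @return List: `report`, `labels` (combined instance labels),
#'   `cm_labels` (watershed labels), `classification`, `masks`,
#'   `thresholds`.
#' @export
analyze_fluo <- function(channels, config, line_mask = NULL,
                         exclusion_ids = NULL, image_id = "") {
  stopifnot(inherits(channels, "channel_set"))
  relief <- channels$membrane
  labels <- watershed_segment(relief, config$watershed_tolerance)
  if (!is.null(line_mask))
    labels <- merge_manual_lines(labels, relief, line_mask,
                                 config$watershed_tolerance)
  fl <- classify_fluo(channels, labels, config)
  records <- fl$records
  if (!is.null(exclusion_ids) && length(exclusion_ids))
    records <- apply_exclusions(records, exclusion_ids)
  cm_ids <- records$instance_id[records$class == "cardiomyocyte"]
  contacts <- NULL; expressions <- NULL
  if (!is.na(channels$marker_role) &&
      channels$marker_role == "endothelium") {
    cap_ids <- records$instance_id[records$class == "capillary"]
    contacts <- count_capillary_contacts(cm_ids, cap_ids, fl$labels,
                                         config$contact_max_distance_um,
                                         channels$microns_per_pixel,
                                         cm_labels = fl$labels)
  } else if (!is.na(channels$marker_role) &&
             channels$marker_role == "intracellular_expression") {
    expressions <- expression_per_cm(cm_ids, fl$labels, fl$masks$marker)
  }
  report <- summarize_image(records, contacts, expressions, config,
                            image_id)
  list(report = report, labels = fl$labels, cm_labels = labels,
       classification = fl$classification, masks = fl$masks,
       thresholds = fl$thresholds)
}
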