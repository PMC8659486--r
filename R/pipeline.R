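#' Pipeline configuration
#'
#' Validated settings for an end-to-end run: localisation, per-kidney
#' whole-kidney segmentation and rule-based compartment segmentation. Two
#' modes exist: `use_truth_masks = TRUE` runs the rule-based stage on
#' supplied whole-kidney masks (no trained models needed); otherwise
#' checkpoints for the localiser and segmenter must be given.
#'
#' Unknown arguments are rejected (R's argument matching enforces the
#' schema).
#'
#' @param series path to a 4D NIfTI series, or a [dce_series()] object.
#' @param out_dir output directory (`NULL` = return results only).
#' @param mask_right,mask_left paths to whole-kidney mask NIfTIs (or
#'   [kidney_mask()] objects) when `use_truth_masks` is `TRUE`.
#' @param truth_labels optional ground-truth compartment labels (path or
#'   [compartment_labels()]) for evaluation.
#' @param use_truth_masks logical; bypass the networks and use the given
#'   masks.
#' @param localizer,segmenter model checkpoints (paths or `rs_model`
#'   objects) used when `use_truth_masks` is `FALSE`.
#' @param params a [compartment_params()].
#' @param seed integer seed for any stochastic step.
#' @export
pipeline_config <- function(series, out_dir = NULL,
                            mask_right = NULL, mask_left = NULL,
                            truth_labels = NULL,
                            use_truth_masks = !is.null(mask_right) ||
                              !is.null(mask_left),
                            localizer = NULL, segmenter = NULL,
                            params = compartment_params(), seed = 1L) {
  if (!use_truth_masks && (is.null(localizer) || is.null(segmenter)))
    stop(paste("no trained checkpoints given: supply `localizer` and",
               "`segmenter`, or set `use_truth_masks = TRUE` with",
               "whole-kidney masks for a rule-only run"), call. = FALSE)
  structure(list(series = series, out_dir = out_dir,
                 mask_right = mask_right, mask_left = mask_left,
                 truth_labels = truth_labels,
                 use_truth_masks = use_truth_masks,
                 localizer = localizer, segmenter = segmenter,
                 params = params, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_series <- function(x) if (inherits(x, "dce_series")) x else read_dce(x)
resolve_mask <- function(x, side) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "kidney_mask")) return(x)
  kidney_mask(read_volume3d(x), side = side)
}
resolve_labels <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "compartment_labels")) return(x)
  compartment_labels(read_volume3d(x))
}
resolve_model <- function(x) {
  if (is.null(x) || inherits(x, "rs_model")) return(x)
  load_model(x)
}

#' Run the full segmentation pipeline on one case
#'
#' Localise each kidney (or take the supplied masks), segment the whole
#' kidney per side — skipping absent kidneys, which are encoded as
#' single-voxel `present = FALSE` boxes — then run the per-frame
#' medulla/cortex cascade and the temporal fusion. Writes the compartment
#' label volume, per-compartment time-intensity curves (CSV), an optional
#' evaluation against ground truth, and a JSON run manifest.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `labels` ([compartment_labels()]),
#'   `masks`, `boxes`, `curves`, optional `scores`, and `absent` (sides
#'   without a kidney).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  series <- resolve_series(config$series)
  d <- series_dims(series)
  masks <- list()
  boxes <- list()
  if (config$use_truth_masks) {
    for (side in c("right", "left")) {
      mk <- resolve_mask(config[[paste0("mask_", side)]], side)
      if (is.null(mk)) mk <- kidney_mask(array(0L, c(d$D, d$H, d$W)), side = side)
      masks[[side]] <- mk
      boxes[[side]] <- compute_bounding_box(mk)
    }
  } else {
    loc <- resolve_model(config$localizer)
    seg <- resolve_model(config$segmenter)
    boxes <- predict_boxes(loc, series)
    for (side in c("right", "left")) {
      masks[[side]] <- predict_kidney_mask(seg, series, boxes[[side]])
    }
  }
  absent <- names(boxes)[!vapply(boxes, `[[`, TRUE, "present")]
  active <- setdiff(c("right", "left"), absent)
  labels <- segment_compartments(series, masks[active], config$params)
  curves <- tryCatch(
    extract_curves(series, labels, sides = masks[active]),
    error = function(e) NULL)
  truth <- resolve_labels(config$truth_labels)
  scores <- if (!is.null(truth)) score_case(truth$data, labels$data) else NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume3d(labels, file.path(config$out_dir, "labels_medcor.nii.gz"),
                   series$spacing)
    for (side in active) {
      write_volume3d(masks[[side]],
                     file.path(config$out_dir, sprintf("mask_%s.nii.gz", side)),
                     series$spacing)
    }
    if (!is.null(curves))
      write.csv(curves, file.path(config$out_dir, "curves.csv"),
                row.names = FALSE)
    if (!is.null(scores))
      write.csv(scores, file.path(config$out_dir, "scores.csv"),
                row.names = FALSE)
    manifest <- list(
      package = "renalseg",
      version = as.character(utils::packageVersion("renalseg")),
      seed = config$seed,
      use_truth_masks = config$use_truth_masks,
      absent_kidneys = absent,
      params = config$params,
      shape = c(d$D, d$H, d$W), frames = d$T)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(labels = labels, masks = masks, boxes = boxes,
                 curves = curves, scores = scores, absent = absent))
}
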