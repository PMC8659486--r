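#' Per-compartment time-intensity curves
#'
#' Extracts, for every side and compartment, the mean intensity of the
#' labelled voxels in each frame, converted to relative contrast
#' enhancement `(I_t - I_0) / I_0` where `I_0` is the mean at the baseline
#' (first) frame. The cortex curve of a functioning kidney peaks earlier
#' than the medulla curve, reflecting the earlier cortical transit of the
#' contrast agent.
#'
#' @param series a [dce_series()].
#' @param labels a [compartment_labels()] (or 3D array) aligned with the
#'   series' spatial grid.
#' @param sides named list of per-kidney [kidney_mask()]s restricting the
#'   curves to one kidney each; `NULL` extracts curves over the whole
#'   label volume under side `"both"`.
#' @param compartments which curves to extract: any of `"medulla"`,
#'   `"cortex"`, `"whole"` (whole = any labelled voxel).
#' @return A long-format data frame with columns `side`, `compartment`,
#'   `time_s`, `value`. Empty compartments are omitted with a warning.
#' @export
extract_curves <- function(series, labels,
                           sides = NULL,
                           compartments = c("medulla", "cortex", "whole")) {
  lab <- if (inherits(labels, "compartment_labels")) labels$data else labels
  d <- series_dims(series)
  if (!all(dim(lab) == c(d$D, d$H, d$W)))
    stop("labels do not align with the series grid", call. = FALSE)
  if (is.null(sides)) sides <- list(both = NULL)
  sel <- list(medulla = function(v) v == 1, cortex = function(v) v == 2,
              whole = function(v) v > 0)
  tmat <- matrix(aperm(series$data, c(2, 3, 4, 1)), ncol = d$T)  # voxels x T
  out <- list()
  for (side in names(sides)) {
    sm <- sides[[side]]
    smv <- if (is.null(sm)) TRUE
           else as.vector((if (inherits(sm, "kidney_mask")) sm$data else sm) != 0)
    for (cp in compartments) {
      vox <- which(sel[[cp]](as.vector(lab)) & smv)
      if (length(vox) == 0L) {
        warning(sprintf("no %s voxels on side '%s': curve omitted", cp, side),
                call. = FALSE)
        next
      }
      means <- colMeans(tmat[vox, , drop = FALSE])
      i0 <- means[1L]
      vals <- if (i0 != 0) (means - i0) / i0 else means - i0
      out[[length(out) + 1L]] <- data.frame(side = side, compartment = cp,
                                            time_s = series$times,
                                            value = vals)
    }
  }
  if (length(out) == 0L) stop("no curves could be extracted", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
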