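as_binary <- function(x) {
  if (inherits(x, "kidney_mask") || inherits(x, "compartment_labels")) x <- x$data
  x != 0
}

#' Volumetric overlap metrics
#'
#' Dice similarity coefficient `DSC = 2|G n S| / (|G| + |S|)`, precision
#' `PC = |S n G| / |S|` and recall `RC = |S n G| / |G|` between a ground
#' truth `G` and a segmentation `S` of equal shape. Conventions for empty
#' inputs: if both are empty all three scores are 1 (with a warning); an
#' empty denominator with a non-empty counterpart scores 0.
#'
#' @param G,S binary arrays (or mask objects) of equal shape; any non-zero
#'   voxel counts as foreground.
#' @return A score in `[0, 1]`.
#' @export
dsc <- function(G, S) {
  g <- as_binary(G); s <- as_binary(S)
  if (!all(dim(g) == dim(s))) stop("shape mismatch", call. = FALSE)
  ng <- sum(g); ns <- sum(s)
  if (ng == 0 && ns == 0) {
    warning("both volumes empty: DSC defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(g & s) / (ng + ns)
}

#' @rdname dsc
#' @export
precision <- function(G, S) {
  g <- as_binary(G); s <- as_binary(S)
  if (!all(dim(g) == dim(s))) stop("shape mismatch", call. = FALSE)
  ns <- sum(s)
  if (ns == 0) {
    if (sum(g) == 0) {
      warning("both volumes empty: precision defined as 1", call. = FALSE)
      return(1)
    }
    return(0)
  }
  sum(g & s) / ns
}

#' @rdname dsc
#' @export
recall <- function(G, S) {
  g <- as_binary(G); s <- as_binary(S)
  if (!all(dim(g) == dim(s))) stop("shape mismatch", call. = FALSE)
  ng <- sum(g)
  if (ng == 0) {
    if (sum(s) == 0) {
      warning("both volumes empty: recall defined as 1", call. = FALSE)
      return(1)
    }
    return(0)
  }
  sum(g & s) / ng
}

score_case <- function(truth, pred) {
  classes <- list(kidney = function(v) v > 0,
                  medulla = function(v) v == 1,
                  cortex = function(v) v == 2)
  do.call(rbind, lapply(names(classes), function(cl) {
    f <- classes[[cl]]
    data.frame(class = cl,
               dsc = suppressWarnings(dsc(f(truth), f(pred))),
               pc = suppressWarnings(precision(f(truth), f(pred))),
               rc = suppressWarnings(recall(f(truth), f(pred))))
  }))
}

#' Evaluate predicted label volumes against ground truth
#'
#' Matches prediction and truth NIfTI files by name, scores each case for
#' the whole kidney (any label), medulla (1) and cortex (2), and summarises
#' with the mean and sample standard deviation per class and stratum.
#'
#' @param pred_dir,truth_dir directories of NIfTI label volumes with
#'   matching file names. Cases missing a counterpart are excluded with a
#'   warning.
#' @param strata optional named character vector mapping case id (file name
#'   without extension) to a stratum such as `"normal"` / `"abnormal"`.
#' @param csv optional path; when given the per-case table is written as
#'   CSV.
#' @return List with `per_case` and `summary` data frames.
#' @export
evaluate_cases <- function(pred_dir, truth_dir, strata = NULL, csv = NULL) {
  preds <- list.files(pred_dir, pattern = "\\.nii(\\.gz)?$")
  truths <- list.files(truth_dir, pattern = "\\.nii(\\.gz)?$")
  common <- intersect(preds, truths)
  missing <- setdiff(union(preds, truths), common)
  if (length(missing))
    warning("cases without a counterpart excluded: ",
            paste(missing, collapse = ", "), call. = FALSE)
  if (length(common) == 0L) stop("no matching cases", call. = FALSE)
  per_case <- do.call(rbind, lapply(common, function(f) {
    truth <- read_volume3d(file.path(truth_dir, f))
    pred <- read_volume3d(file.path(pred_dir, f))
    id <- sub("\\.nii(\\.gz)?$", "", f)
    sc <- score_case(truth, pred)
    sc$case <- id
    sc$stratum <- if (!is.null(strata) && id %in% names(strata))
      strata[[id]] else "all"
    sc
  }))
  agg <- function(df) {
    data.frame(stratum = df$stratum[1], class = df$class[1],
               mean_dsc = mean(df$dsc),
               sd_dsc = if (nrow(df) > 1) sd(df$dsc) else 0,
               mean_pc = mean(df$pc), mean_rc = mean(df$rc),
               n = nrow(df))
  }
  groups <- split(per_case, list(per_case$stratum, per_case$class), drop = TRUE)
  summary <- do.call(rbind, lapply(groups, agg))
  rownames(summary) <- NULL
  if (!is.null(csv)) write.csv(per_case, csv, row.names = FALSE)
  list(per_case = per_case, summary = summary)
}
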