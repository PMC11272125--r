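#' TIL proportion from class counts
#'
#' The slide-level tumor-infiltrating-lymphocyte proportion: lymphocyte
#' count divided by the total cell count, as a percentage.
#'
#' @param counts Named numeric vector with elements `cancer`, `lymphocyte`,
#'   `stroma` (extra names are ignored).
#' @return Percentage in `[0, 100]`.
#' @examples
#' til_proportion(c(cancer = 188, lymphocyte = 12, stroma = 50))  # 4.8
#' @export
til_proportion <- function(counts) {
  stopifnot(all(CELL_CLASSES %in% names(counts)))
  counts <- counts[CELL_CLASSES]
  if (any(counts < 0)) stopf("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stopf("undefined proportion: no cells detected")
  100 * counts[["lymphocyte"]] / total
}

#' Quantify TIL infiltration of one slide
#'
#' The composed pipeline: [segment_slide()], [nucleus_intensity()],
#' [extract_features()], [classify_cells()] and [til_proportion()].
#'
#' @param img RGB array of the H&E section.
#' @param model A [train_classifier()] model.
#' @param params [seg_params()].
#' @param slide_id Identifier for the result.
#' @return A list of class `slide_result`: `slide_id`, `counts` (per class),
#'   `til_proportion` (%), `n_cells`, and the per-cell table `cells`.
#' @export
quantify_slide <- function(img, model, params = seg_params(),
                           slide_id = "slide") {
  lab <- segment_slide(img, params)
  if (max(lab) == 0L)
    stopf("undefined proportion: no cells detected in slide '%s'", slide_id)
  cells <- extract_features(lab, nucleus_intensity(img),
                            slide_id = slide_id)
  cells <- classify_cells(model, cells)
  counts <- table(factor(cells$label, levels = CELL_CLASSES))
  counts <- setNames(as.numeric(counts), CELL_CLASSES)
  structure(list(slide_id = slide_id, counts = counts,
                 til_proportion = til_proportion(counts),
                 n_cells = nrow(cells), cells = cells),
            class = "slide_result")
}

#' @export
print.slide_result <- function(x, ...) {
  cat(sprintf("Slide '%s': %d cells (%d cancer, %d lymphocyte, %d stroma)\n",
              x$slide_id, x$n_cells, x$counts[["cancer"]],
              x$counts[["lymphocyte"]], x$counts[["stroma"]]))
  cat(sprintf("  TIL proportion: %.2f%%\n", x$til_proportion))
  invisible(x)
}

#' Split slides into high/low TIL groups at the cohort median
#'
#' The cutoff is the sample median of the TIL proportions (midpoint
#' convention for even n); values at or below the cutoff go to the low
#' group, values above to the high group.
#'
#' @param pi_values Numeric vector of TIL percentages (>= 2 values).
#' @return A list of class `til_groups`: `cutoff` and `assignment` (factor
#'   with levels `low`, `high`).
#' @examples
#' median_split(c(1, 2, 3, 4))  # cutoff 2.5
#' @export
median_split <- function(pi_values) {
  stopifnot(length(pi_values) >= 2L)
  cutoff <- median(pi_values)
  if (length(unique(pi_values)) == 1L)
    warnf("degenerate split: all TIL proportions identical; all in low group")
  assignment <- factor(ifelse(pi_values > cutoff, "high", "low"),
                       levels = c("low", "high"))
  structure(list(cutoff = cutoff, assignment = assignment),
            class = "til_groups")
}
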