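#' Segmentation precision and recall against ground truth
#'
#' Matches predicted to true nuclei greedily by decreasing intersection-
#' over-union (one-to-one); pairs with IoU at or above the threshold are
#' true positives.
#'
#' @param true_mask,pred_mask Integer label matrices of the same shape.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return List with `precision`, `recall`, `f1`, counts `tp`/`fp`/`fn`, and
#'   the match table.
#' @export
segmentation_metrics <- function(true_mask, pred_mask, iou_threshold = 0.5) {
  stopifnot(identical(dim(true_mask), dim(pred_mask)))
  n_true <- max(true_mask)
  n_pred <- max(pred_mask)
  if (n_true == 0L || n_pred == 0L) {
    tp <- 0L
    return(list(precision = if (n_pred) 0 else NA_real_,
                recall = if (n_true) 0 else NA_real_,
                f1 = NA_real_, tp = tp, fp = n_pred, fn = n_true,
                matches = data.frame()))
  }
  area_t <- tabulate(true_mask[true_mask > 0L], n_true)
  area_p <- tabulate(pred_mask[pred_mask > 0L], n_pred)
  sel <- true_mask > 0L & pred_mask > 0L
  ov <- as.data.frame(table(true = true_mask[sel], pred = pred_mask[sel]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0L, , drop = FALSE]
  ov$true <- as.integer(ov$true)
  ov$pred <- as.integer(ov$pred)
  ov$iou <- ov$Freq / (area_t[ov$true] + area_p[ov$pred] - ov$Freq)
  ov <- ov[order(-ov$iou), , drop = FALSE]
  used_t <- logical(n_true)
  used_p <- logical(n_pred)
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (ov$iou[i] < iou_threshold) break
    if (!used_t[ov$true[i]] && !used_p[ov$pred[i]]) {
      keep[i] <- TRUE
      used_t[ov$true[i]] <- TRUE
      used_p[ov$pred[i]] <- TRUE
    }
  }
  tp <- sum(keep)
  list(precision = tp / n_pred, recall = tp / n_true,
       f1 = 2 * tp / (n_true + n_pred),
       tp = tp, fp = n_pred - tp, fn = n_true - tp,
       matches = ov[keep, c("true", "pred", "iou"), drop = FALSE])
}
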