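#' Construct a labelled cellular training set
#'
#' A training set is the unit the cell classifier learns from: one labelled
#' feature table per cancer type. Every record must be labelled and all three
#' classes (cancer, lymphocyte, stroma) must be present.
#'
#' @param records Data frame with a `label` column (values in `cancer`,
#'   `lymphocyte`, `stroma`) and feature columns `f01`..`f43`.
#' @param cancer_type One of `"AEGJ"`, `"GAC"`, `"ESCC"` (other identifiers
#'   are allowed for synthetic sets).
#' @return A list of class `training_set`.
#' @export
training_set <- function(records, cancer_type = "AEGJ") {
  fc <- feature_columns()
  if (!all(fc %in% names(records)))
    stopf("records must contain feature columns f01..f43")
  if (is.null(records$label) || anyNA(records$label))
    stopf("every record must carry a class label")
  records$label <- as.character(records$label)
  if (!all(records$label %in% CELL_CLASSES))
    stopf("labels must be one of: %s", paste(CELL_CLASSES, collapse = ", "))
  missing_cls <- setdiff(CELL_CLASSES, unique(records$label))
  if (length(missing_cls))
    stopf("missing class in training set: %s",
          paste(missing_cls, collapse = ", "))
  if (!all(is.finite(as.matrix(records[fc]))))
    stopf("training features must be finite")
  structure(list(cancer_type = cancer_type, records = records),
            class = "training_set")
}

#' Generate a labelled training set from synthetic slides
#'
#' Simulates slides with equal class fractions, segments them, extracts
#' features, and labels each detected nucleus with the class of the
#' overlapping ground-truth nucleus -- emulating pathologists labelling the
#' cells outlined by the pipeline.
#'
#' @param n_per_class Records per class.
#' @param cancer_type Identifier stored with the set.
#' @param seed Integer seed driving the simulated slides.
#' @param params [seg_params()] used for segmentation.
#' @return A [training_set()].
#' @export
generate_training_set <- function(n_per_class = 200L, cancer_type = "AEGJ",
                                  seed = 1L, params = seg_params()) {
  recs <- list()
  counts <- setNames(integer(3L), CELL_CLASSES)
  for (i in seq_len(25L)) {
    sp <- slide_spec(width_px = 500L, height_px = 500L, n_nuclei = 120L,
                     class_fractions = c(cancer = 1, lymphocyte = 1,
                                         stroma = 1) / 3,
                     seed = seed * 100L + i)
    sl <- generate_slide(sp)
    lab <- segment_slide(sl$image, params)
    if (max(lab) == 0L) next
    ft <- extract_features(lab, nucleus_intensity(sl$image),
                           slide_id = sprintf("train%02d", i))
    ft$label <- transfer_truth_labels(lab, sl$truth)
    ft <- ft[!is.na(ft$label), , drop = FALSE]
    recs[[length(recs) + 1L]] <- ft
    counts <- counts + table(factor(ft$label, levels = CELL_CLASSES))
    if (all(counts >= n_per_class)) break
  }
  all_rec <- do.call(rbind, recs)
  keep <- unlist(lapply(CELL_CLASSES, function(cl)
    head(which(all_rec$label == cl), n_per_class)))
  training_set(all_rec[sort(keep), , drop = FALSE], cancer_type)
}

#' Train the three-class cell classifier
#'
#' Fits a support-vector machine (RBF kernel) on features standardised with
#' the training-set means and standard deviations. Defaults: cost `C = 1`,
#' kernel width `gamma = 1/43`.
#'
#' @param ts A [training_set()].
#' @param hyperparams List with elements `cost` and `gamma`.
#' @param seed Integer seed (stored in the model; the fit is deterministic
#'   given the data).
#' @return A list of class `til_classifier`.
#' @export
train_classifier <- function(ts, hyperparams = list(cost = 1, gamma = 1 / 43),
                             seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  fc <- feature_columns()
  X <- as.matrix(ts$records[fc])
  y <- factor(ts$records$label, levels = CELL_CLASSES)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  fit <- with_seed(seed, e1071::svm(
    x = Xs, y = y, kernel = "radial", cost = hyperparams$cost,
    gamma = hyperparams$gamma, scale = FALSE))
  structure(list(cancer_type = ts$cancer_type, fit = fit, center = mu,
                 scale = sdv, hyperparams = hyperparams, seed = seed,
                 registry_version = "1"),
            class = "til_classifier")
}

#' Classify segmented cells
#'
#' @param model A [train_classifier()] model.
#' @param cells Data frame with feature columns `f01`..`f43` (e.g. from
#'   [extract_features()]).
#' @return `cells` with a `label` column added (one of cancer, lymphocyte,
#'   stroma).
#' @export
classify_cells <- function(model, cells) {
  stopifnot(inherits(model, "til_classifier"))
  fc <- feature_columns()
  if (!all(fc %in% names(cells)))
    stopf("feature registry mismatch: cells lack columns f01..f43")
  if (nrow(cells) == 0L) {
    cells$label <- character(0)
    return(cells)
  }
  Xs <- scale(as.matrix(cells[fc]), center = model$center,
              scale = model$scale)
  cells$label <- as.character(predict(model$fit, Xs))
  cells
}

#' Stratified k-fold cross-validation of the cell classifier
#'
#' Records are assigned to `k` folds stratified by class (seeded); overall
#' accuracy pools correct predictions over all held-out folds, and per-class
#' accuracy is the held-out recall of each class.
#'
#' @inheritParams train_classifier
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @return A list of class `til_validation` with `overall_accuracy` (%),
#'   `per_class_accuracy` (%), `confusion` and metadata.
#' @export
cross_validate <- function(ts, k = 10L, seed = 1L,
                           hyperparams = list(cost = 1, gamma = 1 / 43)) {
  stopifnot(inherits(ts, "training_set"), k >= 2L)
  rec <- ts$records
  n <- nrow(rec)
  cls_n <- table(rec$label)
  if (any(cls_n < k))
    stopf("stratification error: class '%s' has fewer than k = %d members",
          names(cls_n)[which.min(cls_n)], k)
  folds <- integer(n)
  with_seed(seed, for (cl in CELL_CLASSES) {
    ii <- which(rec$label == cl)
    folds[ii] <- sample(rep(seq_len(k), length.out = length(ii)))
  })
  pred <- character(n)
  for (f in seq_len(k)) {
    tr <- training_set(rec[folds != f, , drop = FALSE], ts$cancer_type)
    mod <- train_classifier(tr, hyperparams, seed = seed)
    pred[folds == f] <- classify_cells(mod, rec[folds == f, ,
                                                drop = FALSE])$label
  }
  conf <- table(true = factor(rec$label, CELL_CLASSES),
                pred = factor(pred, CELL_CLASSES))
  per_class <- 100 * diag(conf) / rowSums(conf)
  structure(list(overall_accuracy = 100 * mean(pred == rec$label),
                 per_class_accuracy = per_class, confusion = conf,
                 k = k, n = n, seed = seed,
                 cancer_type = ts$cancer_type),
            class = "til_validation")
}

#' @export
print.til_validation <- function(x, ...) {
  cat(sprintf("Cross-validation (%s, %d-fold, n = %d)\n",
              x$cancer_type, x$k, x$n))
  cat(sprintf("  overall accuracy: %.2f%%\n", x$overall_accuracy))
  for (cl in names(x$per_class_accuracy))
    cat(sprintf("  %-11s accuracy: %.2f%%\n", cl, x$per_class_accuracy[cl]))
  invisible(x)
}

#' Concordance between automated and manual cell counts
#'
#' Pearson correlation of per-sample class proportions between automated
#' image analysis and manual (pathologist) counts, pooled over classes and
#' per class.
#'
#' @param auto_counts,manual_counts Numeric matrices (samples x 3 classes,
#'   columns cancer/lymphocyte/stroma) of per-sample cell counts.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `overall` correlation and `per_class` named vector.
#' @export
concordance_with_manual <- function(auto_counts, manual_counts,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  auto_counts <- as.matrix(auto_counts)
  manual_counts <- as.matrix(manual_counts)
  stopifnot(identical(dim(auto_counts), dim(manual_counts)),
            ncol(auto_counts) == 3L, nrow(auto_counts) >= 3L)
  pa <- auto_counts / rowSums(auto_counts)
  pm <- manual_counts / rowSums(manual_counts)
  if (sd(as.vector(pa)) == 0 || sd(as.vector(pm)) == 0)
    stopf("undefined correlation: zero variance in proportions")
  per_class <- vapply(seq_len(3L), function(j) {
    if (sd(pa[, j]) == 0 || sd(pm[, j]) == 0) return(NA_real_)
    cor(pa[, j], pm[, j], method = method)
  }, numeric(1L))
  names(per_class) <- CELL_CLASSES
  list(overall = cor(as.vector(pa), as.vector(pm), method = method),
       per_class = per_class)
}
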