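#' Read and write RGB images (PNG or TIFF)
#'
#' 8-bit RGB round trip: `write_image` stores a `height x width x 3` array
#' with values 0-255; `read_image` returns the same array.
#'
#' @param img RGB array, values in `[0, 255]`.
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image` returns the RGB array; `write_image` returns `path`
#'   invisibly.
#' @export
write_image <- function(img, path) {
  img <- validate_rgb(img)                  # scales 0-255 to [0, 1]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(img, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path,
                                                      bits.per.sample = 8L)
  else stopf("unsupported image format: .%s", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stopf("unsupported image format: .%s", ext)
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 4L)
    arr <- arr[, , 1:3, drop = FALSE]       # drop alpha
  if (length(dim(arr)) == 2L)
    arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  round(arr * 255)
}

#' Write / read a training set as CSV
#'
#' Dialect: header `cancer_type,label,f01,...,f43`; labels in
#' cancer/lymphocyte/stroma. `column_map` adapts external tables whose
#' feature columns are named differently: a named character vector mapping
#' external names to `f01`..`f43` (or to registry feature names).
#'
#' @param ts A [training_set()].
#' @param path CSV path.
#' @param column_map Optional named character vector, `c(external = "fNN")`.
#' @return `read_training_set` returns a [training_set()];
#'   `write_training_set` returns `path` invisibly.
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  out <- cbind(data.frame(cancer_type = ts$cancer_type,
                          label = ts$records$label),
               ts$records[feature_columns()])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path, column_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    reg <- feature_registry()
    to <- ifelse(column_map %in% reg$name,
                 reg$column[match(column_map, reg$name)], column_map)
    hit <- match(names(column_map), names(df))
    if (anyNA(hit)) stopf("column_map names absent from file: %s",
                          paste(names(column_map)[is.na(hit)], collapse = ", "))
    names(df)[hit] <- to
  }
  need <- c("cancer_type", "label", feature_columns())
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("registry mismatch in '%s': missing columns %s", path,
          paste(miss, collapse = ", "))
  bad <- which(!df$label %in% CELL_CLASSES)
  if (length(bad))
    stopf("unknown label '%s' at row %d of '%s'", df$label[bad[1L]],
          bad[1L], path)
  fm <- as.matrix(df[feature_columns()])
  if (!all(is.finite(fm))) {
    ij <- which(!is.finite(fm), arr.ind = TRUE)[1L, ]
    stopf("non-finite feature at row %d, column %s of '%s'", ij[1L],
          feature_columns()[ij[2L]], path)
  }
  training_set(df[c("label", feature_columns())],
               cancer_type = df$cancer_type[1L])
}

#' Write / read a patient cohort table as CSV
#'
#' Required columns: `id`, `til` (percentage in `[0, 100]` or missing),
#' `time` (years, non-negative), `event` (0/1); any additional covariate
#' columns are kept.
#'
#' @param cohort Data frame.
#' @param path CSV path.
#' @return `read_cohort` returns the validated data frame.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  validate_cohort(read.csv(path, stringsAsFactors = FALSE))
}

validate_cohort <- function(df) {
  need <- c("id", "til", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("cohort table missing columns: %s", paste(miss, collapse = ", "))
  bad <- which(df$time < 0)
  if (length(bad)) stopf("negative follow-up time at row %d", bad[1L])
  if (!all(df$event %in% c(0L, 1L)))
    stopf("event indicator must be 0 or 1")
  bad <- which(!is.na(df$til) & (df$til < 0 | df$til > 100))
  if (length(bad)) stopf("TIL proportion out of [0, 100] at row %d", bad[1L])
  df
}

#' Apply the ordered cohort exclusion flow
#'
#' Records are excluded by the first matching rule only, in the stated
#' order; the default flow excludes low-quality images first, then cases
#' with missing survival time.
#'
#' @param registry Data frame of cases with logical flag columns.
#' @param rules Character vector of flag column names, in exclusion order.
#' @return List with `retained` (data frame), `excluded` (named counts per
#'   rule), `n_input`, and `retention_pct`.
#' @examples
#' reg <- build_case_registry(1005, n_low_quality = 233,
#'                            n_missing_survival = 20)
#' apply_exclusions(reg)$retained |> nrow()  # 752
#' @export
apply_exclusions <- function(registry,
                             rules = c("low_quality", "missing_survival")) {
  miss <- setdiff(rules, names(registry))
  if (length(miss))
    stopf("registry lacks flag columns: %s", paste(miss, collapse = ", "))
  n <- nrow(registry)
  excluded <- setNames(integer(length(rules)), rules)
  alive <- rep(TRUE, n)
  for (r in rules) {
    hit <- alive & as.logical(registry[[r]])
    excluded[r] <- sum(hit)
    alive <- alive & !hit
  }
  list(retained = registry[alive, , drop = FALSE], excluded = excluded,
       n_input = n, retention_pct = 100 * sum(alive) / n)
}

#' Build a flagged case registry from exclusion counts
#'
#' Constructs a registry with the given numbers of low-quality-image cases
#' and, among the remainder, cases missing survival time -- the inputs to
#' [apply_exclusions()] when reproducing a published selection flow.
#'
#' @param n_total Total cases.
#' @param n_low_quality Cases flagged as low-quality images.
#' @param n_missing_survival Cases (without the low-quality flag) missing
#'   survival time.
#' @param cancer_type Label stored with each case.
#' @return Data frame with `id`, `cancer_type`, `low_quality`,
#'   `missing_survival`.
#' @export
build_case_registry <- function(n_total, n_low_quality, n_missing_survival,
                                cancer_type = "ESCC") {
  stopifnot(n_low_quality + n_missing_survival <= n_total)
  data.frame(id = seq_len(n_total), cancer_type = cancer_type,
             low_quality = seq_len(n_total) <= n_low_quality,
             missing_survival = seq_len(n_total) >
               n_low_quality & seq_len(n_total) <=
               n_low_quality + n_missing_survival)
}

#' Default run configuration
#'
#' One serialisable list holding every tunable of the pipeline; [run_all()]
#' echoes the resolved configuration into its output directory.
#'
#' @param seed Master seed; all randomness in a run derives from it.
#' @return A nested list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       segmentation = unclass(seg_params()),
       classifier = list(cost = 1, gamma = 1 / 43),
       k_folds = 10L,
       neighbor_radius = 50,
       training = list(n_per_class = 150L),
       slides = list(width_px = 600L, height_px = 600L, n_nuclei = 150L,
                     lymphocyte_fractions = c(0.05, 0.2, 0.4),
                     n_per_level = 2L),
       cohort = list(n_patients = 500L, hr_per_til_point = 0.965))
}

#' @rdname default_run_config
#' @param path YAML file path.
#' @param config Configuration list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname default_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
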