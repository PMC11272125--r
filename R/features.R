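#' The fixed 43-feature registry
#'
#' The ordered, versioned set of per-nucleus features fed to the classifier:
#' 12 shape, 12 intensity, 13 grey-level co-occurrence texture, 3
#' neighbourhood and 3 boundary-gradient features. Feature columns in
#' [extract_features()] output and training-set CSVs are named `f01`..`f43`
#' in this order.
#'
#' @return A data frame with columns `column` (`f01`..`f43`), `name` and
#'   `group`; attribute `version` identifies the registry revision.
#' @export
feature_registry <- function() {
  defs <- rbind(
    data.frame(group = "shape", name = c(
      "area", "perimeter", "major_axis", "minor_axis", "eccentricity",
      "solidity", "extent", "circularity", "convex_area", "orientation",
      "equiv_diameter", "boundary_roughness")),
    data.frame(group = "intensity", name = c(
      "int_mean", "int_sd", "int_min", "int_max", "int_median", "int_mad",
      "int_skewness", "int_kurtosis", "int_q10", "int_q90", "int_integrated",
      "ring_contrast")),
    data.frame(group = "texture", name = c(
      "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity", "glcm_asm",
      "glcm_energy", "glcm_entropy", "glcm_correlation", "glcm_mean",
      "glcm_variance", "glcm_sd", "glcm_cluster_shade",
      "glcm_cluster_prominence", "glcm_max_prob")),
    data.frame(group = "neighbourhood", name = c(
      "neighbor_count", "nn_distance", "local_density")),
    data.frame(group = "gradient", name = c(
      "grad_mean", "grad_sd", "grad_max")))
  defs <- cbind(column = sprintf("f%02d", seq_len(nrow(defs))), defs)
  stopifnot(nrow(defs) == 43L, !anyDuplicated(defs$name))
  structure(defs, version = "1")
}

feature_columns <- function() sprintf("f%02d", 1:43)

#' Extract the 43-feature vector for every segmented nucleus
#'
#' Shape features come from the region mask (moment-based axes and
#' eccentricity, Crofton perimeter, convex hull solidity), intensity features
#' from the nucleus-signal grayscale within the region (including contrast
#' against a 2-px dilated ring), texture features from a 32-level grey-level
#' co-occurrence matrix on the region's bounding patch (background masked to
#' the region median, 4 symmetric offsets averaged), neighbourhood features
#' from centroid distances, and gradient features from the Sobel gradient
#' magnitude on the region boundary.
#'
#' @param labels Integer label matrix (from [segment_slide()] or
#'   [watershed_split()]).
#' @param gray Grayscale matrix (same shape) from [to_nucleus_grayscale()].
#' @param registry Feature registry; only version "1" is supported.
#' @param slide_id Identifier stored with each record.
#' @param neighbor_radius Radius (px) for the neighbour count and local
#'   density.
#' @return A data frame with one row per nucleus: `cell_id`, `slide_id`,
#'   centroid `row`/`col`, and feature columns `f01`..`f43`.
#' @export
extract_features <- function(labels, gray, registry = feature_registry(),
                             slide_id = "slide", neighbor_radius = 50) {
  stopifnot(identical(dim(labels), dim(gray)))
  if (!identical(attr(registry, "version"), "1"))
    stopf("unsupported feature registry version")
  k <- max(labels)
  if (k == 0L)
    return(cbind(data.frame(cell_id = integer(0), slide_id = character(0),
                            row = numeric(0), col = numeric(0)),
                 as.data.frame(matrix(numeric(0), 0L, 43L,
                                      dimnames = list(NULL,
                                                      feature_columns())))))
  nr <- nrow(labels)
  idx_by_lab <- split(which(labels > 0L), labels[labels > 0L])
  grad <- sobel_magnitude(gray)
  feats <- matrix(NA_real_, k, 43L, dimnames = list(NULL, feature_columns()))
  cent <- matrix(NA_real_, k, 2L)
  for (li in seq_len(k)) {
    idx <- idx_by_lab[[as.character(li)]]
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    cent[li, ] <- c(mean(rr), mean(cc))
    feats[li, 1:12] <- shape_features(rr, cc)
    feats[li, 13:24] <- intensity_features(idx, rr, cc, labels, gray, li)
    feats[li, 25:37] <- glcm_features(rr, cc, labels, gray, li)
    feats[li, 41:43] <- gradient_features(rr, cc, labels, grad, li)
  }
  feats[, 38:40] <- neighborhood_features(cent, neighbor_radius,
                                          dim(labels))
  stopifnot(all(is.finite(feats)))
  cbind(data.frame(cell_id = seq_len(k), slide_id = slide_id,
                   row = cent[, 1L], col = cent[, 2L]),
        as.data.frame(feats))
}

# --- shape -------------------------------------------------------------------

shape_features <- function(rr, cc) {
  area <- length(rr)
  mr <- mean(rr); mc <- mean(cc)
  # second central moments with a 1/12 pixel-extent correction
  mu20 <- mean((rr - mr)^2) + 1 / 12
  mu02 <- mean((cc - mc)^2) + 1 / 12
  mu11 <- mean((rr - mr) * (cc - mc))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(max(l2, 0))
  ecc <- sqrt(max(1 - l2 / l1, 0))
  orientation <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  per <- crofton_perimeter(rr, cc)
  hull <- convex_hull_area(rr, cc)
  bbox <- (diff(range(rr)) + 1) * (diff(range(cc)) + 1)
  c(area = area, perimeter = per, major_axis = major, minor_axis = minor,
    eccentricity = ecc, solidity = min(area / hull, 1), extent = area / bbox,
    circularity = 4 * pi * area / per^2, convex_area = hull,
    orientation = orientation, equiv_diameter = sqrt(4 * area / pi),
    boundary_roughness = per / (2 * sqrt(pi * area)))
}

region_patch <- function(rr, cc, pad = 0L) {
  r0 <- min(rr) - pad; c0 <- min(cc) - pad
  m <- matrix(FALSE, diff(range(rr)) + 1L + 2L * pad,
              diff(range(cc)) + 1L + 2L * pad)
  m[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
  list(mask = m, r0 = r0, c0 = c0)
}

# Crofton-style perimeter from intercept counts in 4 directions.
crofton_perimeter <- function(rr, cc) {
  m <- region_patch(rr, cc, pad = 1L)$mask
  ih <- sum(abs(m[, -1L] != m[, -ncol(m)])) + sum(m[, 1L]) + sum(m[, ncol(m)])
  iv <- sum(abs(m[-1L, ] != m[-nrow(m), ])) + sum(m[1L, ]) + sum(m[nrow(m), ])
  d1 <- sum(m[-1L, -1L] != m[-nrow(m), -ncol(m)])
  d2 <- sum(m[-nrow(m), -1L] != m[-1L, -ncol(m)])
  (pi / 8) * (ih + iv + (d1 + d2) / sqrt(2))
}

# Pixel count inside the convex hull of the region's pixel centres,
# estimated from the hull polygon area via Pick's theorem.
convex_hull_area <- function(rr, cc) {
  if (length(rr) <= 2L) return(length(rr))
  pts <- unique(cbind(cc, rr))
  if (nrow(pts) <= 2L) return(length(rr))
  h <- grDevices::chull(pts)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  n <- length(x)
  a <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  if (a == 0) return(length(rr))
  b <- sum(mapply(function(i, j) {
    dgcd(abs(x[i] - x[j]), abs(y[i] - y[j]))
  }, seq_len(n), c(seq_len(n)[-1L], 1L)))
  a + b / 2 + 1
}

dgcd <- function(a, b) if (b == 0) max(a, 1) else dgcd(b, a %% b)

# --- intensity ---------------------------------------------------------------

intensity_features <- function(idx, rr, cc, labels, gray, li) {
  v <- gray[idx]
  s <- sd(v)
  if (is.na(s)) s <- 0
  z <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
  # 2-px dilated ring around the region
  p <- region_patch(rr, cc, pad = 2L)
  ring <- binary_dilate(p$mask, 2L) & !p$mask
  ij <- which(ring, arr.ind = TRUE)
  gr <- ij[, 1L] + p$r0 - 1L
  gc <- ij[, 2L] + p$c0 - 1L
  ok <- gr >= 1L & gr <= nrow(gray) & gc >= 1L & gc <= ncol(gray)
  ring_mean <- if (any(ok)) mean(gray[cbind(gr[ok], gc[ok])]) else mean(v)
  c(int_mean = mean(v), int_sd = s, int_min = min(v), int_max = max(v),
    int_median = median(v), int_mad = mad(v),
    int_skewness = mean(z^3),
    int_kurtosis = if (s > 0) mean(z^4) - 3 else 0,
    int_q10 = unname(quantile(v, 0.1)), int_q90 = unname(quantile(v, 0.9)),
    int_integrated = sum(v), ring_contrast = mean(v) - ring_mean)
}

# --- texture -----------------------------------------------------------------

GLCM_LEVELS <- 32L

glcm_features <- function(rr, cc, labels, gray, li) {
  r0 <- min(rr); c0 <- min(cc)
  rows <- r0:max(rr); cols <- c0:max(cc)
  patch <- gray[rows, cols, drop = FALSE]
  inreg <- labels[rows, cols, drop = FALSE] == li
  patch[!inreg] <- median(patch[inreg])
  q <- matrix(pmin(floor(patch * GLCM_LEVELS), GLCM_LEVELS - 1L) + 1L,
              nrow(patch), ncol(patch))
  P <- matrix(0, GLCM_LEVELS, GLCM_LEVELS)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (o in offs) {
    nr <- nrow(q); nc <- ncol(q)
    r1 <- seq_len(nr - abs(o[1L])) + max(0L, -o[1L])
    c1 <- seq_len(nc - abs(o[2L])) + max(0L, -o[2L])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + o[1L], c1 + o[2L], drop = FALSE]
    if (!length(a)) next
    tab <- table(factor(a, levels = 1:GLCM_LEVELS),
                 factor(b, levels = 1:GLCM_LEVELS))
    P <- P + tab + t(tab)                   # symmetric accumulation
  }
  if (sum(P) == 0) P[1L, 1L] <- 1
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  pij <- P
  mu <- sum(i * pij)
  vr <- sum((i - mu)^2 * pij)
  pos <- pij[pij > 0]
  c(glcm_contrast = sum(pij * (i - j)^2),
    glcm_dissimilarity = sum(pij * abs(i - j)),
    glcm_homogeneity = sum(pij / (1 + (i - j)^2)),
    glcm_asm = sum(pij^2),
    glcm_energy = sqrt(sum(pij^2)),
    glcm_entropy = -sum(pos * log(pos)),
    glcm_correlation = if (vr > 0) sum((i - mu) * (j - mu) * pij) / vr else 1,
    glcm_mean = mu,
    glcm_variance = vr,
    glcm_sd = sqrt(vr),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * pij),
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * pij),
    glcm_max_prob = max(pij))
}

# --- neighbourhood -----------------------------------------------------------

#' Count neighbouring cells within a radius
#'
#' For each centroid, the number of other centroids within Euclidean
#' distance `radius_px`.
#'
#' @param centroids Two-column matrix of `(row, col)` centroids.
#' @param radius_px Positive radius in pixels.
#' @return Integer vector of counts.
#' @export
neighbor_count <- function(centroids, radius_px) {
  stopifnot(radius_px > 0)
  n <- nrow(centroids)
  if (n <= 1L) return(rep(0L, n))
  d <- as.matrix(dist(centroids))
  diag(d) <- Inf
  as.integer(rowSums(d <= radius_px))
}

neighborhood_features <- function(cent, radius, dims) {
  n <- nrow(cent)
  cnt <- neighbor_count(cent, radius)
  nn <- if (n > 1L) {
    d <- as.matrix(dist(cent))
    diag(d) <- Inf
    apply(d, 1L, min)
  } else sqrt(sum(dims^2))                  # sentinel: image diagonal
  cbind(neighbor_count = cnt, nn_distance = nn,
        local_density = cnt / (pi * radius^2))
}

# --- gradient ----------------------------------------------------------------

sobel_magnitude <- function(gray) {
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3L, 3L)
  gx <- conv3(gray, sx)
  gy <- conv3(gray, t(sx))
  sqrt(gx^2 + gy^2)
}

conv3 <- function(m, k) {
  out <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1)
    for (dc in -1:1) {
      w <- k[dr + 2L, dc + 2L]
      if (w != 0)
        out <- out + w * shift_mat(m, dr, dc, 0)
    }
  out
}

gradient_features <- function(rr, cc, labels, grad, li) {
  nr <- nrow(labels); ncl <- ncol(labels)
  on_boundary <- logical(length(rr))
  for (k in seq_len(4L)) {
    dr <- DR4_R[k]; dc <- DC4_R[k]
    r2 <- rr + dr; c2 <- cc + dc
    outside <- r2 < 1L | r2 > nr | c2 < 1L | c2 > ncl
    nb <- rep(FALSE, length(rr))
    nb[!outside] <- labels[cbind(r2[!outside], c2[!outside])] != li
    on_boundary <- on_boundary | outside | nb
  }
  v <- grad[cbind(rr, cc)][on_boundary]
  if (!length(v)) v <- 0
  s <- sd(v)
  c(grad_mean = mean(v), grad_sd = if (is.na(s)) 0 else s, grad_max = max(v))
}

DR4_R <- c(-1L, 1L, 0L, 0L)
DC4_R <- c(0L, 0L, -1L, 1L)
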