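#' Specification of a synthetic H&E-like slide
#'
#' Describes a simulated haematoxylin-eosin stained section: an eosin-pink
#' background with haematoxylin-dark nuclei of three morphologies mirroring
#' the classes the classifier must separate -- large cancer nuclei with
#' variable texture and perturbed boundaries, small round dark lymphocyte
#' nuclei, and elongated stromal (fibroblast/endothelial) nuclei.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param class_fractions Named numeric triple `(cancer, lymphocyte, stroma)`
#'   of class probabilities; must sum to 1.
#' @param overlap_fraction Proportion of nuclei intentionally placed touching
#'   an already-placed neighbour, to exercise watershed splitting.
#' @param noise_sd Standard deviation of additive per-pixel Gaussian noise
#'   (on the `[0, 1]` intensity scale).
#' @param blur_sigma Gaussian blur applied to the rendered image, in px.
#' @param seed Integer RNG seed; identical specs give bit-identical slides.
#' @return A list of class `slide_spec`.
#' @export
slide_spec <- function(width_px = 1000L, height_px = 1000L, n_nuclei = 200L,
                       class_fractions = c(cancer = 0.5, lymphocyte = 0.2,
                                           stroma = 0.3),
                       overlap_fraction = 0, noise_sd = 0.02,
                       blur_sigma = 0.8, seed = 1L) {
  stopifnot(width_px >= 1, height_px >= 1, n_nuclei >= 0,
            length(class_fractions) == 3L,
            overlap_fraction >= 0, overlap_fraction <= 1,
            noise_sd >= 0, blur_sigma >= 0)
  if (any(class_fractions < 0) || any(class_fractions > 1) ||
      abs(sum(class_fractions) - 1) > 1e-9)
    stopf("class_fractions must lie in [0,1] and sum to 1")
  names(class_fractions) <- CELL_CLASSES
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 n_nuclei = as.integer(n_nuclei),
                 class_fractions = class_fractions,
                 overlap_fraction = overlap_fraction,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "slide_spec")
}

# Morphology priors (px): chosen so size, eccentricity and texture separate
# the three classes, as the classifier requires.
NUCLEUS_PRIORS <- list(
  cancer     = list(radius = c(8, 16), boundary_noise = 0.08,
                    texture = 0.15, color = c(0.36, 0.24, 0.52)),
  lymphocyte = list(radius = c(3, 5), boundary_noise = 0,
                    texture = 0, color = c(0.20, 0.13, 0.40)),
  stroma     = list(major = c(7, 12), axis_ratio = c(3, 5),
                    texture = 0.05, color = c(0.48, 0.35, 0.58))
)
EOSIN_BACKGROUND <- c(0.93, 0.76, 0.83)

#' Generate a synthetic H&E-like slide with ground truth
#'
#' Places nuclei by rejection sampling (retry cap 1000 per nucleus; failure
#' signals an error), renders them over an eosin-pink background, adds
#' Gaussian pixel noise and blur, and quantises to 8-bit. The returned ground
#' truth contains the true label map, per-nucleus classes and centroids, and
#' the true TIL proportion `100 * lymphocytes / n_nuclei`.
#'
#' @param spec A [slide_spec()].
#' @return A list with `image` (`height x width x 3` array, values 0-255) and
#'   `truth` (list: `mask` integer label matrix, `classes` character vector,
#'   `centroids` matrix of `(row, col)`, `til_proportion` percentage, `NA`
#'   with attribute `undefined = TRUE` when `n_nuclei = 0`).
#' @examples
#' sl <- generate_slide(slide_spec(width_px = 200, height_px = 200,
#'                                 n_nuclei = 10, seed = 42))
#' sl$truth$til_proportion
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  with_seed(spec$seed, generate_slide_impl(spec))
}

generate_slide_impl <- function(spec) {
  h <- spec$height_px; w <- spec$width_px; n <- spec$n_nuclei
  classes <- if (n > 0)
    CELL_CLASSES[sample.int(3L, n, replace = TRUE,
                            prob = spec$class_fractions)] else character(0)

  shapes <- lapply(classes, draw_shape_params)
  rb <- vapply(shapes, `[[`, numeric(1L), "bound")

  centers <- matrix(NA_real_, n, 2L)
  touching <- if (n > 1) runif(n) < spec$overlap_fraction else logical(n)
  touching[1L] <- FALSE
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      if (touching[i]) {
        j <- sample.int(i - 1L, 1L)
        d <- rb[j] + rb[i] * runif(1, 0.2, 0.8)
        ang <- runif(1, 0, 2 * pi)
        cand <- centers[j, ] + d * c(cos(ang), sin(ang))
        if (cand[1L] < rb[i] + 1 || cand[1L] > h - rb[i] ||
            cand[2L] < rb[i] + 1 || cand[2L] > w - rb[i]) next
        others <- setdiff(seq_len(i - 1L), j)
      } else {
        if (h - 2 * rb[i] - 2 < 1 || w - 2 * rb[i] - 2 < 1) next
        cand <- c(runif(1, rb[i] + 1, h - rb[i]),
                  runif(1, rb[i] + 1, w - rb[i]))
        others <- seq_len(i - 1L)
      }
      if (length(others)) {
        dd <- sqrt((centers[others, 1L] - cand[1L])^2 +
                   (centers[others, 2L] - cand[2L])^2)
        if (any(dd <= rb[others] + rb[i] + 2)) next
      }
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("placement failure: nucleus %d could not be placed in %d tries",
            i, 1000L)
  }

  mask <- matrix(0L, h, w)
  ch_r <- matrix(EOSIN_BACKGROUND[1L], h, w)
  ch_g <- matrix(EOSIN_BACKGROUND[2L], h, w)
  ch_b <- matrix(EOSIN_BACKGROUND[3L], h, w)
  for (i in seq_len(n)) {
    px <- rasterize_nucleus(shapes[[i]], centers[i, ], h, w)
    if (!length(px$idx)) next
    mask[px$idx] <- i                       # later (touching) nuclei overwrite
    col <- NUCLEUS_PRIORS[[classes[i]]]$color
    tex <- shapes[[i]]$texture
    f <- if (tex > 0) 1 + runif(length(px$idx), -tex, tex) else 1
    ch_r[px$idx] <- col[1L] * f
    ch_g[px$idx] <- col[2L] * f
    ch_b[px$idx] <- col[3L] * f
  }

  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) {
    ch <- list(ch_r, ch_g, ch_b)[[k]]
    if (spec$noise_sd > 0) ch <- ch + rnorm(h * w, sd = spec$noise_sd)
    if (spec$blur_sigma > 0) ch <- cpp_gaussian_blur(ch, spec$blur_sigma)
    img[, , k] <- pmin(pmax(ch, 0), 1)
  }
  img <- round(img * 255)

  til <- if (n > 0) 100 * sum(classes == "lymphocyte") / n
  else structure(NA_real_, undefined = TRUE)
  list(image = img,
       truth = list(mask = mask, classes = classes, centroids = centers,
                    til_proportion = til),
       spec = spec)
}

draw_shape_params <- function(class) {
  pr <- NUCLEUS_PRIORS[[class]]
  if (class == "stroma") {
    a <- runif(1, pr$major[1L], pr$major[2L])
    b <- max(a / runif(1, pr$axis_ratio[1L], pr$axis_ratio[2L]), 1.5)
    list(type = "ellipse", a = a, b = b, theta = runif(1, 0, pi),
         texture = pr$texture, bound = a)
  } else {
    r <- runif(1, pr$radius[1L], pr$radius[2L])
    bn <- pr$boundary_noise
    amp <- if (bn > 0) runif(2, 0.3 * bn, bn) else c(0, 0)
    phs <- runif(2, 0, 2 * pi)
    list(type = "blob", r = r, amp = amp, phase = phs,
         texture = pr$texture, bound = r * (1 + sum(amp)))
  }
}

# Pixel indices (column-major) covered by one nucleus.
rasterize_nucleus <- function(sh, center, h, w) {
  rb <- ceiling(sh$bound)
  rows <- max(1L, floor(center[1L] - rb)):min(h, ceiling(center[1L] + rb))
  cols <- max(1L, floor(center[2L] - rb)):min(w, ceiling(center[2L] + rb))
  dy <- rows - center[1L]
  dx <- cols - center[2L]
  DY <- matrix(dy, length(rows), length(cols))
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  inside <- if (sh$type == "ellipse") {
    xr <- DX * cos(sh$theta) + DY * sin(sh$theta)
    yr <- -DX * sin(sh$theta) + DY * cos(sh$theta)
    (xr / sh$a)^2 + (yr / sh$b)^2 <= 1
  } else {
    rr <- sqrt(DX^2 + DY^2)
    th <- atan2(DY, DX)
    rloc <- sh$r * (1 + sh$amp[1L] * cos(2 * th + sh$phase[1L]) +
                      sh$amp[2L] * cos(3 * th + sh$phase[2L]))
    rr <= rloc
  }
  ij <- which(inside, arr.ind = TRUE)
  list(idx = (cols[ij[, 2L]] - 1L) * h + rows[ij[, 1L]])
}

#' Transfer ground-truth classes onto segmented nuclei
#'
#' Assigns each predicted label the class of the ground-truth nucleus with
#' the largest pixel overlap; predicted labels overlapping no true nucleus
#' get `NA`.
#'
#' @param pred_labels Integer label matrix from [segment_slide()].
#' @param truth Ground-truth list from [generate_slide()].
#' @return Character vector of length `max(pred_labels)`.
#' @export
transfer_truth_labels <- function(pred_labels, truth) {
  k <- max(pred_labels)
  if (k == 0L) return(character(0))
  out <- rep(NA_character_, k)
  sel <- pred_labels > 0L & truth$mask > 0L
  if (!any(sel)) return(out)
  tab <- table(pred = pred_labels[sel], true = truth$mask[sel])
  best <- apply(tab, 1L, which.max)
  truth_ids <- as.integer(colnames(tab))[best]
  out[as.integer(rownames(tab))] <- truth$classes[truth_ids]
  out
}
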