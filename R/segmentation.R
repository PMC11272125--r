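#' Segmentation parameters
#'
#' Bundles the tunable parameters of nucleus segmentation.
#'
#' @param opening_radius_px Radius (px) of the disk structuring element used
#'   for morphological opening after thresholding. `0` disables opening.
#' @param min_nucleus_area_px Minimum area (px) of a retained nucleus;
#'   smaller watershed regions are discarded as debris.
#' @param hmax_suppression Prominence `h` (px of distance-transform height)
#'   below which neighbouring distance-transform maxima are merged before
#'   seeding the watershed.
#' @param connectivity Pixel connectivity, 4 or 8.
#' @param grid Tiling grid `(rows, cols)` used by [segment_slide()]; the
#'   default `c(10, 10)` processes a section in 100 equal parts.
#' @param min_contrast Minimum standard deviation of the CIELAB lightness
#'   channel for a slide to be considered non-blank; below it
#'   [segment_slide()] returns an empty label map.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(opening_radius_px = 1L,
                       min_nucleus_area_px = 9L,
                       hmax_suppression = 2,
                       connectivity = 8L,
                       grid = c(10L, 10L),
                       min_contrast = 4) {
  stopifnot(opening_radius_px >= 0, min_nucleus_area_px >= 1,
            hmax_suppression >= 0, connectivity %in% c(4L, 8L),
            length(grid) == 2L, all(grid >= 1))
  structure(list(opening_radius_px = as.integer(opening_radius_px),
                 min_nucleus_area_px = as.integer(min_nucleus_area_px),
                 hmax_suppression = hmax_suppression,
                 connectivity = as.integer(connectivity),
                 grid = as.integer(grid),
                 min_contrast = min_contrast),
            class = "seg_params")
}

#' Otsu threshold of a grayscale image
#'
#' Histogram threshold maximising the between-class variance
#' \eqn{\sigma^2_B(t) = w_0 w_1 (\mu_0 - \mu_1)^2} of background vs.
#' foreground. Values are binned into `n_bins` right-open bins on `[0, 1]`;
#' candidate thresholds are the interior bin boundaries and ties are broken
#' towards the lowest boundary.
#'
#' @param gray Numeric matrix with values in `[0, 1]` and at least two
#'   distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return The threshold `t*` in `(0, 1)`; pixels with `gray > t*` are
#'   foreground.
#' @export
otsu_threshold <- function(gray, n_bins = 256L) {
  if (any(!is.finite(gray))) stopf("gray image contains non-finite values")
  if (min(gray) < 0 || max(gray) > 1) stopf("gray values must lie in [0, 1]")
  if (length(unique(as.vector(gray))) < 2L)
    stopf("degenerate image: constant grayscale, no threshold exists")
  n_bins <- as.integer(n_bins)
  bin <- pmin(floor(as.vector(gray) * n_bins), n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  k <- seq_len(n_bins - 1L)                    # boundary after bin k
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  sigma_b[valid] <- (mu_t * w0[k][valid] - mu0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  best <- which.max(sigma_b)                   # lowest maximiser
  best / n_bins
}

#' Threshold and morphologically open a grayscale image
#'
#' Applies `gray > t` and an opening (erosion then dilation) with a disk of
#' radius `params$opening_radius_px`, removing speckle smaller than the
#' structuring element and smoothing cell edges.
#'
#' @inheritParams otsu_threshold
#' @param t Threshold, e.g. from [otsu_threshold()].
#' @param params A [seg_params()] list.
#' @return A logical matrix (foreground mask).
#' @export
binarize_and_open <- function(gray, t, params = seg_params()) {
  mask <- gray > t
  binary_open(mask, params$opening_radius_px)
}

#' Split touching nuclei with a marker-controlled watershed
#'
#' Connected foreground clusters are split at necks: the Euclidean distance
#' transform of the mask is computed, its maxima with prominence at least
#' `params$hmax_suppression` become seeds (h-maxima via morphological
#' reconstruction), and a watershed on the negated distance transform assigns
#' every foreground pixel to a seed. Regions smaller than
#' `params$min_nucleus_area_px` are discarded and labels are made contiguous.
#'
#' @param mask Logical matrix of nuclear foreground.
#' @param gray Optional grayscale image (same shape); kept for interface
#'   compatibility, the current seeding uses the distance transform only.
#' @param params A [seg_params()] list.
#' @return An integer label matrix (`0` = background, labels `1..K`).
#' @export
watershed_split <- function(mask, gray = NULL, params = seg_params()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  d <- cpp_edt(mask)
  h <- params$hmax_suppression
  hm <- if (h > 0) cpp_reconstruct(pmax(d - h, 0), d) else d
  seeds <- cpp_regional_maxima(hm, mask)
  markers <- cpp_label_components(seeds, params$connectivity)
  lab <- cpp_watershed(-d, markers, mask)
  filter_small_regions(lab, params$min_nucleus_area_px)
}

# Drop labelled regions below a minimum area and relabel 1..K contiguously.
filter_small_regions <- function(lab, min_area) {
  if (!any(lab > 0L)) return(lab)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  map <- integer(length(areas))
  map[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

#' Tile an image into a regular grid
#'
#' Divides an image into `grid[1] x grid[2]` tiles in row-major order. Tile
#' extents use floor division; remainder pixels are appended to the tiles of
#' the last column/row, so reassembling the tiles at their offsets
#' reproduces the input exactly.
#'
#' @param img A matrix or a `height x width x channels` array.
#' @param grid Integer pair `(rows, cols)`; default `c(10, 10)` gives the 100
#'   equal parts used for whole sections.
#' @return A list with `tiles` (list of sub-images, row-major) and `offsets`,
#'   a data frame with 0-based `row_off`, `col_off` and tile `rows`, `cols`.
#' @export
tile_image <- function(img, grid = c(10L, 10L)) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]
  grid <- as.integer(grid)
  if (h < grid[1L] || w < grid[2L]) {
    warnf("image (%d x %d) smaller than the %d x %d grid; using a single tile",
          h, w, grid[1L], grid[2L])
    grid <- c(1L, 1L)
  }
  bh <- h %/% grid[1L]; bw <- w %/% grid[2L]
  r0 <- (seq_len(grid[1L]) - 1L) * bh
  c0 <- (seq_len(grid[2L]) - 1L) * bw
  rh <- rep(bh, grid[1L]); rh[grid[1L]] <- h - r0[grid[1L]]
  cw <- rep(bw, grid[2L]); cw[grid[2L]] <- w - c0[grid[2L]]
  tiles <- vector("list", grid[1L] * grid[2L])
  off <- data.frame(row_off = integer(0), col_off = integer(0),
                    rows = integer(0), cols = integer(0))
  idx <- 0L
  for (i in seq_len(grid[1L])) {
    for (j in seq_len(grid[2L])) {
      idx <- idx + 1L
      rows <- (r0[i] + 1L):(r0[i] + rh[i])
      cols <- (c0[j] + 1L):(c0[j] + cw[j])
      tiles[[idx]] <- if (length(d) == 3L) img[rows, cols, , drop = FALSE]
      else img[rows, cols, drop = FALSE]
      off[idx, ] <- c(r0[i], c0[j], rh[i], cw[j])
    }
  }
  list(tiles = tiles, offsets = off)
}

#' Segment all nuclei in an RGB section image
#'
#' The full detection chain: nucleus-signal grayscale conversion, a global
#' Otsu threshold, then per-tile morphological opening and watershed
#' splitting over a `params$grid` tiling, merged back at the tile offsets.
#' Nuclei straddling a tile boundary are deduplicated by keeping the largest
#' fragment of each group of labels touching across a boundary. A slide whose
#' lightness variation falls below `params$min_contrast` (no stained nuclei)
#' yields an empty label map.
#'
#' @param img RGB array (`height x width x 3`, values in `[0, 255]` or
#'   `[0, 1]`).
#' @param params A [seg_params()] list.
#' @return Integer label matrix of the full image; `0` = background.
#' @examples
#' sl <- generate_slide(slide_spec(width_px = 220, height_px = 220,
#'                                 n_nuclei = 12, seed = 1))
#' lab <- segment_slide(sl$image, seg_params(grid = c(2, 2)))
#' max(lab)  # number of detected nuclei
#' @export
segment_slide <- function(img, params = seg_params()) {
  img <- validate_rgb(img)
  lab3 <- rgb_to_lab(img)
  L <- lab3[, , 1L]
  if (sd(L) < params$min_contrast)            # blank / unstained slide
    return(matrix(0L, dim(img)[1L], dim(img)[2L]))
  z <- -(L - mean(L)) / sd(L)
  rng <- range(z)
  gray <- (z - rng[1L]) / (rng[2L] - rng[1L])
  t_star <- otsu_threshold(gray)

  tl <- tile_image(gray, params$grid)
  global <- matrix(0L, nrow(gray), ncol(gray))
  next_label <- 0L
  for (i in seq_along(tl$tiles)) {
    o <- tl$offsets[i, ]
    mask <- binarize_and_open(tl$tiles[[i]], t_star, params)
    lab <- watershed_split(mask, tl$tiles[[i]], params)
    if (max(lab) > 0L) {
      lab[lab > 0L] <- lab[lab > 0L] + next_label
      next_label <- max(lab)
      global[o$row_off + seq_len(o$rows), o$col_off + seq_len(o$cols)] <-
        pmax(global[o$row_off + seq_len(o$rows),
                    o$col_off + seq_len(o$cols)], lab)
    }
  }
  dedup_boundary_fragments(global, tl$offsets)
}

# Suppress the smaller fragments of nuclei cut by tile boundaries: labels
# adjacent across an internal tile edge are grouped (union-find) and only the
# largest fragment of each group is kept.
dedup_boundary_fragments <- function(lab, offsets) {
  if (!any(lab > 0L)) return(lab)
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  link_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pr))) union(pr[i, 1L], pr[i, 2L])
    }
  }
  row_cuts <- setdiff(unique(offsets$row_off), 0L)
  col_cuts <- setdiff(unique(offsets$col_off), 0L)
  for (r in row_cuts) link_pairs(lab[r, ], lab[r + 1L, ])
  for (cc in col_cuts) link_pairs(lab[, cc], lab[, cc + 1L])
  roots <- vapply(seq_len(k), find, integer(1L))
  if (all(roots == seq_len(k))) return(relabel_contiguous(lab))
  areas <- tabulate(lab[lab > 0L], nbins = k)
  keep <- logical(k)
  for (g in unique(roots)) {
    members <- which(roots == g)
    keep[members[which.max(areas[members])]] <- TRUE
  }
  idx <- which(lab > 0L)
  lab[idx[!keep[lab[idx]]]] <- 0L
  relabel_contiguous(lab)
}

relabel_contiguous <- function(lab) {
  if (!any(lab > 0L)) return(lab)
  ids <- sort(unique(lab[lab > 0L]))
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# --- binary morphology -------------------------------------------------------

disk_offsets <- function(radius) {
  if (radius <= 0) return(cbind(dr = 0L, dc = 0L))
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE])
}

shift_mat <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out & shift_mat(mask, -off[i, 1L], -off[i, 2L], FALSE)
  out
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | shift_mat(mask, off[i, 1L], off[i, 2L], FALSE)
  out
}

binary_open <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}
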