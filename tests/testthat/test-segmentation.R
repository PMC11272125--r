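test_that("rgb_to_lab matches the standard sRGB->XYZ->LAB chain", {
  black <- rgb_to_lab(flat_rgb(1, 1, c(0, 0, 0)))
  expect_equal(unname(black[1, 1, "L"]), 0)
  white <- rgb_to_lab(flat_rgb(1, 1, c(255, 255, 255)))
  expect_equal(unname(white[1, 1, "L"]), 100, tolerance = 1e-6)
  expect_lt(abs(white[1, 1, "a"]) + abs(white[1, 1, "b"]), 1e-3)

  # mid-gray, chained by hand: sRGB inverse gamma, BT.709 matrix, D65, f()
  v <- 128 / 255
  lin <- ((v + 0.055) / 1.055)^2.4
  Y <- lin * (0.2126729 + 0.7151522 + 0.0721750)
  fy <- if (Y > (6 / 29)^3) Y^(1 / 3) else Y / (3 * (6 / 29)^2) + 4 / 29
  L_hand <- 116 * fy - 16
  mid <- rgb_to_lab(flat_rgb(1, 1, c(128, 128, 128)))
  expect_equal(unname(mid[1, 1, "L"]), L_hand, tolerance = 1e-6)
  expect_lt(abs(mid[1, 1, "a"]), 1e-4)
})

test_that("nucleus grayscale inverts lightness and preserves contrast", {
  img <- flat_rgb(20, 20, c(230, 190, 200))
  img[5:10, 5:10, ] <- 40                    # dark square
  g <- to_nucleus_grayscale(img)
  expect_true(min(g[5:10, 5:10]) > max(g[-(5:10), -(5:10)]))
  expect_true(all(g >= 0 & g <= 1))
  # inverting the input lightness inverts the score ranking
  g_inv <- to_nucleus_grayscale(255 - img)
  expect_equal(rank(as.vector(g)), rank(-as.vector(g_inv)))
  expect_error(to_nucleus_grayscale(flat_rgb(4, 4, c(100, 100, 100))),
               "degenerate")
})

test_that("Otsu separates a two-valued image and honours the tie-break", {
  g <- matrix(c(rep(0.1, 40), rep(0.9, 60)), 10, 10)
  t_star <- otsu_threshold(g)
  expect_gt(t_star, 0.1)
  expect_lt(t_star, 0.9)
  expect_error(otsu_threshold(matrix(0.5, 3, 3)), "degenerate")
  # symmetric bimodal histogram: threshold at the centre
  g2 <- matrix(c(rep(0.25, 50), rep(0.75, 50)), 10, 10)
  expect_equal(otsu_threshold(g2, n_bins = 4), 0.5)
})

test_that("Otsu equals the exhaustive between-class variance scan", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(50:500, 1)
    g <- switch(sample(3, 1),
                runif(n),
                c(rnorm(n, 0.3, 0.05), rnorm(n, 0.7, 0.1)),
                rbeta(n, 0.5, 0.5))
    g <- pmin(pmax(g, 0), 1)
    if (length(unique(g)) < 2) next
    expect_equal(otsu_threshold(g |> matrix(ncol = 1)), oracle_otsu(g))
  }
})

test_that("opening removes speckle but keeps solid structures", {
  g <- matrix(0, 30, 30)
  g[15, 15] <- 1                             # isolated pixel
  m <- binarize_and_open(g, 0.5, seg_params(opening_radius_px = 1))
  expect_false(any(m))

  disk <- matrix(0, 30, 30)
  ctr <- 15.5
  for (r in 1:30) for (cc in 1:30)
    if ((r - ctr)^2 + (cc - ctr)^2 <= 100) disk[r, cc] <- 1
  before <- sum(disk > 0.5)
  m2 <- binarize_and_open(disk, 0.5, seg_params(opening_radius_px = 2))
  expect_gt(sum(m2), before * 0.85)          # area loss < 15%

  empty <- binarize_and_open(matrix(0, 5, 5), 0.5, seg_params())
  expect_false(any(empty))
})

test_that("watershed splits touching disks at the neck", {
  mk_disk <- function(m, cr, cc, rad) {
    for (r in seq_len(nrow(m))) for (col in seq_len(ncol(m)))
      if ((r - cr)^2 + (col - cc)^2 <= rad^2) m[r, col] <- TRUE
    m
  }
  m <- matrix(FALSE, 40, 60)
  m <- mk_disk(m, 20, 20, 8)
  lab1 <- watershed_split(m, params = seg_params())
  expect_equal(max(lab1), 1L)                # single convex blob

  m2 <- mk_disk(m, 20, 32, 8)                # centres 12 px apart
  lab2 <- watershed_split(m2, params = seg_params())
  expect_equal(max(lab2), 2L)
  # cut within 2 px of the midline between the centres (col 26)
  border <- which(lab2[, 24:28] > 0, arr.ind = TRUE)
  l_left <- unique(lab2[, 1:23][lab2[, 1:23] > 0])
  l_right <- unique(lab2[, 29:60][lab2[, 29:60] > 0])
  expect_length(l_left, 1L)
  expect_length(l_right, 1L)
  expect_false(l_left == l_right)

  expect_equal(max(watershed_split(matrix(FALSE, 5, 5),
                                   params = seg_params())), 0L)
  # labelled area never exceeds the mask area
  expect_lte(sum(lab2 > 0), sum(m2))
  expect_true(all(lab2[!m2] == 0L))
})

test_that("tiling partitions the image exactly", {
  img <- array(runif(1000 * 1000 * 3), dim = c(1000, 1000, 3))
  tl <- tile_image(img, c(10, 10))
  expect_length(tl$tiles, 100L)
  expect_true(all(vapply(tl$tiles, function(t) all(dim(t)[1:2] == 100),
                         logical(1L))))
  # odd size: floor division with the remainder on the last row/column
  img2 <- matrix(rnorm(1005 * 998), 1005, 998)
  tl2 <- tile_image(img2, c(10, 10))
  expect_equal(sum(tl2$offsets$rows * tl2$offsets$cols), 1005 * 998)
  expect_equal(max(tl2$offsets$rows), 1005 - 9 * 100)
  expect_equal(max(tl2$offsets$cols), 998 - 9 * 99)
  # reassembly is bit-exact
  rec <- matrix(0, 1005, 998)
  for (i in seq_along(tl2$tiles)) {
    o <- tl2$offsets[i, ]
    rec[o$row_off + seq_len(o$rows), o$col_off + seq_len(o$cols)] <-
      tl2$tiles[[i]]
  }
  expect_identical(rec, img2)
  expect_warning(tile_image(matrix(0, 5, 5), c(10, 10)), "single tile")
})

test_that("slide segmentation is deterministic and empty on blank slides", {
  sl <- generate_slide(slide_spec(width_px = 300, height_px = 300,
                                  n_nuclei = 25, seed = 4))
  l1 <- segment_slide(sl$image)
  l2 <- segment_slide(sl$image)
  expect_identical(l1, l2)
  expect_gt(max(l1), 0L)

  blank <- generate_slide(slide_spec(width_px = 200, height_px = 200,
                                     n_nuclei = 0, seed = 1))
  expect_equal(max(segment_slide(blank$image)), 0L)
})
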