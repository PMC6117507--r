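# Vegetation indices, mask thresholds, mixed-pixel erosion, treatment
# labelling and cube flattening.

make_index_cube <- function() {
  # bands at the default index wavelengths
  bands <- c(470, 550, 670, 800)
  vals <- array(0, dim = c(3, 3, 4))
  spectral_cube(vals, bands, state = "reflectance")
}

test_that("NDVI arithmetic, symmetry and the zero-denominator rule", {
  cube <- make_index_cube()
  cube$values[1, 1, ] <- c(0.1, 0.1, 0.05, 0.45)   # vegetation-like
  cube$values[2, 2, ] <- c(0.2, 0.2, 0.30, 0.30)   # red == nir
  ndvi <- ndvi_image(cube)
  expect_equal(ndvi[1, 1], 0.8)
  expect_equal(ndvi[2, 2], 0)
  expect_equal(ndvi[3, 3], 0)      # 0/0 maps to 0 by convention
  expect_error(ndvi_image(cube, nir_nm = 1500), "outside spectral range")
})

test_that("EGI arithmetic and the achromatic case", {
  cube <- make_index_cube()
  cube$values[1, 1, ] <- c(0.05, 0.20, 0.08, 0)
  cube$values[2, 2, ] <- c(0.13, 0.13, 0.13, 0)
  cube$values[3, 1, ] <- c(0.10, 0.00, 0.10, 0)
  egi <- egi_image(cube)
  expect_equal(egi[1, 1], 0.27)
  expect_equal(egi[2, 2], 0)
  expect_equal(egi[3, 1], -0.2)
})

test_that("primary mask is the conjunction and is monotone in thresholds", {
  set.seed(4)
  ndvi <- matrix(runif(100, -1, 1), 10)
  egi <- matrix(runif(100, -0.5, 0.5), 10)
  m <- primary_mask(ndvi, egi, 0.2, 0.1)
  expect_identical(m, (ndvi > 0.2) & (egi > 0.1))
  expect_true(all(primary_mask(ndvi, egi, -2, -2)))
  # raising either threshold never adds pixels
  for (dt in c(0.1, 0.3)) {
    expect_true(all(m >= primary_mask(ndvi, egi, 0.2 + dt, 0.1)))
    expect_true(all(m >= primary_mask(ndvi, egi, 0.2, 0.1 + dt)))
  }
  expect_error(primary_mask(ndvi, egi[1:5, ], 0, 0), "same shape")
})

test_that("erosion keeps a pixel only when all eight neighbours pass", {
  f <- matrix(FALSE, 9, 9)
  # 3x3 block -> only its center survives
  a <- f; a[4:6, 4:6] <- TRUE
  ea <- filter_mixed_pixels(a)
  expect_equal(which(ea), which(f | {z <- f; z[5, 5] <- TRUE; z}))
  # 5x5 block -> interior 3x3 survives
  b <- f; b[3:7, 3:7] <- TRUE
  eb <- filter_mixed_pixels(b)
  want <- f; want[4:6, 4:6] <- TRUE
  expect_identical(eb, want)
  # isolated pixel vanishes; border pixels always vanish
  c1 <- f; c1[5, 5] <- TRUE
  expect_false(any(filter_mixed_pixels(c1)))
  allon <- matrix(TRUE, 4, 4)
  er <- filter_mixed_pixels(allon)
  expect_identical(er, rbind(FALSE, cbind(FALSE, matrix(TRUE, 2, 2), FALSE), FALSE))
  # single pass only: output is a subset of the input
  expect_true(all(b[eb]))
})

test_that("erosion agrees with an independent morphological implementation", {
  set.seed(8)
  m <- matrix(runif(30 * 30) > 0.35, 30, 30)
  # interior comparison: EBImage does not contract at the image border, so
  # frame the mask with FALSE and compare the interior
  framed <- matrix(FALSE, 34, 34)
  framed[3:32, 3:32] <- m
  ours <- filter_mixed_pixels(framed)
  ref <- EBImage::erode(EBImage::Image(framed * 1), EBImage::makeBrush(3, "box"))
  expect_identical(ours[2:33, 2:33], (ref@.Data > 0)[2:33, 2:33])
})

test_that("single-pass erosion differs from a double pass", {
  f <- matrix(FALSE, 11, 11)
  f[3:9, 3:9] <- TRUE
  once <- filter_mixed_pixels(f)
  twice <- filter_mixed_pixels(once)
  expect_gt(sum(once), sum(twice))
})

test_that("treatment labelling splits, drops and rejects overlap", {
  m <- matrix(TRUE, 6, 10)
  lab <- assign_treatment(m, region(1, 6, 1, 4), region(1, 6, 7, 10))
  expect_equal(sum(lab == 1L), 6 * 4)
  expect_equal(sum(lab == 2L), 6 * 4)
  expect_equal(attr(lab, "dropped"), 6 * 2)  # columns 5:6 unassigned
  expect_error(assign_treatment(m, region(1, 6, 1, 5), region(1, 6, 5, 10)),
               "overlap")
})

test_that("flattening is a lossless, label-preserving round trip", {
  sc <- small_scene()
  reg <- sc$regions
  lab <- assign_treatment(sc$truth$label_map != "background",
                          reg$control, reg$salt)
  pm <- flatten_cube(sc$cube, lab)
  expect_equal(ncol(pm$X), sum(lab > 0))
  expect_equal(pm$n_c + pm$n_s, ncol(pm$X))
  # coords invert the flattening: every column matches its source spectrum
  for (j in sample(ncol(pm$X), 10)) {
    expect_identical(pm$X[, j],
                     sc$cube$values[pm$coords[j, 1], pm$coords[j, 2], ])
  }
  # scan order is row-major
  ord <- order(pm$coords[, 1], pm$coords[, 2])
  expect_identical(ord, seq_len(nrow(pm$coords)))
  # unflatten puts each value back at its pixel
  img <- unflatten(pm, seq_len(ncol(pm$X)))
  expect_equal(img[pm$coords], as.numeric(seq_len(ncol(pm$X))))
  expect_error(flatten_cube(sc$cube, matrix(0L, 40, 60)), "no labelled")
})

test_that("planted edge-mix pixels never reach the final mask", {
  sc <- small_scene(seed = 13)
  ndvi <- ndvi_image(sc$cube); egi <- egi_image(sc$cube)
  prim <- primary_mask(ndvi, egi)
  fin <- filter_mixed_pixels(prim)
  expect_false(any(fin[sc$truth$edge_map]))
  expect_true(all(prim[fin]))      # final is a subset of primary
})
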