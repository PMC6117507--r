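# Vegetation segmentation: spectral-index thresholding (step I) followed by
# morphological erosion to purge mixed edge pixels (step II), then treatment
# labelling and flattening of the cube into a labelled pixel matrix.

nearest_band <- function(cube, nm) {
  bc <- cube$band_centers
  if (nm < min(bc) || nm > max(bc))
    stop(sprintf("requested wavelength %.1f nm outside spectral range [%.1f, %.1f]",
                 nm, min(bc), max(bc)))
  which.min(abs(bc - nm))
}

#' Normalized difference vegetation index image
#'
#' NDVI = (NIR - Red) / (NIR + Red), computed on the reflectance bands nearest
#' to the requested wavelengths. Pixels with a zero denominator map to 0.
#'
#' @param cube a reflectance [spectral_cube()].
#' @param red_nm,nir_nm requested band centers (nm); the nearest kept band is
#'   used.
#' @return A numeric matrix of NDVI values.
#' @export
ndvi_image <- function(cube, red_nm = 670, nir_nm = 800) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state != "reflectance") stop("NDVI requires a reflectance cube")
  red <- cube$values[, , nearest_band(cube, red_nm)]
  nir <- cube$values[, , nearest_band(cube, nir_nm)]
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- 0
  out
}

#' Excess green index image
#'
#' EGI = 2 Green - Red - Blue on the reflectance bands nearest to the
#' requested wavelengths.
#'
#' @param cube a reflectance [spectral_cube()].
#' @param blue_nm,green_nm,red_nm requested band centers (nm).
#' @return A numeric matrix of EGI values.
#' @export
egi_image <- function(cube, blue_nm = 470, green_nm = 550, red_nm = 670) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state != "reflectance") stop("EGI requires a reflectance cube")
  b <- cube$values[, , nearest_band(cube, blue_nm)]
  g <- cube$values[, , nearest_band(cube, green_nm)]
  r <- cube$values[, , nearest_band(cube, red_nm)]
  2 * g - r - b
}

#' Primary vegetation mask
#'
#' Element-wise conjunction of the NDVI and EGI threshold masks.
#'
#' @param ndvi_img,egi_img index images of identical shape.
#' @param t_ndvi,t_egi strict lower thresholds.
#' @return A logical matrix.
#' @export
primary_mask <- function(ndvi_img, egi_img, t_ndvi = 0.5, t_egi = 0.05) {
  if (!identical(dim(ndvi_img), dim(egi_img)))
    stop("index images must have the same shape")
  (ndvi_img > t_ndvi) & (egi_img > t_egi)
}

#' Filter mixed pixels by binary erosion
#'
#' Erodes the mask with a 3 x 3 structuring element of ones: a pixel survives
#' only if it and all eight neighbours are TRUE. Out-of-bounds neighbours
#' count as FALSE, so image-border pixels are always removed. Pixels at
#' leaf/background boundaries carry mixed spectra; a single erosion pass
#' removes exactly the 1-pixel rim of each connected vegetation object.
#'
#' @param mask a logical matrix.
#' @return The eroded logical matrix.
#' @export
filter_mixed_pixels <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(TRUE, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out & pad[(1:nr) + dr, (1:nc) + dc]
  out
}

#' Assign treatment labels to masked pixels
#'
#' Masked pixels inside `control_region` are labelled control, those inside
#' `salt_region` salt. Masked pixels in neither region are dropped and
#' counted.
#'
#' @param mask a logical matrix (typically the eroded final mask).
#' @param control_region,salt_region disjoint [region()]s.
#' @return An integer matrix (0 background, 1 control, 2 salt) with attribute
#'   `dropped` giving the number of masked pixels outside both regions.
#' @export
assign_treatment <- function(mask, control_region, salt_region) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  cr <- as_region(control_region, dim(mask))
  sr <- as_region(salt_region, dim(mask))
  if (regions_overlap(cr, sr)) stop("control and salt regions overlap")
  idx <- which(mask, arr.ind = TRUE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  inc <- in_region(idx[, 1], idx[, 2], cr)
  ins <- in_region(idx[, 1], idx[, 2], sr)
  lab[idx[inc, , drop = FALSE]] <- 1L
  lab[idx[ins, , drop = FALSE]] <- 2L
  attr(lab, "dropped") <- sum(!inc & !ins)
  lab
}

#' Flatten a masked cube to a labelled pixel matrix
#'
#' Converts the labelled vegetation pixels of a cube to a d x n matrix `X`
#' whose rows are spectral bands and whose columns are pixels, in row-major
#' scan order (row by row, left to right). The stored coordinates invert the
#' flattening exactly.
#'
#' @param cube a [spectral_cube()].
#' @param labeled_mask integer matrix from [assign_treatment()].
#' @return An object of class `pixel_matrix`: list with `X` (d x n matrix),
#'   `labels` (factor with levels control/salt), `coords` (n x 2 matrix of
#'   row, col), `band_centers`, `shape`, and class counts `n_c`, `n_s`.
#' @export
flatten_cube <- function(cube, labeled_mask) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  if (!identical(dim(labeled_mask), d[1:2]))
    stop("cube and mask must have the same spatial shape")
  idx <- which(labeled_mask > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask selects no labelled pixel")
  # row-major scan: order by row, then column
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  lin <- idx[, 1] + (idx[, 2] - 1L) * d[1]
  X <- t(flat[lin, , drop = FALSE])
  labels <- factor(ifelse(labeled_mask[idx] == 1L, "control", "salt"),
                   levels = c("control", "salt"))
  dimnames(idx) <- list(NULL, c("row", "col"))
  structure(list(X = X, labels = labels, coords = idx,
                 band_centers = cube$band_centers, shape = d[1:2],
                 n_c = sum(labels == "control"), n_s = sum(labels == "salt")),
            class = "pixel_matrix")
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf("<pixel_matrix> %d bands x %d pixels (%d control, %d salt)\n",
              nrow(x$X), ncol(x$X), x$n_c, x$n_s))
  invisible(x)
}

#' Scatter per-pixel values back onto the image grid
#'
#' @param pm a `pixel_matrix`.
#' @param values per-column values (defaults to 1 for a mask image).
#' @param fill background fill value.
#' @return A matrix of shape `pm$shape`.
#' @export
unflatten <- function(pm, values = rep(1, ncol(pm$X)), fill = 0) {
  stopifnot(inherits(pm, "pixel_matrix"))
  if (length(values) != nrow(pm$coords)) stop("one value per pixel required")
  out <- matrix(fill, pm$shape[1], pm$shape[2])
  out[pm$coords] <- values
  out
}
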