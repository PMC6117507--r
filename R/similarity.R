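# Vector-wise similarity measurement (VSM): every pixel spectrum is projected
# onto the axis through the two endmembers and the normalized position along
# that axis, clamped to [0, 1], is its similarity to the salt endmember. The
# clamp makes the similarity to control and to salt sum to one for every
# pixel and reproduces the box-constrained quadratic-unmixing solution, which
# serves as the slow per-pixel oracle.

#' Vector-wise similarity to the salt endmember
#'
#' For each pixel spectrum r, the signed projection coordinate
#' t = <r - w1, w2 - w1> / ||w2 - w1||^2 is clamped to `[0, 1]`. t = 0 at the
#' control endmember, 1 at the salt endmember. The whole field is computed as
#' one matrix product; cost is linear in pixels x bands.
#'
#' @param pm a `pixel_matrix` (or bare d x n matrix).
#' @param pair an `endmember_pair`.
#' @return An object of class `similarity_field`: `s` (per-pixel similarity in
#'   `[0, 1]`), plus `labels`, `coords` and `shape` inherited from `pm` when
#'   available.
#' @export
vsm <- function(pm, pair) {
  stopifnot(inherits(pair, "endmember_pair"))
  if (pair$separation <= 0) stop("endmember separation must be positive")
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  L <- pair$w2 - pair$w1
  t_raw <- as.vector(crossprod(L, X) - sum(L * pair$w1)) / sum(L * L)
  s <- pmin(pmax(t_raw, 0), 1)
  structure(list(s = s,
                 labels = if (inherits(pm, "pixel_matrix")) pm$labels else NULL,
                 coords = if (inherits(pm, "pixel_matrix")) pm$coords else NULL,
                 shape = if (inherits(pm, "pixel_matrix")) pm$shape else NULL),
            class = "similarity_field")
}

#' @export
print.similarity_field <- function(x, ...) {
  cat(sprintf("<similarity_field> %d pixels, s in [%.3f, %.3f], mean %.3f\n",
              length(x$s), min(x$s), max(x$s), mean(x$s)))
  invisible(x)
}

#' Constrained quadratic unmixing of pixels onto the endmember pair
#'
#' Solves, for every pixel x_j, the two-endmember abundance problem
#' min ||x_j - W h||^2 subject to h >= 0, h <= 1, sum(h) = 1, where
#' W = (w1, w2). With the sum constraint the problem is one-dimensional in
#' the salt abundance t, and each column is minimised numerically over
#' `[0, 1]` by golden-section/parabolic search ([stats::optimize()],
#' tolerance 1e-10). This per-pixel solver loop is the reference method;
#' [vsm()] must agree with it to within 1e-6 and is the fast path.
#'
#' @param pm a `pixel_matrix` or d x n matrix.
#' @param pair an `endmember_pair`.
#' @return A 2 x n matrix of abundances; rows `control`, `salt`.
#' @export
qp_unmix <- function(pm, pair) {
  stopifnot(inherits(pair, "endmember_pair"))
  if (pair$separation <= 0) stop("endmember separation must be positive")
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  w1 <- pair$w1; w2 <- pair$w2
  t_hat <- vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    obj <- function(t) sum((x - (1 - t) * w1 - t * w2)^2)
    # compare the interior search against both box corners
    opt <- stats::optimize(obj, interval = c(0, 1), tol = 1e-10)
    cand_t <- c(opt$minimum, 0, 1)
    cand_f <- c(opt$objective, obj(0), obj(1))
    cand_t[which.min(cand_f)]
  }, numeric(1))
  rbind(control = 1 - t_hat, salt = t_hat)
}

#' Render a similarity field as a 2-D image
#'
#' Masked pixels carry their similarity value; background pixels are exactly
#' 0. A pixel whose similarity is exactly 0 is distinguished from background
#' by the mask coordinates, not by the grid.
#'
#' @param field a `similarity_field` with coordinates.
#' @param shape optional c(rows, cols); defaults to the field's shape.
#' @return A numeric matrix.
#' @export
similarity_image <- function(field, shape = field$shape) {
  stopifnot(inherits(field, "similarity_field"))
  if (is.null(field$coords)) stop("field carries no coordinates")
  if (is.null(shape)) stop("image shape unknown")
  if (any(field$coords[, 1] > shape[1]) || any(field$coords[, 2] > shape[2]))
    stop("coordinates outside image shape")
  lin <- field$coords[, 1] + (field$coords[, 2] - 1) * shape[1]
  if (anyDuplicated(lin)) stop("coordinate collision in similarity field")
  img <- matrix(0, shape[1], shape[2])
  img[field$coords] <- field$s
  img
}

#' Write a similarity image as an 8-bit grayscale PNG
#'
#' Similarity is scaled by 255 and rounded. Requires the png package.
#'
#' @param field a `similarity_field`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_png <- function(field, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG output")
  img <- similarity_image(field)
  png::writePNG(round(img * 255) / 255, path)
  invisible(path)
}

#' Export a similarity field as a per-pixel data frame
#'
#' @param field a `similarity_field`.
#' @return A data frame with columns `row`, `col`, `label`, `s`.
#' @export
similarity_table <- function(field) {
  stopifnot(inherits(field, "similarity_field"))
  data.frame(row = field$coords[, 1], col = field$coords[, 2],
             label = field$labels, s = field$s)
}
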