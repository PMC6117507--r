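#' Rectangular image region
#'
#' Regions use the R convention: 1-based, inclusive row and column bounds.
#'
#' @param row_min,row_max,col_min,col_max inclusive pixel bounds.
#' @return An integer vector of class `region`:
#'   `(row_min, row_max, col_min, col_max)`.
#' @export
region <- function(row_min, row_max, col_min, col_max) {
  r <- as.integer(c(row_min, row_max, col_min, col_max))
  if (any(is.na(r)) || r[1] < 1 || r[3] < 1 || r[2] < r[1] || r[4] < r[3])
    stop("invalid region bounds")
  structure(r, class = "region")
}

as_region <- function(x, shape = NULL) {
  if (!inherits(x, "region")) {
    if (length(x) != 4) stop("a region needs 4 bounds")
    x <- region(x[1], x[2], x[3], x[4])
  }
  if (!is.null(shape) && (x[2] > shape[1] || x[4] > shape[2]))
    stop("region exceeds image bounds")
  x
}

regions_overlap <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

in_region <- function(rows, cols, r) {
  r <- as_region(r)
  rows >= r[1] & rows <= r[2] & cols >= r[3] & cols <= r[4]
}
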