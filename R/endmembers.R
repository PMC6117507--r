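# Two-endmember extraction. With exactly two classes the maximum-volume
# simplex spanned by pure pixels degenerates to the 1-simplex between the two
# most separated pixels in spectral feature space, so the search reduces to
# the farthest pair of columns of X.

pairwise_sq_dists <- function(X) {
  # columns of X; returns n x n matrix of squared Euclidean distances
  n2 <- colSums(X^2)
  G <- crossprod(X)
  D <- outer(n2, n2, "+") - 2 * G
  D[D < 0] <- 0
  D
}

farthest_pair_exact <- function(X) {
  D <- pairwise_sq_dists(X)
  D[lower.tri(D, diag = TRUE)] <- -Inf
  m <- max(D)
  hits <- which(D == m, arr.ind = TRUE)
  # deterministic tie-break: lexicographically smallest (i, j)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  unname(c(hits[1, 1], hits[1, 2]))
}

# Alternating maximization refines a start pixel: move each end to the pixel
# farthest from the other until a fixed point. A single start can stall in a
# local optimum, so the search restarts from the pixel farthest from the
# centroid and from the extremes along the leading principal directions.
farthest_pair_iterative <- function(X) {
  n <- ncol(X)
  n2 <- colSums(X^2)
  sq_to_all <- function(v) n2 + sum(v^2) - 2 * as.vector(crossprod(v, X))
  centroid <- rowMeans(X)
  # the alternation is exact whenever one endpoint of the optimal pair is a
  # start, so seed it generously: the pixels most distant from the centroid
  # plus the extremes along the leading principal directions
  r2 <- n2 + sum(centroid^2) - 2 * as.vector(crossprod(centroid, X))
  m <- min(n, 200L)
  starts <- order(r2, decreasing = TRUE)[seq_len(m)]
  k <- min(8L, nrow(X), n - 1L)
  if (k >= 1) {
    Xc <- X - centroid
    u <- tryCatch(svd(Xc, nu = k, nv = 0)$u, error = function(e) NULL)
    if (!is.null(u)) {
      proj <- crossprod(u, Xc)                    # k x n
      starts <- c(starts,
                  apply(proj, 1, which.max), apply(proj, 1, which.min))
    }
  }
  starts <- unique(starts)
  # one batched half-step: the farthest pixel from every start at once
  G <- crossprod(X[, starts, drop = FALSE], X)    # |starts| x n
  D0 <- sweep(-2 * G, 2, n2, "+")                 # + n2[s] is constant per row
  first_b <- apply(D0, 1, which.max)
  seeds <- unique(t(apply(cbind(starts, first_b), 1, sort)))
  best <- NULL; best_d <- -1
  for (q in seq_len(nrow(seeds))) {
    a <- seeds[q, 1]; b <- seeds[q, 2]
    for (it in seq_len(n)) {
      a2 <- which.max(sq_to_all(X[, b]))
      b2 <- which.max(sq_to_all(X[, a2]))
      if ((a2 == a && b2 == b) || (a2 == b && b2 == a)) { a <- a2; b <- b2; break }
      a <- a2; b <- b2
    }
    d <- sum((X[, a] - X[, b])^2)
    if (d > best_d) { best_d <- d; best <- sort(c(a, b)) }
  }
  best
}

#' Extract the control and salt endmembers
#'
#' Finds the two most spectrally extreme pixels, the vertices of the
#' maximum-length 1-simplex in feature space. `method = "exact"` performs the
#' full O(n^2) pairwise search; `method = "farthest_point"` iterates the
#' alternating farthest-point heuristic from the pixel farthest from the
#' centroid until a fixed point. The endmember whose column carries the
#' control label is oriented as `w1`; if both carry the same label, `w1` is
#' the one nearer the control-class centroid.
#'
#' @param pm a `pixel_matrix` (or a bare d x n matrix, in which case
#'   orientation by label is skipped).
#' @param method `"farthest_point"` (default) or `"exact"`.
#' @return An object of class `endmember_pair`: `w1`, `w2`, source column
#'   indices `idx1`, `idx2`, and the Euclidean `separation`.
#' @export
extract_endmembers <- function(pm, method = c("farthest_point", "exact")) {
  method <- match.arg(method)
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  if (ncol(X) < 2) stop("need at least two pixels")
  pair <- switch(method,
                 exact = farthest_pair_exact(X),
                 farthest_point = farthest_pair_iterative(X))
  i <- pair[1]; j <- pair[2]
  sep <- sqrt(sum((X[, i] - X[, j])^2))
  if (sep == 0) stop("all pixels identical: endmember separation is zero")
  labels <- if (inherits(pm, "pixel_matrix")) pm$labels else NULL
  if (!is.null(labels)) {
    li <- as.character(labels[i]); lj <- as.character(labels[j])
    if (li == "salt" && lj == "control") {
      tmp <- i; i <- j; j <- tmp
    } else if (li == lj) {
      cc <- rowMeans(X[, labels == "control", drop = FALSE])
      if (sum((X[, j] - cc)^2) < sum((X[, i] - cc)^2)) {
        tmp <- i; i <- j; j <- tmp
      }
    }
  }
  structure(list(w1 = X[, i], w2 = X[, j], idx1 = i, idx2 = j,
                 separation = sep,
                 band_centers = if (inherits(pm, "pixel_matrix")) pm$band_centers else NULL),
            class = "endmember_pair")
}

#' @export
print.endmember_pair <- function(x, ...) {
  cat(sprintf("<endmember_pair> d = %d, columns %d (control, w1) / %d (salt, w2), separation %.4g\n",
              length(x$w1), x$idx1, x$idx2, x$separation))
  invisible(x)
}

#' Export endmember spectra as a data frame
#'
#' @param pair an `endmember_pair`.
#' @return A data frame with columns `wavelength_nm`, `control`, `salt`.
#' @export
endmember_table <- function(pair) {
  stopifnot(inherits(pair, "endmember_pair"))
  wl <- pair$band_centers
  if (is.null(wl)) wl <- seq_along(pair$w1)
  data.frame(wavelength_nm = wl, control = pair$w1, salt = pair$w2)
}

#' Project pixels onto the first three principal components
#'
#' Mean-centered projection used for visual inspection of the pixel cloud and
#' the endmember locations (reporting only).
#'
#' @param pm a `pixel_matrix` or d x n matrix.
#' @return An n x 3 matrix of scores; rank-deficient data yield zero columns.
#' @export
project_pca3 <- function(pm) {
  X <- if (inherits(pm, "pixel_matrix")) pm$X else as.matrix(pm)
  if (ncol(X) < 3) stop("need at least three pixels")
  p <- stats::prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(p$x))
  out <- matrix(0, ncol(X), 3L)
  out[, seq_len(k)] <- p$x[, seq_len(k)]
  colnames(out) <- c("PC1", "PC2", "PC3")
  out
}
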