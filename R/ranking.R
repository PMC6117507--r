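# The three ranking statistics. All compare the salt-treatment pixels of one
# line against that line's own control pixels, so inherent differences
# between lines (leaf colour, waxiness) cancel out:
#   - NRD-AUC: per-band relative drop of the salt class mean, integrated over
#     photon energy;
#   - MDPA: ordinal (earth-mover) histogram distance between the similarity
#     distributions of the balanced classes;
#   - Bayesian posterior of the salt class given similarity above a split.

#' Normalized reflectance difference curve
#'
#' Per band i: (mean control reflectance - mean salt reflectance) / mean
#' control reflectance. Bands where the control mean is zero are flagged NA
#' and excluded from the area computation.
#'
#' @param C,S d x n matrices of control and salt pixel spectra.
#' @param band_centers wavelengths (nm), length d.
#' @return An object of class `nrd_curve` with fields `nrd` and
#'   `band_centers`.
#' @export
nrd_curve <- function(C, S, band_centers) {
  C <- as.matrix(C); S <- as.matrix(S)
  if (ncol(C) == 0 || ncol(S) == 0) stop("both classes must be nonempty")
  if (nrow(C) != nrow(S) || nrow(C) != length(band_centers))
    stop("C, S and band_centers must agree on the number of bands")
  mc <- rowMeans(C); ms <- rowMeans(S)
  nrd <- (mc - ms) / mc
  nrd[mc == 0] <- NA_real_
  structure(list(nrd = nrd, band_centers = as.numeric(band_centers)),
            class = "nrd_curve")
}

# Planck: photon energy E = h c / lambda
planck_h <- 6.62607015e-34   # J s
speed_c  <- 2.99792458e8     # m / s

#' Area under the NRD curve on the energy axis
#'
#' Band-center wavelengths are converted to photon energies E = h c / lambda
#' (lambda in meters) and the curve is integrated by the trapezoid rule over
#' successive bands taken in wavelength order, using absolute energy
#' increments. NA (undefined) bands are excluded.
#'
#' @param curve an `nrd_curve`.
#' @return Area under the curve, in joules.
#' @export
auc_energy <- function(curve) {
  stopifnot(inherits(curve, "nrd_curve"))
  ok <- !is.na(curve$nrd)
  y <- curve$nrd[ok]
  lam <- curve$band_centers[ok]
  if (length(y) < 2) stop("need at least two defined bands")
  ord <- order(lam)
  y <- y[ord]; lam <- lam[ord]
  x <- planck_h * speed_c / (lam * 1e-9)
  sum(0.5 * (y[-1] + y[-length(y)]) * abs(diff(x)))
}

# bin index on [0,1]: half-open bins [k/b, (k+1)/b), last bin closed at 1
bin_index <- function(s, b) {
  if (any(s < 0 | s > 1)) stop("similarity values must lie in [0, 1]")
  pmin(floor(s * b), b - 1L) + 1L
}

#' Class similarity histograms
#'
#' Bins the similarity values of each class into `b` ordinal bins tiling
#' `[0, 1]`: bins are half-open except the last, which is closed at 1 so that
#' the salt endmember itself (s = 1) is in range. Means and standard
#' deviations are computed from the raw similarity values, not bin centers.
#'
#' @param field a `similarity_field` with class labels.
#' @param b number of bins (default 100, bin width 0.01).
#' @return A list with `control` and `salt` elements of class
#'   `class_histogram` (fields `counts`, `b`, `n`, `mean`, `sd`, `values`).
#' @export
class_histograms <- function(field, b = 100) {
  stopifnot(inherits(field, "similarity_field"))
  if (b < 2) stop("need at least two bins")
  if (is.null(field$labels)) stop("field carries no class labels")
  mk <- function(v) {
    if (length(v) == 0) stop("empty class")
    structure(list(counts = tabulate(bin_index(v, b), nbins = b),
                   b = as.integer(b), n = length(v),
                   mean = mean(v), sd = stats::sd(v), values = v),
              class = "class_histogram")
  }
  list(control = mk(field$s[field$labels == "control"]),
       salt = mk(field$s[field$labels == "salt"]))
}

#' @export
print.class_histogram <- function(x, ...) {
  cat(sprintf("<class_histogram> %d values in %d bins, mean %.3f, sd %.3f\n",
              x$n, x$b, x$mean, x$sd))
  invisible(x)
}

#' Stratified subsample of the larger class
#'
#' Draws a balanced sample from a class histogram: each bin contributes
#' round(bin count x target_n / n) members (computed by floor plus a
#' deterministic largest-remainder top-up so the total is exactly
#' `target_n`), selected uniformly at random within the bin. Stratifying by
#' bin preserves the shape of the similarity distribution, which both the
#' MDPA distance and the equal-prior Bayes computation require.
#'
#' @param h a `class_histogram` (with member values).
#' @param target_n number of members to keep, at most `h$n`.
#' @param seed RNG seed for the within-bin selection.
#' @return A `class_histogram` of exactly `target_n` members.
#' @export
stratified_subsample <- function(h, target_n, seed = 1L) {
  stopifnot(inherits(h, "class_histogram"))
  if (target_n <= 0) stop("target_n must be positive")
  if (target_n > h$n) stop("target_n exceeds class size")
  exact <- h$counts * target_n / h$n
  take <- floor(exact)
  deficit <- target_n - sum(take)
  if (deficit > 0) {
    rem <- exact - take
    # largest remainders first; ties broken by lower bin index
    ord <- order(-rem, seq_along(rem))
    top <- ord[seq_len(deficit)]
    take[top] <- take[top] + 1L
  }
  idx_by_bin <- split(seq_len(h$n), factor(bin_index(h$values, h$b),
                                           levels = seq_len(h$b)))
  sel <- local_seed(seed, {
    unlist(lapply(seq_len(h$b), function(k) {
      members <- idx_by_bin[[k]]
      if (take[k] == 0L) return(integer(0))
      if (take[k] >= length(members)) return(members)
      sample(members, take[k])
    }), use.names = FALSE)
  })
  v <- h$values[sort(sel)]
  structure(list(counts = tabulate(bin_index(v, h$b), nbins = h$b),
                 b = h$b, n = length(v), mean = mean(v), sd = stats::sd(v),
                 values = v),
            class = "class_histogram")
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Minimum difference of pair assignments (MDPA) histogram distance
#'
#' The ordinal histogram distance of Cha and Srihari: the sum over bins of
#' absolute prefix-sum differences, equal to the minimal number of one-bin
#' sample moves that turns one histogram into the other (the 1-D earth-mover
#' distance on bin indices). Requires equal bin counts and equal totals;
#' subsample the larger class first. The raw distance is divided by the
#' per-class pixel count, giving bin-index units per pixel.
#'
#' @param hc,hs `class_histogram`s (or bare count vectors) with equal totals.
#' @return Normalized MDPA distance (>= 0).
#' @export
mdpa <- function(hc, hs) {
  cc <- if (inherits(hc, "class_histogram")) hc$counts else as.numeric(hc)
  cs <- if (inherits(hs, "class_histogram")) hs$counts else as.numeric(hs)
  if (length(cc) != length(cs)) stop("histograms must have equal bin counts")
  if (sum(cc) != sum(cs))
    stop("histograms must have equal totals; subsample the larger class first")
  if (sum(cc) == 0) stop("histograms are empty")
  sum(abs(cumsum(cc - cs))) / sum(cc)
}

#' Bayes-rule components for the salt class at a similarity split
#'
#' Discretizes similarity at `split` (strict inequality `s > split`) and
#' computes the class-conditional probabilities, the evidence and the
#' posterior P(salt | s > split) by Bayes' rule. Classes must be balanced
#' (equal priors); enforce balance by stratified subsampling first.
#'
#' @param field a `similarity_field` with balanced classes, or `NULL` when
#'   `cc_salt` and one of `evidence`/`cc_control` are given directly.
#' @param split similarity split point, default 0.5.
#' @param cc_salt,cc_control,evidence optional probabilities (fractions)
#'   bypassing the field: P(s>split|salt), P(s>split|control), P(s>split).
#'   With equal priors, `cc_control = 2 * evidence - cc_salt`.
#' @param prior prior P(salt), default 0.5.
#' @return An object of class `bayes_table`: `prior`, `cc_salt`,
#'   `cc_control`, `evidence`, `posterior` (all fractions), and `undefined`
#'   flag (TRUE when no pixel exceeds the split).
#' @export
bayes_table <- function(field = NULL, split = 0.5, cc_salt = NULL,
                        cc_control = NULL, evidence = NULL, prior = 0.5) {
  if (!is.null(field)) {
    stopifnot(inherits(field, "similarity_field"))
    if (split <= 0 || split >= 1) stop("split must lie in (0, 1)")
    sc <- field$s[field$labels == "control"]
    ss <- field$s[field$labels == "salt"]
    if (length(sc) == 0 || length(ss) == 0) stop("empty class")
    if (length(sc) != length(ss))
      stop("classes must be balanced (equal priors); subsample first")
    cc_salt <- mean(ss > split)
    cc_control <- mean(sc > split)
  } else {
    if (is.null(cc_salt)) stop("supply a field or cc_salt")
    if (is.null(cc_control)) {
      if (is.null(evidence)) stop("supply cc_control or evidence")
      cc_control <- (evidence - prior * cc_salt) / (1 - prior)
    }
  }
  evidence <- prior * cc_salt + (1 - prior) * cc_control
  undefined <- (cc_salt + cc_control) == 0
  posterior <- if (undefined) NA_real_ else prior * cc_salt / evidence
  structure(list(prior = prior, cc_salt = cc_salt, cc_control = cc_control,
                 evidence = evidence, posterior = posterior, split = split,
                 undefined = undefined),
            class = "bayes_table")
}

#' @export
print.bayes_table <- function(x, digits = 2, ...) {
  pc <- function(v) sprintf(paste0("%.", digits, "f"), 100 * v)
  cat(sprintf("P(salt) = %s%%  P(s>%.2g|salt) = %s%%  P(s>%.2g) = %s%%  P(salt|s>%.2g) = %s%%\n",
              pc(x$prior), x$split, pc(x$cc_salt), x$split, pc(x$evidence),
              x$split, if (x$undefined) "undefined" else pc(x$posterior)))
  invisible(x)
}

#' Posterior probability of the salt class per similarity bin
#'
#' Discretizes similarity into `nbins` ordinal bins and computes, for each
#' bin, P(salt | s in bin) = salt count / total count in the bin. Empty bins
#' are flagged NA. The control curve is the complement.
#'
#' @param field a `similarity_field` with balanced classes.
#' @param nbins number of similarity bins, default 10.
#' @return A data frame with columns `bin`, `lower`, `upper`, `n`,
#'   `posterior_salt`, `posterior_control`.
#' @export
binned_posterior <- function(field, nbins = 10) {
  stopifnot(inherits(field, "similarity_field"))
  if (nbins < 2) stop("need at least two bins")
  idx <- bin_index(field$s, nbins)
  n_salt <- tabulate(idx[field$labels == "salt"], nbins = nbins)
  n_all <- tabulate(idx, nbins = nbins)
  post <- ifelse(n_all > 0, n_salt / n_all, NA_real_)
  data.frame(bin = seq_len(nbins),
             lower = (seq_len(nbins) - 1) / nbins,
             upper = seq_len(nbins) / nbins,
             n = n_all,
             posterior_salt = post,
             posterior_control = 1 - post)
}

#' Rank lines by a tolerance statistic
#'
#' Orders lines by ascending statistic: a smaller AUC, MDPA or posterior all
#' mean a smaller spectral response to the salt treatment, i.e. a more
#' tolerant line. Ties are broken by line-name order and flagged.
#'
#' @param statistics named numeric vector, one value per line.
#' @return A data frame with columns `line`, `value`, `rank` (1 = most
#'   tolerant), `tied`.
#' @export
rank_lines <- function(statistics) {
  if (length(statistics) < 2) stop("ranking needs at least two lines")
  if (is.null(names(statistics)) || any(!nzchar(names(statistics))))
    stop("statistics must be named by line")
  ord <- order(statistics, names(statistics))
  v <- statistics[ord]
  tied <- duplicated(v) | duplicated(v, fromLast = TRUE)
  data.frame(line = names(v), value = as.numeric(v),
             rank = seq_along(v), tied = tied, row.names = NULL)
}
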