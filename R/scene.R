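# Synthetic hyperspectral scenes with known ground truth. A scene holds two
# rectangular vegetation blobs (control tank on the left, salt tank on the
# right) on a near-achromatic background. Every vegetation pixel is a convex
# mixture of two vegetation-like endmember spectra:
#     pixel = illum * ((1 - a) * w_control + a * w_salt) + noise
# where the salt abundance a follows a Beta distribution whose mean is
# `base_abundance` for control pixels and `base_abundance + shift` for salt
# pixels. A log-normal unit-median illumination factor is a crude surrogate
# for leaf-angle effects; additive Gaussian noise models the sensor. One pure
# pixel per class (a = 0 / a = 1, illumination 1) is planted so endmember
# recovery is verifiable, and a 1-pixel 50/50 vegetation/background rim is
# planted around each blob to exercise the mixed-pixel filter.

#' Construct a vegetation-like endmember pair
#'
#' Builds two smooth reflectance spectra on the given band grid: low blue and
#' red reflectance, a green bump near 550 nm, a red edge near 700 nm and a
#' high NIR plateau. The salt spectrum is a deterministic, seed-reproducible
#' perturbation of the control spectrum, chiefly a depressed NIR plateau with
#' small smooth seeded variation, mirroring the broad reflectance drop of
#' salt-stressed tissue.
#'
#' @param band_centers wavelengths in nm, strictly increasing, at least 10
#'   bands.
#' @param seed integer seed for the perturbation.
#' @return A list with `w_control` and `w_salt`, both in `[0, 1]`.
#' @export
make_vegetation_spectra <- function(band_centers, seed = 1L) {
  band_centers <- as.numeric(band_centers)
  if (length(band_centers) < 10) stop("need at least 10 bands")
  if (any(diff(band_centers) <= 0)) stop("band_centers must be strictly increasing")
  lam <- band_centers
  w_control <- 0.05 +
    0.10 * exp(-((lam - 550) / 40)^2) +          # green bump
    0.55 / (1 + exp(-(lam - 710) / 12))          # red edge -> NIR plateau
  w_control <- pmin(pmax(w_control, 0), 1)
  pert <- local_seed(as.integer(seed), {
    # smooth seeded modulation of the NIR depression depth
    amp <- stats::runif(1, 0.12, 0.18)
    wig <- stats::runif(3, -0.02, 0.02)
    amp + wig[1] * sin(2 * pi * (lam - 400) / 500) +
      wig[2] * cos(2 * pi * (lam - 400) / 250) + wig[3] * (lam - 650) / 500
  })
  nir_weight <- 1 / (1 + exp(-(lam - 710) / 12))
  w_salt <- w_control * (1 - pert * nir_weight) -
    0.01 * exp(-((lam - 550) / 40)^2)
  w_salt <- pmin(pmax(w_salt, 0), 1)
  if (sqrt(sum((w_control - w_salt)^2)) <= 0)
    stop("degenerate endmember pair")
  list(w_control = w_control, w_salt = w_salt)
}

#' Scene specification
#'
#' Collects all parameters of the synthetic scene generator. Defaults define
#' the package's standard validation conditions: a 160 x 160 pixel scene, 51
#' bands over 400-900 nm, two 128 x 58 vegetation blobs (about 14,000
#' vegetation pixels per scene), mean salt abundance 0.40 for control pixels
#' raised by `shift` for salt pixels, Beta concentration 40, 1% multiplicative
#' illumination variation, additive noise sd 0.003 and a 1-pixel edge-mix
#' rim.
#'
#' @param n_rows,n_cols scene size in pixels.
#' @param band_centers wavelengths (nm), strictly increasing.
#' @param w_control,w_salt endmember reflectance spectra in `[0, 1]`; default
#'   from [make_vegetation_spectra()].
#' @param shift mean salt-abundance increase for salt-treatment pixels, in
#'   `[0, 1]`.
#' @param base_abundance mean salt abundance of control pixels.
#' @param concentration Beta concentration (shape1 + shape2) of the abundance
#'   distribution.
#' @param illum_sd sd of log illumination (log-normal, unit median).
#' @param noise_sd additive sensor noise sd (reflectance units).
#' @param background_spectrum background reflectance per band; default a
#'   near-achromatic ~0.10 ramp.
#' @param edge_mix_width width in pixels of the 50/50 vegetation/background
#'   rim planted at blob borders (0 or 1).
#' @param seed integer RNG seed governing all draws.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 160, n_cols = 160,
                       band_centers = seq(400, 900, length.out = 51),
                       w_control = NULL, w_salt = NULL,
                       shift = 0.1, base_abundance = 0.4, concentration = 40,
                       illum_sd = 0.01, noise_sd = 0.003,
                       background_spectrum = NULL,
                       edge_mix_width = 1, seed = 1L) {
  band_centers <- as.numeric(band_centers)
  if (any(diff(band_centers) <= 0)) stop("band_centers must be strictly increasing")
  if (is.null(w_control) || is.null(w_salt)) {
    sp <- make_vegetation_spectra(band_centers, seed = seed)
    if (is.null(w_control)) w_control <- sp$w_control
    if (is.null(w_salt)) w_salt <- sp$w_salt
  }
  if (is.null(background_spectrum))
    background_spectrum <- 0.09 + 5e-5 * (band_centers - 400)
  nb <- length(band_centers)
  if (length(w_control) != nb || length(w_salt) != nb ||
      length(background_spectrum) != nb)
    stop("all spectra must have one value per band")
  if (any(w_control < 0 | w_control > 1) || any(w_salt < 0 | w_salt > 1))
    stop("endmember spectra must lie in [0, 1]")
  if (shift < 0 || shift > 1) stop("shift must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (illum_sd < 0) stop("illum_sd must be >= 0")
  if (base_abundance + shift > 1)
    stop("base_abundance + shift pushes the mean salt abundance above 1")
  if (!edge_mix_width %in% c(0, 1)) stop("edge_mix_width must be 0 or 1")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 band_centers = band_centers,
                 w_control = w_control, w_salt = w_salt,
                 shift = shift, base_abundance = base_abundance,
                 concentration = concentration,
                 illum_sd = illum_sd, noise_sd = noise_sd,
                 background_spectrum = background_spectrum,
                 edge_mix_width = as.integer(edge_mix_width),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# blob layout: two tall rectangles, left = control, right = salt, inset from
# the borders so a background frame and the treatment-region split both exist
scene_layout <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  rh <- max(3L, round(0.8 * nr)); bw <- max(3L, round(0.36 * nc / 1))
  bw <- min(bw, floor(nc / 2) - 6L)
  r0 <- floor((nr - rh) / 2) + 1L; r1 <- r0 + rh - 1L
  cgap <- floor(nc / 2)
  c0c <- max(3L, cgap - bw - 6L); c1c <- c0c + bw - 1L
  c0s <- min(nc - 2L, cgap + 7L); c1s <- c0s + bw - 1L
  list(control_blob = region(r0, r1, c0c, c1c),
       salt_blob = region(r0, r1, c0s, c1s),
       control_region = region(1, nr, 1, cgap),
       salt_region = region(1, nr, cgap + 1L, nc))
}

#' Treatment regions of a synthetic scene
#'
#' @param spec a `scene_spec`.
#' @return A list with `control` and `salt` [region()]s (the left and right
#'   halves of the scene).
#' @export
scene_regions <- function(spec) {
  l <- scene_layout(spec)
  list(control = l$control_region, salt = l$salt_region)
}

#' Render a synthetic scene
#'
#' Draws the scene deterministically from `spec$seed`. Draw order: one
#' uniform per vegetation pixel for the abundance (converted by the Beta
#' quantile function, so abundances are coupled monotonically across `shift`
#' values at a fixed seed), then the illumination factors, then the noise
#' array. One pure control pixel (a = 0) and one pure salt pixel (a = 1),
#' both at unit illumination, are planted at the blob centers.
#'
#' @param spec a `scene_spec`.
#' @return A list with `cube` (a reflectance [spectral_cube()]) and `truth`
#'   (class `scene_truth`: `abundance_map`, `label_map` with values
#'   background/control/salt, `edge_map`, `endmember_locations`, and the
#'   generating spectra).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols; nb <- length(spec$band_centers)
  lay <- scene_layout(spec)
  label <- matrix("background", nr, nc)
  cb <- lay$control_blob; sb <- lay$salt_blob
  label[cb[1]:cb[2], cb[3]:cb[4]] <- "control"
  label[sb[1]:sb[2], sb[3]:sb[4]] <- "salt"
  # edge rim: outermost ring of each blob
  edge <- matrix(FALSE, nr, nc)
  if (spec$edge_mix_width == 1L) {
    for (b in list(cb, sb)) {
      edge[b[1]:b[2], c(b[3], b[4])] <- TRUE
      edge[c(b[1], b[2]), b[3]:b[4]] <- TRUE
    }
  }
  veg <- label != "background"
  veg_idx <- which(veg)                       # column-major linear indices
  n_veg <- length(veg_idx)

  abund <- matrix(NA_real_, nr, nc)
  illum <- matrix(1, nr, nc)
  m <- ifelse(label[veg_idx] == "salt",
              spec$base_abundance + spec$shift, spec$base_abundance)
  draws <- local_seed(spec$seed, list(
    u = stats::runif(n_veg),
    il = if (spec$illum_sd > 0)
      stats::rlnorm(n_veg, meanlog = 0, sdlog = spec$illum_sd)
    else rep(1, n_veg),
    noise = if (spec$noise_sd > 0)
      array(stats::rnorm(nr * nc * nb, sd = spec$noise_sd), dim = c(nr, nc, nb))
    else array(0, dim = c(nr, nc, nb))))
  # degenerate means collapse to point masses
  abund[veg_idx] <- ifelse(m == 0, 0, ifelse(m == 1, 1,
    stats::qbeta(draws$u, shape1 = m * spec$concentration,
                 shape2 = (1 - m) * spec$concentration)))
  illum[veg_idx] <- draws$il
  noise <- draws$noise

  # planted pure pixels at the blob centers
  pure_c <- c(floor((cb[1] + cb[2]) / 2), floor((cb[3] + cb[4]) / 2))
  pure_s <- c(floor((sb[1] + sb[2]) / 2), floor((sb[3] + sb[4]) / 2))
  abund[pure_c[1], pure_c[2]] <- 0
  abund[pure_s[1], pure_s[2]] <- 1
  illum[pure_c[1], pure_c[2]] <- 1
  illum[pure_s[1], pure_s[2]] <- 1

  vals <- array(rep(spec$background_spectrum, each = nr * nc), dim = c(nr, nc, nb))
  a_vec <- abund[veg_idx]; il_vec <- illum[veg_idx]
  # vegetation spectra: illum * ((1-a) w_c + a w_s), one band at a time
  for (k in seq_len(nb)) {
    plane <- vals[, , k]
    veg_val <- il_vec * ((1 - a_vec) * spec$w_control[k] + a_vec * spec$w_salt[k])
    plane[veg_idx] <- veg_val
    edge_sel <- edge[veg_idx]
    if (any(edge_sel))
      plane[veg_idx[edge_sel]] <- 0.5 * veg_val[edge_sel] +
        0.5 * spec$background_spectrum[k]
    vals[, , k] <- plane
  }
  vals <- vals + noise
  vals[vals < 0] <- 0

  truth <- structure(list(abundance_map = abund, label_map = label,
                          edge_map = edge,
                          endmember_locations = rbind(control = pure_c,
                                                      salt = pure_s),
                          w_control = spec$w_control, w_salt = spec$w_salt,
                          layout = lay),
                     class = "scene_truth")
  list(cube = spectral_cube(vals, spec$band_centers, state = "reflectance"),
       truth = truth)
}

#' Simulate a set of lines differing only in stress response
#'
#' Builds the inputs for [run_experiment()]: one scene per line, all sharing
#' a single endmember-spectra pair (the lines are the same species under the
#' same instrument) and differing only in the salt-abundance `shift` and in
#' the per-scene pixel draws.
#'
#' @param shifts named numeric vector of mean-abundance shifts, one per line.
#' @param seed integer master seed; the shared spectra use `seed` and scene
#'   `i` uses `seed * 100 + i`.
#' @param ... further arguments passed to [scene_spec()].
#' @return A named list of lists with `cube`, `control_region`,
#'   `salt_region`, `truth`, ready for [run_experiment()] (drop `truth`
#'   first or pass as-is; extra fields are ignored by name matching).
#' @export
simulate_lines <- function(shifts, seed = 1L, ...) {
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("shifts must be named by line")
  dots <- list(...)
  bc <- if (!is.null(dots$band_centers)) dots$band_centers
        else seq(400, 900, length.out = 51)
  spectra <- make_vegetation_spectra(bc, seed = seed)
  out <- lapply(seq_along(shifts), function(i) {
    sp <- do.call(scene_spec, c(list(shift = shifts[[i]],
                                     w_control = spectra$w_control,
                                     w_salt = spectra$w_salt,
                                     seed = seed * 100L + i), dots))
    sc <- render_scene(sp)
    reg <- scene_regions(sp)
    list(cube = sc$cube, control_region = reg$control,
         salt_region = reg$salt, truth = sc$truth)
  })
  names(out) <- names(shifts)
  out
}

#' Write a scene truth to plain-text sidecar files
#'
#' Writes `<stem>_abundance.csv` (per-pixel true salt abundance) and
#' `<stem>_labels.csv` (class labels) alongside a cube written with
#' [write_cube()].
#'
#' @param truth a `scene_truth`.
#' @param stem output path stem.
#' @return The two paths, invisibly.
#' @export
write_scene_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "scene_truth"))
  pa <- paste0(stem, "_abundance.csv")
  pl <- paste0(stem, "_labels.csv")
  utils::write.table(truth$abundance_map, pa, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(truth$label_map, pl, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(c(pa, pl))
}
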