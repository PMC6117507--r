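#' Spectral cube container
#'
#' A `spectral_cube` holds a rows x cols x bands array of image data together
#' with the band-center wavelengths (nm) and the radiometric state of the
#' values: raw digital numbers (`"dn"`), at-sensor radiance
#' (W m^-2 sr^-1 nm^-1, `"radiance"`), or unitless `"reflectance"`.
#' Reflectance values above 1 are permitted (specular pixels exist); negative
#' reflectance is not.
#'
#' @param values 3-D numeric array, rows x cols x bands.
#' @param band_centers numeric vector of band-center wavelengths in nm,
#'   strictly increasing, length equal to `dim(values)[3]`.
#' @param state radiometric state, one of `"dn"`, `"radiance"`,
#'   `"reflectance"`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, band_centers,
                          state = c("reflectance", "radiance", "dn")) {
  state <- match.arg(state)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (rows x cols x bands)")
  band_centers <- as.numeric(band_centers)
  if (length(band_centers) != dim(values)[3])
    stop("length(band_centers) must equal the number of bands")
  if (any(!is.finite(band_centers)) || any(diff(band_centers) <= 0))
    stop("`band_centers` must be finite and strictly increasing")
  if (any(!is.finite(values)))
    stop("cube values must be finite")
  if (state == "reflectance" && any(values < 0))
    stop("reflectance cube must be non-negative")
  structure(list(values = values, band_centers = band_centers, state = state),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), state: %s\n",
              d[1], d[2], d[3], min(x$band_centers), max(x$band_centers),
              x$state))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

# ---- ENVI-style raster I/O ------------------------------------------------
# Header is a plain-text `<path>.hdr` companion; binary file holds the samples
# in one of the three standard interleaves. Only floating-point data types
# (ENVI codes 4 = float32, 5 = float64) are supported.

envi_header_path <- function(path) paste0(path, ".hdr")

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_scalar <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NA_character_)
    trimws(m[2])
  }
  get_block <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?si)", key, "\\s*=\\s*\\{([^}]*)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    parts <- strsplit(m[2], "[,[:space:]]+")[[1]]
    as.numeric(parts[nzchar(parts)])
  }
  list(
    samples    = as.integer(get_scalar("samples")),
    lines      = as.integer(get_scalar("lines")),
    bands      = as.integer(get_scalar("bands")),
    data_type  = as.integer(get_scalar("data type")),
    interleave = tolower(get_scalar("interleave")),
    byte_order = as.integer(get_scalar("byte order")),
    state      = get_scalar("radiometric state"),
    wavelength = get_block("wavelength")
  )
}

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a binary raster plus its `<path>.hdr` text header. The header must
#' provide `samples`, `lines`, `bands`, `data type` (4 or 5), `interleave`
#' (bsq, bil or bip) and a `wavelength` block; a nonstandard
#' `radiometric state` key, written by [write_cube()], is honoured when
#' `state` is not supplied.
#'
#' @param path path to the binary raster (header expected at `<path>.hdr`).
#' @param state optional radiometric state overriding the header.
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path, state = NULL) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (!file.exists(hdr_path)) stop("header file not found: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  if (is.null(h$wavelength))
    stop("header is missing the wavelength block")
  for (k in c("samples", "lines", "bands"))
    if (is.na(h[[k]])) stop("header is missing field: ", k)
  if (length(h$wavelength) != h$bands)
    stop("header wavelength count does not match bands")
  if (!h$data_type %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", h$data_type)
  size <- if (h$data_type == 4L) 4L else 8L
  n_expected <- as.numeric(h$samples) * h$lines * h$bands
  actual_bytes <- file.info(path)$size
  if (actual_bytes != n_expected * size)
    stop(sprintf("header/data size mismatch: header implies %d bytes, file has %d",
                 n_expected * size, actual_bytes))
  endian <- if (!is.na(h$byte_order) && h$byte_order == 1L) "big" else "little"
  raw_vals <- readBin(path, what = "numeric", n = n_expected, size = size,
                      endian = endian)
  interleave <- if (is.na(h$interleave)) "bsq" else h$interleave
  # ENVI binary order: sample varies fastest within a line
  arr <- switch(interleave,
    bsq = aperm(array(raw_vals, dim = c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(raw_vals, dim = c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(raw_vals, dim = c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
    stop("unsupported interleave: ", interleave))
  if (is.null(state)) {
    state <- if (!is.na(h$state) && h$state %in% c("dn", "radiance", "reflectance"))
      h$state else "reflectance"
  }
  spectral_cube(arr, h$wavelength, state = state)
}

#' Write an ENVI-style hyperspectral cube
#'
#' Writes the binary raster at `path` and a text header at `<path>.hdr`.
#' Data are stored as float64 (ENVI data type 5) so that a
#' [read_cube()] round trip is bit-exact.
#'
#' @param cube a [spectral_cube()].
#' @param path output path for the binary raster.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bil", "bip", "bsq")) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  arr <- switch(interleave,
    bsq = aperm(cube$values, c(2, 1, 3)),
    bil = aperm(cube$values, c(2, 3, 1)),
    bip = aperm(cube$values, c(3, 2, 1)))
  writeBin(as.vector(arr), path, size = 8L, endian = "little")
  hdr <- c(
    "ENVI",
    "description = {saltrank spectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("radiometric state = %s", cube$state),
    sprintf("wavelength = {%s}",
            paste(format(cube$band_centers, trim = TRUE, digits = 15),
                  collapse = ", ")))
  writeLines(hdr, envi_header_path(path))
  invisible(path)
}

# ---- Radiometric conversion -----------------------------------------------

#' Convert raw digital numbers to radiance
#'
#' Applies a per-band linear model `radiance = gain * DN + offset`, standing in
#' for an instrument radiometric-calibration table.
#'
#' @param cube a [spectral_cube()] in `"dn"` state.
#' @param gain,offset numeric, length 1 or one value per band.
#' @return A [spectral_cube()] in `"radiance"` state.
#' @export
dn_to_radiance <- function(cube, gain, offset = 0) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state != "dn") stop("cube is not in dn state")
  nb <- dim(cube$values)[3]
  gain <- rep_len(gain, nb); offset <- rep_len(offset, nb)
  vals <- sweep(sweep(cube$values, 3, gain, "*"), 3, offset, "+")
  spectral_cube(vals, cube$band_centers, state = "radiance")
}

#' Convert radiance to reflectance against a white reference panel
#'
#' For each band, reflectance = radiance / (mean panel radiance) x
#' `panel_reflectance`. The default panel reflectance 0.997 corresponds to a
#' Spectralon white reference, which reflects ~99.7% of incident light
#' diffusely.
#'
#' @param cube a [spectral_cube()] in `"radiance"` state (or `"dn"` with
#'   `gain`/`offset` supplied, converted linearly first).
#' @param panel_region a [region()] covering the reference panel.
#' @param panel_reflectance panel reflectance fraction, default 0.997.
#' @param gain,offset optional per-band linear DN-to-radiance coefficients.
#' @return A [spectral_cube()] in `"reflectance"` state.
#' @export
to_reflectance <- function(cube, panel_region, panel_reflectance = 0.997,
                           gain = NULL, offset = 0) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$state == "dn") {
    if (is.null(gain)) stop("dn cube requires gain/offset for conversion")
    cube <- dn_to_radiance(cube, gain, offset)
  }
  if (cube$state != "radiance")
    stop("cube must be in radiance (or dn) state")
  if (missing(panel_region) || is.null(panel_region))
    stop("panel_region is required to convert radiance to reflectance")
  r <- as_region(panel_region, dim(cube$values)[1:2])
  panel <- cube$values[r[1]:r[2], r[3]:r[4], , drop = FALSE]
  panel_mean <- apply(panel, 3, mean)
  if (any(panel_mean == 0))
    stop("panel has zero mean radiance in at least one band")
  vals <- sweep(cube$values, 3, panel_mean, "/") * panel_reflectance
  spectral_cube(vals, cube$band_centers, state = "reflectance")
}

# ---- Noisy-band removal ---------------------------------------------------

#' Remove noisy spectral bands
#'
#' Drops `edge_trim` bands at each spectral end, then every band whose center
#' wavelength falls inside any of the closed nm intervals in `windows`. The
#' defaults drop the first and last five bands and the windows around the
#' O2 (~760 nm) and H2O (~820 nm) atmospheric absorption features.
#'
#' @param cube a [spectral_cube()].
#' @param edge_trim number of bands dropped at each spectral end.
#' @param windows list of length-2 numeric vectors `(low_nm, high_nm)`.
#' @return A list with elements `cube` (the filtered [spectral_cube()]) and
#'   `filter` (a `band_filter` recording kept indices and wavelengths).
#' @export
remove_noisy_bands <- function(cube, edge_trim = 5,
                               windows = list(c(753, 766), c(813, 827))) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (edge_trim < 0) stop("edge_trim must be >= 0")
  nb <- length(cube$band_centers)
  keep <- rep(TRUE, nb)
  if (edge_trim > 0) {
    if (2 * edge_trim >= nb) stop("edge_trim removes all bands")
    keep[seq_len(edge_trim)] <- FALSE
    keep[(nb - edge_trim + 1L):nb] <- FALSE
  }
  for (w in windows) {
    if (length(w) != 2 || w[1] > w[2]) stop("each window must be (low, high)")
    keep <- keep & !(cube$band_centers >= w[1] & cube$band_centers <= w[2])
  }
  if (!any(keep)) stop("band removal would drop every band")
  filt <- structure(list(kept_indices = which(keep),
                         kept_wavelengths = cube$band_centers[keep],
                         removal_windows = windows,
                         edge_trim = edge_trim),
                    class = "band_filter")
  list(cube = apply_band_filter(cube, filt), filter = filt)
}

#' Apply a previously computed band filter
#'
#' Keeps the bands whose centers are in the filter's kept-wavelength set, so
#' applying the same filter twice is a no-op.
#'
#' @param cube a [spectral_cube()].
#' @param filter a `band_filter` from [remove_noisy_bands()].
#' @return The filtered [spectral_cube()].
#' @export
apply_band_filter <- function(cube, filter) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(filter, "band_filter"))
  keep <- cube$band_centers %in% filter$kept_wavelengths
  if (!any(keep)) stop("filter keeps no band of this cube")
  spectral_cube(cube$values[, , keep, drop = FALSE],
                cube$band_centers[keep], state = cube$state)
}
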