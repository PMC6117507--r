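# Shared fixtures built in code.

# a tiny deterministic reflectance cube with a centered vegetation-like block
tiny_cube <- function(n_rows = 8, n_cols = 9, bands = seq(450, 850, by = 50),
                      veg = 0.6, bg = 0.1) {
  nb <- length(bands)
  vals <- array(bg, dim = c(n_rows, n_cols, nb))
  spectral_cube(vals, bands, state = "reflectance")
}

# a small rendered scene, smaller than the default study conditions, for
# fast structural tests
small_scene <- function(shift = 0.2, seed = 11, ...) {
  sp <- scene_spec(n_rows = 40, n_cols = 60, shift = shift, seed = seed, ...)
  c(render_scene(sp), list(spec = sp, regions = scene_regions(sp)))
}

# random pixel matrix with labels, for endmember / similarity tests
random_pm <- function(n = 50, d = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n * d), d, n)
  structure(list(X = X,
                 labels = factor(sample(c("control", "salt"), n, replace = TRUE),
                                 levels = c("control", "salt")),
                 coords = cbind(row = seq_len(n), col = rep(1L, n)),
                 band_centers = seq(400, by = 10, length.out = d),
                 shape = c(n, 1L),
                 n_c = NA, n_s = NA),
            class = "pixel_matrix")
}

# similarity field from raw values and labels
field_of <- function(s, labels) {
  structure(list(s = s,
                 labels = factor(labels, levels = c("control", "salt")),
                 coords = NULL, shape = NULL),
            class = "similarity_field")
}
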