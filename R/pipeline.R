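# End-to-end orchestration: preprocessing -> vegetation mask -> endmember
# extraction -> similarity -> ranking statistics, per line and per
# experiment.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline on one line's image
#'
#' Executes, in order: radiometric conversion (when the cube is not yet
#' reflectance), noisy-band removal, NDVI/EGI masking, mixed-pixel erosion,
#' treatment labelling, flattening, endmember extraction, vector-wise
#' similarity, class balancing by stratified subsampling, and the three
#' ranking statistics. Errors are propagated with the failing stage name.
#'
#' @param cube a [spectral_cube()] containing both treatments of one line.
#' @param control_region,salt_region disjoint [region()]s assigning
#'   treatments.
#' @param panel_region optional white-panel [region()]; required when the
#'   cube is in radiance or dn state.
#' @param panel_reflectance panel reflectance fraction (default 0.997).
#' @param gain,offset optional per-band DN-to-radiance coefficients.
#' @param edge_trim,drop_windows noisy-band removal settings (see
#'   [remove_noisy_bands()]); `edge_trim = 0` and `drop_windows = list()`
#'   disable removal.
#' @param t_ndvi,t_egi vegetation index thresholds.
#' @param index_bands named vector with `blue`, `green`, `red`, `nir`
#'   requested wavelengths (nm).
#' @param n_bins similarity histogram bin count (default 100).
#' @param split posterior split point (default 0.5).
#' @param posterior_bins bins for the binned posterior curves (default 10).
#' @param method endmember search method (see [extract_endmembers()]).
#' @param seed RNG seed for the stratified subsampling.
#' @return An object of class `line_result`: pixel `counts` per stage,
#'   `filter`, `pair`, `field` (full similarity field), `balanced` (balanced
#'   similarity field), `nrd`, `auc`, `histograms`, `mdpa`, `bayes`,
#'   `posterior_curve`.
#' @export
run_line <- function(cube, control_region, salt_region,
                     panel_region = NULL, panel_reflectance = 0.997,
                     gain = NULL, offset = 0,
                     edge_trim = 5, drop_windows = list(c(753, 766), c(813, 827)),
                     t_ndvi = 0.5, t_egi = 0.05,
                     index_bands = c(blue = 470, green = 550, red = 670, nir = 800),
                     n_bins = 100, split = 0.5, posterior_bins = 10,
                     method = "farthest_point", seed = 1L) {
  cube <- stage("cube_io", {
    stopifnot(inherits(cube, "spectral_cube"))
    if (cube$state != "reflectance")
      cube <- to_reflectance(cube, panel_region, panel_reflectance,
                             gain = gain, offset = offset)
    cube
  })
  filt <- NULL
  cube <- stage("cube_io", {
    if (edge_trim > 0 || length(drop_windows) > 0) {
      rb <- remove_noisy_bands(cube, edge_trim = edge_trim,
                               windows = drop_windows)
      filt <- rb$filter
      rb$cube
    } else cube
  })
  masked <- stage("vegetation_mask", {
    ndvi <- ndvi_image(cube, red_nm = index_bands[["red"]],
                       nir_nm = index_bands[["nir"]])
    egi <- egi_image(cube, blue_nm = index_bands[["blue"]],
                     green_nm = index_bands[["green"]],
                     red_nm = index_bands[["red"]])
    prim <- primary_mask(ndvi, egi, t_ndvi = t_ndvi, t_egi = t_egi)
    fin <- filter_mixed_pixels(prim)
    lab <- assign_treatment(fin, control_region, salt_region)
    pm <- flatten_cube(cube, lab)
    counts <- c(primary = sum(prim), final = sum(fin),
                dropped = attr(lab, "dropped"), labeled = ncol(pm$X))
    stopifnot(counts[["labeled"]] == counts[["final"]] - counts[["dropped"]])
    list(pm = pm, counts = counts)
  })
  pm <- masked$pm
  pair <- stage("endmember_extraction", extract_endmembers(pm, method = method))
  field <- stage("similarity", vsm(pm, pair))
  ranked <- stage("stress_ranking", {
    nrd <- nrd_curve(pm$X[, pm$labels == "control", drop = FALSE],
                     pm$X[, pm$labels == "salt", drop = FALSE],
                     pm$band_centers)
    auc <- auc_energy(nrd)
    hists <- class_histograms(field, b = n_bins)
    # balance classes by stratified subsampling of the larger one
    target <- min(hists$control$n, hists$salt$n)
    hc <- if (hists$control$n > target)
      stratified_subsample(hists$control, target, seed = seed) else hists$control
    hs <- if (hists$salt$n > target)
      stratified_subsample(hists$salt, target, seed = seed) else hists$salt
    balanced <- structure(list(
      s = c(hc$values, hs$values),
      labels = factor(rep(c("control", "salt"), c(hc$n, hs$n)),
                      levels = c("control", "salt")),
      coords = NULL, shape = NULL), class = "similarity_field")
    list(nrd = nrd, auc = auc, histograms = list(control = hc, salt = hs),
         mdpa = mdpa(hc, hs),
         bayes = bayes_table(balanced, split = split),
         posterior_curve = binned_posterior(balanced, nbins = posterior_bins),
         balanced = balanced)
  })
  structure(c(list(counts = masked$counts, filter = filt, pair = pair,
                   field = field), ranked),
            class = "line_result")
}

#' @export
print.line_result <- function(x, ...) {
  cat("<line_result>\n")
  cat(sprintf("  pixels: %d primary -> %d after erosion -> %d labeled (%d dropped)\n",
              x$counts[["primary"]], x$counts[["final"]],
              x$counts[["labeled"]], x$counts[["dropped"]]))
  cat(sprintf("  endmember separation: %.4g\n", x$pair$separation))
  cat(sprintf("  AUC: %.4g J   MDPA: %.4g   posterior P(salt|s>%.2g): %.4f\n",
              x$auc, x$mdpa, x$bayes$split, x$bayes$posterior))
  invisible(x)
}

#' Run the pipeline over several lines and rank them
#'
#' Applies [run_line()] to each line and ranks the lines by each of the three
#' statistics (ascending: most tolerant first). A concordance note records
#' whether all three statistics agree on the ordering.
#'
#' @param lines a named list; each element is a list with at least `cube`,
#'   `control_region`, `salt_region`, plus any [run_line()] overrides.
#' @param ... shared arguments passed to [run_line()].
#' @return An object of class `salt_rank`: per-line results, the three
#'   ranking tables, and `concordant`.
#' @export
run_experiment <- function(lines, ...) {
  if (length(lines) < 2) stop("ranking needs at least two lines")
  if (is.null(names(lines)) || any(!nzchar(names(lines))))
    stop("lines must be named")
  shared <- list(...)
  results <- lapply(names(lines), function(nm) {
    args <- lines[[nm]]
    args <- args[names(args) %in% names(formals(run_line))]
    do.call(run_line, c(args, shared[setdiff(names(shared), names(args))]))
  })
  names(results) <- names(lines)
  stats_of <- function(f) vapply(results, f, numeric(1))
  rankings <- list(
    auc = rank_lines(stats_of(function(r) r$auc)),
    mdpa = rank_lines(stats_of(function(r) r$mdpa)),
    posterior = rank_lines(stats_of(function(r) r$bayes$posterior)))
  orders <- lapply(rankings, function(r) r$line)
  concordant <- all(vapply(orders[-1], identical, logical(1), orders[[1]]))
  structure(list(results = results, rankings = rankings,
                 concordant = concordant),
            class = "salt_rank")
}

#' @export
print.salt_rank <- function(x, ...) {
  cat("Salt-stress tolerance ranking (", length(x$results), " lines)\n", sep = "")
  tab <- summary(x)
  print(tab, row.names = FALSE, digits = 4)
  cat(if (x$concordant) "All three statistics agree on the ordering.\n"
      else "The three statistics disagree on the ordering.\n")
  invisible(x)
}

#' Summarise a ranked experiment
#'
#' @param object a `salt_rank`.
#' @param ... unused.
#' @return A data frame, one row per line in posterior order (most tolerant
#'   first), with the three statistics and the Bayes components as
#'   percentages.
#' @export
summary.salt_rank <- function(object, ...) {
  ord <- object$rankings$posterior$line
  r <- object$results[ord]
  data.frame(
    line = ord,
    auc_J = vapply(r, function(z) z$auc, numeric(1)),
    mdpa = vapply(r, function(z) z$mdpa, numeric(1)),
    prior_pct = vapply(r, function(z) 100 * z$bayes$prior, numeric(1)),
    cc_salt_pct = vapply(r, function(z) 100 * z$bayes$cc_salt, numeric(1)),
    evidence_pct = vapply(r, function(z) 100 * z$bayes$evidence, numeric(1)),
    posterior_pct = vapply(r, function(z) 100 * z$bayes$posterior, numeric(1)),
    row.names = NULL)
}

#' Plot a ranked experiment
#'
#' Draws the per-line NRD curves, the three ranking statistics as bar charts,
#' and the binned posterior curves, using base graphics.
#'
#' @param x a `salt_rank`.
#' @param ... unused.
#' @export
plot.salt_rank <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  nms <- names(x$results)
  cols <- grDevices::hcl.colors(length(nms), "Dark 2")
  # NRD curves
  first <- x$results[[1]]$nrd
  graphics::plot(first$band_centers, first$nrd, type = "n",
                 xlab = "wavelength (nm)", ylab = "NRD", main = "NRD curves",
                 ylim = range(unlist(lapply(x$results, function(r) r$nrd$nrd)),
                              na.rm = TRUE))
  for (i in seq_along(nms)) {
    cv <- x$results[[i]]$nrd
    graphics::lines(cv$band_centers, cv$nrd, col = cols[i])
  }
  graphics::legend("topleft", legend = nms, col = cols, lty = 1, cex = 0.7)
  graphics::barplot(vapply(x$results, function(r) r$auc, numeric(1)),
                    names.arg = nms, main = "NRD AUC (J)", las = 2,
                    col = cols)
  graphics::barplot(vapply(x$results, function(r) r$mdpa, numeric(1)),
                    names.arg = nms, main = "MDPA", las = 2, col = cols)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "similarity to salt endmember", ylab = "P(salt | bin)",
                 main = "Binned posterior")
  for (i in seq_along(nms)) {
    pc <- x$results[[i]]$posterior_curve
    mid <- (pc$lower + pc$upper) / 2
    graphics::lines(mid, pc$posterior_salt, col = cols[i], type = "b", pch = 16,
                    cex = 0.6)
  }
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Per-line report in Table-1 layout
#'
#' @param result a `line_result`.
#' @param digits decimals for the percentage columns.
#' @return A one-row data frame with the Bayes components as percentages.
#' @export
bayes_report <- function(result, digits = 2) {
  stopifnot(inherits(result, "line_result"))
  b <- result$bayes
  data.frame(prior_pct = round(100 * b$prior, digits),
             cc_salt_pct = round(100 * b$cc_salt, digits),
             evidence_pct = round(100 * b$evidence, digits),
             posterior_pct = round(100 * b$posterior, digits))
}

#' Run an experiment described by a YAML configuration
#'
#' The configuration lists per-line cube paths and treatment regions plus any
#' shared pipeline settings, e.g.:
#' ```yaml
#' seed: 1
#' edge_trim: 5
#' lines:
#'   A: {cube: a.bil, control_region: [1,100,1,50], salt_region: [1,100,51,100]}
#'   B: {cube: b.bil, control_region: [1,100,1,50], salt_region: [1,100,51,100]}
#' ```
#'
#' @param path path to the YAML file.
#' @return A `salt_rank` object.
#' @export
run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$lines) || length(cfg$lines) < 2)
    stop("config must list at least two lines")
  lines <- lapply(cfg$lines, function(l) {
    stopifnot(!is.null(l$cube), !is.null(l$control_region), !is.null(l$salt_region))
    out <- l
    out$cube <- read_cube(l$cube)
    out$control_region <- as_region(unlist(l$control_region))
    out$salt_region <- as_region(unlist(l$salt_region))
    if (!is.null(l$panel_region)) out$panel_region <- as_region(unlist(l$panel_region))
    out
  })
  shared <- cfg[setdiff(names(cfg), "lines")]
  shared <- shared[names(shared) %in% names(formals(run_line))]
  do.call(run_experiment, c(list(lines = lines), shared))
}
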