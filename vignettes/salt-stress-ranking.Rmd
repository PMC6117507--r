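---
title: "Ranking salt-stress tolerance from hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking salt-stress tolerance from hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltrank)
```

## The measurement model

A push-broom hyperspectral camera delivers, per plant line, one reflectance
cube containing both a control and a salt-treated group of plants. The
working assumptions of the pipeline are:

* **Linear mixing.** After masking, each vegetation pixel's spectrum is
  approximately a convex combination of two pure spectra — healthy (control)
  tissue and salt-responding tissue — plus noise. This is the standard
  linear spectral unmixing model restricted to two endmembers.
* **Pure pixels exist.** At millimetre ground resolution, at least one pixel
  per class is essentially pure, so the two endmembers can be *selected*
  from the data rather than estimated: they are the two pixels farthest
  apart in spectral feature space (the vertices of the maximum-volume
  1-simplex).
* **Within-image comparison.** Every statistic compares a line's salt pixels
  with that same line's control pixels from the same image, so between-line
  differences in leaf colour, waxiness or illumination largely cancel.

Under these assumptions the similarity of a pixel `r` to the salt endmember
is its normalized projection coordinate on the endmember axis,

$$ s \;=\; \operatorname{clamp}\!\left(
   \frac{\langle r - w_1,\; w_2 - w_1\rangle}{\lVert w_2 - w_1\rVert^2},
   \; 0, \; 1\right), $$

and the similarity to the control endmember is `1 - s`. The cube collapses
to a single gray-scale image, a d-fold storage reduction, with no loss of
the information the ranking statistics use.

### Why the clamp

The projection coordinate of a pixel lying beyond either endmember falls
outside `[0, 1]`, and a definition via absolute distances would then violate
the sum-to-one property. Clamping restores both the box constraint and the
complementarity `s_control + s_salt = 1`, and it reproduces exactly the
solution of the constrained unmixing problem

$$ \min_h \lVert x - W h \rVert^2
   \quad\text{s.t.}\quad \mathbf{1}^{\!\top} h = 1,\; 0 \le h \le 1, $$

which the package keeps as an independent oracle: `qp_unmix()` minimises the
residual over the simplex parameter by golden-section/parabolic search
(`stats::optimize`, tolerance 1e-10) per pixel — a deliberately different
numerical route from the closed-form projection, so agreement (`vsm` vs
`qp_unmix` within 1e-6, tested at scale) is evidence, not tautology.

## Ranking statistics

* **NRD-AUC.** Per band, `NRD = (mean_control - mean_salt) / mean_control`;
  bands with a zero control mean are flagged undefined and *excluded* from
  the area (zero-filling would silently shrink it). Wavelengths are
  converted to photon energies `E = hc/lambda` and the signed curve is
  integrated by trapezoids over absolute energy increments, bands taken in
  wavelength order. Units: joules.
* **MDPA.** Class similarity histograms use `b = 100` bins of width 0.01;
  bins are half-open `[k/b, (k+1)/b)` with the last bin closed so that the
  salt endmember itself (`s = 1`) is in range. The distance is the sum of
  absolute prefix-sum differences — the minimal number of one-bin moves
  equalising the histograms, i.e. the 1-D earth-mover distance on an
  ordinal axis — divided by the per-class pixel count. Equal totals are a
  precondition; the larger class is reduced by stratified subsampling
  (below). The ordinal character matters: permuting bins changes MDPA,
  unlike Euclidean or Bhattacharyya distances, and the tests assert this.
* **Bayesian posterior.** Similarities are split at `s > 0.5` (strict); with
  balanced classes the priors are equal and
  `P(salt | s > 0.5) = cc_s / (cc_s + cc_c)` with
  `cc_c = 2 * evidence - cc_s`. Both parameterisations are implemented and
  agree to 1e-12. If no pixel exceeds the split the posterior is flagged
  undefined rather than forced. A 10-bin posterior curve
  (`binned_posterior()`) shows where along the similarity axis the classes
  separate; empty bins are NA.

Ascending order of any of the three statistics is the tolerance ranking
(smallest response first). `rank_lines()` breaks ties by line name and
flags them.

### Stratified subsampling

The larger class is reduced bin-by-bin: each bin contributes
`round(count * target/n)` members, implemented as floor plus a
largest-remainder top-up (ties to the lower bin index) so the total is
*exactly* the smaller class size — both Eq.-style balance for MDPA and the
equal-prior simplification of Bayes' rule require exact equality. Within a
bin, selection is uniform under the caller's seed; the same seed reproduces
the same subsample bit for bit.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `edge_trim` | 5 | bands | sensor edges are noisy |
| `drop_windows` | (753, 766), (813, 827) | nm | O₂ / H₂O absorption |
| `t_ndvi` | 0.5 | – | vegetation/background contrast; see below |
| `t_egi` | 0.05 | – | excludes achromatic background and shadow |
| index bands | 470/550/670/800 | nm | canonical blue/green/red/NIR; nearest kept band, no interpolation |
| `n_bins` | 100 | – | bin width 0.01 on `[0, 1]` |
| `split` | 0.5 | – | midpoint between endmembers |
| `posterior_bins` | 10 | – | posterior curve resolution |
| `panel_reflectance` | 0.997 | – | Spectralon white reference |

The NDVI/EGI thresholds have no canonical published values; the defaults are
package decisions. Band-removal windows operate on band *centers* as closed
nm intervals — the reproducible reading when the instrument's exact band
table is unknown; consequently the number of surviving bands depends on the
band grid and is reported, not contracted.

## Coordinate and interface conventions

Pixels are addressed 1-based as `(row, col)` and rectangular regions are
inclusive `(row_min, row_max, col_min, col_max)` — the native R convention,
preferred over a 0-based half-open scheme that would fight every subscript
in the implementation language. Flattening scans row-major (row by row) and
stores coordinates that invert it exactly. Erosion treats out-of-bounds
neighbours as background, so image-border pixels never survive — the literal
reading of "fewer than eight vegetation neighbours".

## Endmember search

The exact farthest pair costs O(n²) and is used for n up to a few thousand
and in tests. The default `farthest_point` search alternates
"move each end to the pixel farthest from the other" until a fixed point.
A single start can stall in a local optimum; but whenever *either* endpoint
of the globally farthest pair is a start, one alternation round finds the
optimum. The search therefore seeds from the 200 pixels most distant from
the centroid plus the extremes along the leading principal directions, with
the first half-step batched through one BLAS product. On 400 random
instances (n up to 2000, d up to 100; Gaussian, uniform and two-cluster
clouds) it matched the exact search in every case; the acceptance suite
re-runs 100 such instances. Ties in the exact search resolve to the
lexicographically smallest index pair.

Orientation — which end is "salt" — uses the treatment labels: the endmember
whose column is labelled control becomes `w1`; if both extremes carry the
same label, `w1` is the one nearer the control-class centroid. The labels
exist in every image by experimental design, so no spectral heuristic is
needed.

## The synthetic scene generator

`render_scene()` emulates exactly the features the pipeline's correctness
depends on:

* two vegetation-like endmember spectra (green bump, red edge near 700 nm,
  NIR plateau; the salt spectrum has a seed-reproducible depressed NIR
  plateau);
* per-pixel convex mixtures whose salt-class abundance is
  `Beta(mean = base + shift, concentration = 40)` — unimodal similarity
  histograms; abundances are drawn by quantile inversion of shared
  uniforms, so at a fixed seed the true class mean is monotone in `shift`;
* a multiplicative log-normal illumination factor with unit median
  (leaf-angle surrogate), applied to the whole spectrum;
* a distinct near-achromatic background, a planted pure pixel per class,
  and a planted 1-pixel 50/50 vegetation/background rim at every blob
  border to exercise the mixed-pixel filter.

The default *study conditions* are a 160 × 160 scene with two 128 × 58
blobs — roughly 14,000 vegetation pixels, matching the scale of a real
greenhouse image — 51 bands over 400–900 nm, base abundance 0.40,
illumination sd 0.01 (a 1 % multiplicative spread) and additive noise sd
0.003 in reflectance units (about 0.5 % of the NIR plateau; plausible for
noon imaging with a 12-bit sensor).
These sizes keep the full 4-line × 20-seed validation study within a few
minutes on one core. The noise level matters more than it may appear:
because the endmembers are *copies of data columns*, they inherit their
pixels' noise vectors, and that — not the illumination spread — dominates
the line-to-line jitter of the similarity scale.

**What the generator does not emulate** and what passing tests therefore do
not certify: realistic radiative transfer (no PROSPECT/SAIL), specular
highlights, strong leaf-geometry effects (real canopies can show far larger
geometry-driven variance than the 1 % surrogate), sensor smile/keystone or
PSF, and spatially correlated noise. Results on real imagery depend on those
factors; the synthetic study validates the algorithmic chain, not the
biology.

In multi-line experiments all lines share one endmember-spectra pair and
differ only in `shift` (`simulate_lines()`): the lines of a real experiment
are one species under one instrument, and giving each line its own spectral
perturbation would confound the stress response amplitude with the planted
ordering.

## Numerical and degenerate-input policy

* Zero-denominator NDVI pixels map to 0; zero control-mean NRD bands are NA
  and excluded from AUC; an all-identical pixel matrix (zero endmember
  separation) is an error, as is an empty class or an empty mask.
* `qp_unmix` compares the interior optimum against both box corners, so
  boundary solutions are exact.
* The degenerate generator settings (`shift = 0`, zero noise, point-mass
  abundance) reproduce `w_control` exactly; planted pure pixels override
  the abundance draw by construction.
* All randomness flows from explicit integer seeds: the scene seed governs
  the draw order (abundance uniforms, illumination, noise), and the
  subsampling seed is restored-state local, so library calls never perturb
  the caller's RNG stream.

## Validation summary

The test suite ties each stage to an independent reference: quadratic
unmixing for the similarity projection; a sorted-matching transport oracle
(itself certified by exhaustive permutation search at tiny sizes) plus full
enumeration of all histograms with up to 6 bins and 8 samples for MDPA;
brute-force O(n²) search for the endmember pair; EBImage erosion for the
morphological filter; direct Planck arithmetic for the energy AUC; and the
published worked examples for the Bayes table and the acquisition geometry.
The end-to-end study (4 lines at shifts 0/0.08/0.10/0.20, 20 seeds) checks
that all three statistics recover the planted order in at least 95 % of
seeds and that a zero shift yields a posterior statistically
indistinguishable from 50 %.

## Known limitations

* Two endmembers only; no multi-class unmixing or nonlinear mixing.
* The farthest-pair search is exact with high reliability but without a
  worst-case guarantee below O(n²); `method = "exact"` exists when
  certainty matters and n permits.
* Radiometric calibration is a per-band linear gain/offset model; vendor
  calibration file formats are out of scope.
* No geometric correction (smile, keystone, orthorectification) and no
  3-D leaf-geometry compensation.
* Ranking significance is not assessed; the package orders lines but does
  not test whether two lines differ beyond sampling noise.
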