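# saltrank

Quantitative ranking of plant lines by salt-stress tolerance from
hyperspectral images.

## The problem

Screening germplasm for salinity tolerance conventionally means weeks of
hydroponic culture followed by destructive biomass harvests, and even then a
genuinely tolerant landrace can look mediocre because biomass loss and yield
stability are different things. Hyperspectral imaging offers a faster route:
the reflectance spectrum of stressed leaf tissue deviates from that of
healthy tissue within a day of salt application, long before visual
symptoms. The difficulty is turning a `rows x cols x 200+ band` reflectance
cube into a single defensible number per line.

`saltrank` implements a full pipeline for that reduction, aimed at plant
phenotyping researchers working with push-broom hyperspectral cameras:

1. **Preprocessing** — ENVI-style cube I/O, DN → radiance → reflectance
   against a white reference panel (`read_cube()`, `to_reflectance()`), and
   removal of noisy bands at the spectral edges and around the O₂ (~760 nm)
   and H₂O (~820 nm) absorption features (`remove_noisy_bands()`).
2. **Vegetation mask** — NDVI and excess-green thresholding, then a 3 × 3
   binary erosion that discards every pixel with fewer than eight vegetation
   neighbours, purging spectrally mixed leaf-edge pixels
   (`primary_mask()`, `filter_mixed_pixels()`).
3. **Endmember extraction** — the two most spectrally extreme pixels of the
   masked image, i.e. the vertices of the maximum-length 1-simplex in
   feature space, serve as the pure control and salt spectra
   (`extract_endmembers()`).
4. **Similarity reduction** — every pixel spectrum *r* is projected onto the
   endmember axis and summarised by its clamped normalized position

   *s* = clamp( ⟨r − w₁, w₂ − w₁⟩ / ‖w₂ − w₁‖², 0, 1 ),

   its similarity to the salt endmember (`vsm()`). This equals the
   box-constrained two-endmember unmixing solution
   min ‖x − W h‖² s.t. h ≥ 0, 1ᵀh = 1 (`qp_unmix()`, kept as a slow
   per-pixel oracle) but needs one matrix product for the whole image.
5. **Ranking statistics** — three per-line numbers, each comparing the
   line's salt pixels against its own control pixels:
   - the normalized reflectance difference NRDᵢ = (C̄ᵢ − S̄ᵢ)/C̄ᵢ per band,
     integrated over photon energy E = hc/λ (`nrd_curve()`,
     `auc_energy()`);
   - the minimum difference of pair assignments (MDPA), the ordinal
     earth-mover distance between the class similarity histograms on
     balanced classes, D = Σᵢ |Σⱼ≤ᵢ (Hⱼ(C) − Hⱼ(S))| / n (`mdpa()`, with
     `stratified_subsample()` for balancing);
   - the Bayesian posterior P(salt | s > 0.5) =
     P(s > 0.5 | salt) / (P(s > 0.5 | salt) + P(s > 0.5 | control)) under
     the equal priors that balancing guarantees (`bayes_table()`,
     `binned_posterior()`).

   Smaller values mean a smaller spectral response to the treatment — a more
   tolerant line (`rank_lines()`).

A synthetic scene generator with full ground truth (`scene_spec()`,
`render_scene()`, `simulate_lines()`) makes every stage testable without the
original imagery, and `run_line()` / `run_experiment()` orchestrate the
whole pipeline.

## Worked example

Four synthetic lines whose salt classes shift toward the salt endmember by
0.02, 0.08, 0.10 and 0.20 in mean abundance:

```r
library(saltrank)
lines <- simulate_lines(c(Kharchia_like = 0.02, co_like = 0.08,
                          sp_like = 0.10, CS_like = 0.20), seed = 1)
ex <- run_experiment(lines, seed = 1)
print(ex)
#>           line     auc_J   mdpa prior_pct cc_salt_pct evidence_pct posterior_pct
#>  Kharchia_like 2.312e-22  2.084        50       19.01        16.65         57.09
#>        co_like 9.529e-22  7.946        50       43.38        29.86         72.64
#>        sp_like 1.204e-21  9.916        50       50.14        33.27         75.36
#>        CS_like 2.212e-21 18.880        50       86.32        53.35         80.90
#> All three statistics agree on the ordering.
```

Reading the table: the AUC column is the area under the per-band NRD curve
on the photon-energy axis (joules); MDPA is the histogram transport distance
in bin-index units per pixel; the last four columns are the Bayes-rule
components as percentages. All three statistics increase with the planted
abundance shift, and the least-responsive ("most tolerant") line ranks
first.

A shell interface covers the same ground:

```sh
exec/saltrank geometry --fov 33 --distance 1 --pixels 640 --speed 0.025
exec/saltrank simulate --out-dir scenes --shifts 0,0.08,0.1,0.2 --seed 1
exec/saltrank rank --config scenes/run.yaml --out-dir out
```

`geometry` prints the swath, ground pixel size and the frame rate a
push-broom scanner needs for square pixels (33°, 1 m, 640 px, 0.025 m/s
gives 27 fps).

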