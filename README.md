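# tjscope

Analysis toolkit for single-monolayer tight-junction studies that combine
barrier-function assays with widefield immunofluorescence and single-molecule
localization microscopy (SMLM) on the same Transwell filter.

The package is written for experiments of the following shape: an endothelial
monolayer (e.g. HUVEC) is grown on a porous filter, treated with a
barrier-modulating compound, and characterized in four steps —

1. **Barrier function.** Transendothelial electrical resistance (TER) is
   blank-corrected and area-normalized,
   `TER = (R_raw − R_blank) · A` with `A = 0.33 cm²`, and reported as the
   fold change `(TER_t / TER_initial) / control_ratio`. Paracellular flux of
   a fluorescent dextran tracer is quantified against an OLS calibration
   curve `AU = slope · conc + intercept` and expressed as percent of
   control. Conditions are compared with a classical two-sided Student's
   t-test.
2. **Widefield quantification.** Junction-protein immunofluorescence is
   quantified on maximum-intensity projections of z-stacks, as summed grey
   value per analyzed area, in manually annotated junction regions or over
   the whole (optionally tile-stitched) field.
3. **SMLM localization.** Blinking 16-bit TIFF time-stacks are converted to
   localization tables: the first 30 frames are discarded, candidates must
   exceed the robust per-frame background by 3 robust noise SDs, and each
   candidate is fit with a 2D Gaussian
   `offset + A · exp(−((x−x₀)² + (y−y₀)²) / 2σ²)`, yielding sub-pixel
   positions with covariance-based uncertainties.
4. **Spatial statistics.** Relative pairwise-distance histograms (0–200 nm
   same-channel, 0–400 nm cross-channel) are compared against a
   mask-conditioned complete-spatial-randomness (CSR) reference with a
   Monte-Carlo envelope; clustering is called at the 40 nm bin.
   Coordinate-based colocalization counts molecules with a partner of the
   other channel within 90 nm.

Because such studies rarely deposit raw imaging data, the package ships a
first-class synthetic-data generator: Voronoi junction-belt geometries,
clustered/dispersed fluorophore placements, EMCCD blinking movies
(integrated Gaussian PSF, Poisson shot noise × EM gain, Gaussian read
noise), widefield z-stacks with substrate-dependent background
(glass < PC < PE), and TER/flux records with known effect sizes. Every
analysis stage is therefore testable by parameter recovery.

## Worked example

```r
library(tjscope)

# a 20 x 20 um junction network with a clustered claudin-5-like channel
g  <- generate_junction_network(6, c(15000, 15000), seed = 17)
pc <- clustering_params("clustered", linear_density_per_um = 12,
                        cluster_sigma_nm = 20)
mol <- place_fluorophores(g, pc, seed = 1)

h    <- pairwise_distance_histogram(mol)         # 0-200 nm, 10 nm bins
ref  <- csr_reference(nrow(mol), rasterize_belts(g, 10, 0), seed = 1)
clustering_excess(h, ref, r_eval_nm = 40)
#> cluster_metric at 40 nm: observed 0.1185 vs CSR 0.0504 (ratio 2.35),
#>   envelope [0.0403, 0.0624] -> clustered

# barrier function with the default effect sizes (fold 1.30, flux 31.7%)
ds <- generate_functional_dataset(effect_params(replicate_cv = 0),
                                  n_replicates = 6, seed = 1)
recover_ter_fold(ds$ter, 1)$mean_fold
#> [1] 1.3
calibrate_and_quantify_flux(ds$standards, ds$flux)$percent_of_control
#> treated
#>    31.7
```

The observed 40 nm relative frequency (0.1185) sits far above the CSR
envelope upper bound (0.0624): the clustered placement is flagged, exactly
the signature a tightened claudin-5 belt shows. With measurement noise
switched off the generator's effect parameters are returned to machine
precision, confirming the normalization arithmetic.

The full four-stage workflow (with TIFF/CSV artifacts, a JSON summary and a
log) runs as:

```r
run_demo("demo_out", seed = 1)
```

or from a shell via `Rscript inst/scripts/tjscope-cli.R demo --outdir demo_out`.

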