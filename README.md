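# arrayevo

Tools for studying the architecture and evolution of bacterial chemosensory
arrays, aimed at structural microbiologists and comparative genomicists
working on chemotaxis.

In most γ-proteobacteria the flagellar motor is controlled by an F6-class
chemosensory system, while the enteric model organisms use F7. Tracing how
F7 took over flagellar control requires four kinds of computation, all
implemented here:

1. **Density-layer metrology.** A cryo-ET side view of an array is collapsed
   into a 1D profile along the membrane normal: for each bin at signed
   offset *t* from the membrane midplane, the mean of trilinearly
   interpolated densities over a plane patch parallel to the fitted
   membrane. Peak centres *c* are refined by a three-point parabola,
   `c = x_i + Δ·h` with `Δ = (y₁ − y₃) / (2(y₁ − 2y₂ + y₃))`, and reported
   with expanded uncertainty `U = k·u` (coverage factor k = 2). Distances
   between the CheA/CheW baseplate (AW), intermediate layers (L1, L2, L3)
   and the inner membrane (IM) combine as `U = k·√(u_a² + u_b²)`, and the
   hexagonal receptor-lattice spacing is estimated from the first ring of
   the image autocorrelation.
2. **Evolutionary stage classification.** F7 gene clusters are classified
   into five arrangement stages by token-level Levenshtein distance to
   built-in templates (both orientations; ties reported as ambiguous), with
   single-linkage homolog families built from pairwise scores at
   E ≤ 1e-40 and coverage ≥ 95% (anti-sigma factor antagonists: 1e-5 / 50%).
3. **Pentapeptide tether scan.** Receptor C-termini are tested against the
   CheR-tether motif `x-[HFYW]-x-x-[HFYW]`.
4. **CheY differential conservation.** Alignment columns conserved within
   each CheY group (modal frequency ≥ threshold), identical across the
   stage-3/4/5 groups but different in the ancestral F6 group, are mapped
   to E. coli CheY numbering and labelled (e.g. `M45K`); charge reversals
   (K/R/H vs D/E) are flagged even when the stage residues differ.

A first-class synthetic-data module (`gen_layer_volume()`,
`gen_hex_lattice()`, `gen_stage_cluster()`, `gen_group_alignments()`,
`gen_receptor_set()`) generates every input with machine-readable ground
truth, so the whole pipeline runs and is tested without external data.

## Worked example

Generate a tall-array phantom with layers 17.5 / 24.5 / 30.1 nm above a
baseplate 37 nm below the membrane, add voxel noise at half the layer
amplitude, and measure the layers back:

```r
library(arrayevo)

spec <- phantom_spec(
  dims = c(96, 40, 40), voxel_size = 1, membrane_position = 46,
  baseplate_offset = 37, layer_offsets = c(17.5, 24.5, 30.1),
  layer_sigma = 2, noise_sigma = 0.25, seed = 1
)
ph      <- gen_layer_volume(spec)
profile <- collapse_profile(ph$volume, ph$trace, extent_nm = 45)
peaks   <- label_peaks(detect_peaks(profile, min_prominence = 0.05,
                                    min_separation_nm = 4))
tidy(measure_layers(peaks, reference_label = "AW"))
#> # A tibble: 4 × 4
#>   label distance_nm expanded_uncertainty_nm     k
#>   <chr>       <dbl>                   <dbl> <dbl>
#> 1 IM           36.9                   0.153     2
#> 2 L1           17.4                   0.517     2
#> 3 L2           24.3                   0.417     2
#> 4 L3           29.8                   0.827     2
```

The three layer distances and the membrane height land within their
expanded uncertainties of the generated truth. The same objects plot with
`autoplot(profile, peaks = peaks)`.

Gene-cluster and sequence analyses follow the same tibble-in/tibble-out
style:

```r
cl <- gen_stage_cluster(3, n_flanking = 6, perturbations = "insert", seed = 2)
classify_stage(cl)
#> # A tibble: 1 × 4
#>   stage edit_distance reversed distances
#>   <chr>         <int> <lgl>    <list>
#> 1 3                 1 FALSE    <tbl_df>

hits <- scan_pentapeptide(gen_receptor_set(96, 34, seed = 130))
sum(hits$matched)
#> [1] 96
```

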