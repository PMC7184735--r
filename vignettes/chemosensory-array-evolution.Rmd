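---
title: "Measuring and tracing the evolution of bacterial chemosensory arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and tracing the evolution of bacterial chemosensory arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrayevo)
library(dplyr)
```

# Scope

Most γ-proteobacteria steer their flagella with an F6-class chemosensory
system, but the enterics (including *E. coli*) use an F7-class system.
`arrayevo` implements the computational analyses needed to study how the F7
system acquired flagellar control: metrology of chemoreceptor-array density
layers from cryo-electron tomography volumes, classification of F7 gene
clusters into evolutionary stages, detection of the C-terminal pentapeptide
CheR-tether motif in receptors, and group-differential conservation analysis
of CheY response regulators. Because the raw inputs (tomograms, genome
annotations, curated alignments) are large and externally curated, the
package also ships a synthetic-data module that generates all of them with
known ground truth, so every analysis is exercised end to end by code alone.

# 1D density-profile metrology

## Model

A membrane-bound chemoreceptor array in side view is a stack of density
sheets parallel to the inner membrane (IM): the membrane bilayer itself, the
CheA/CheW kinase baseplate (AW), and intermediate layers (L1, L2, ...,
numbered from the baseplate towards the membrane) arising from receptor
domains. `collapse_profile()` reduces a 3D subvolume to a 1D profile along
the membrane normal:

1. the membrane frame is fitted from user-supplied trace points that follow
   the IM on one 2D slice (`fit_membrane_frame()`): the in-slice major axis
   of the points is the membrane direction, its in-slice perpendicular the
   normal, oriented towards the side declared cytoplasmic;
2. for each bin along the normal, densities are trilinearly interpolated
   over a square patch of points parallel to the membrane and averaged.

Coordinate 0 is the membrane midplane; positive is cytoplasmic.

Peaks are found by prominence-filtered local maxima and refined by a
three-point parabola (`detect_peaks()`). The standard uncertainty of a peak
centre propagates a residual-noise estimate — the median absolute second
difference of the profile, scaled by `1/sqrt(6)` — through the gradient of
the parabola apex formula, and is reported expanded with a coverage factor
`k` (default 2, configurable). Distances between labelled peaks combine
uncertainties as `k * sqrt(u_a^2 + u_b^2)` (`measure_layers()`), and
repeated measurements pool as an arithmetic mean with
`sqrt(sum(u_i^2)) / n` propagation (`pool_measurements()`; inverse-variance
weighting is available behind the `weighted` flag). These estimator choices
are this package's: metrology practice fixes only the coverage-factor
convention, not a specific peak-centre estimator, so the parabola/noise
propagation combination is validated by Monte Carlo in the test suite
(sub-bin centre recovered to < 0.1 nm, ≥ 90% coverage at k = 2).

## Tunable parameters

* `extent_nm` — profile half-extent. Choose it to span the expected
  structure plus a small margin (we use array height + 8 nm): bins far
  beyond the baseplate contain only noise, and a noise bump there could
  masquerade as the most-cytoplasmic peak.
* `lateral_halfwidth_nm` (default 8) — averaging patch half-width; wider
  patches reduce noise but assume a flatter membrane.
* `bin_width_nm` (default 1) — along-normal resolution; the parabola
  refinement recovers sub-bin centres.
* sampling pitch — half the voxel size, halving interpolation aliasing.
* `min_prominence` — peak acceptance threshold in density units. For the
  phantom protocol (layer amplitude 0.5, voxel noise 0.25) we use 0.05:
  an order of magnitude above the per-bin noise after patch averaging, and
  below the weakest structural prominence (~0.13 for the layer squeezed
  between its neighbours).
* `min_separation_nm` (default 4 in our analyses) — merges maxima closer
  than the resolvable sheet separation.
* `invert` — for data where protein is dark rather than bright.

`label_peaks()` encodes the array geometry: the most cytoplasmic peak is
AW, peaks within 4 nm of the midplane are bilayer leaflets and are merged
into a single IM entry at their midpoint (the leaflet pair is symmetric
about the true membrane midplane, so the midpoint is the right coordinate
of record), and everything between is L1, L2, ... from AW towards IM.

## Lattice spacing

`estimate_lattice_spacing()` measures the hexagonal receptor packing from a
top-view image via the FFT autocorrelation. The radially averaged
autocorrelation detects the first ring; when no peak reaches
`min_prominence` (relative to zero lag) the function returns a flagged
no-lattice result instead of a number. The ring *position* from the radial
average alone is biased low — angular averaging of six discrete spots
contributes a `1/sqrt(r)` factor (Bessel asymptotics), and the mean-removed
autocorrelation sits on a negative sloping background — so the spacing is
measured from the individual first-ring maxima of the 2D autocorrelation,
each refined by separable sub-pixel parabolas, and averaged. On synthetic
12 nm lattices this recovers the spacing to better than 0.1 nm, where the
raw radial-average peak sits near 11.7 nm.

# The synthetic phantom

`gen_layer_volume()` renders Gaussian density sheets: two membrane leaflet
sheets 4 nm apart (σ = 1.2 nm; lipid leaflets image sharper than protein
layers), a baseplate sheet, and one sheet per layer (σ = 2 nm by default),
plus i.i.d. Gaussian voxel noise. Higher value means more mass; real data
with inverted polarity is handled by `detect_peaks(invert = TRUE)`. The
truth record carries every sheet position, so recovery can be scored
without human input. The default study geometry places layers 17.5, 24.5
and 30.1 nm above a baseplate 37 nm below the membrane — the tall-array
layout — and the per-species protocols use baseplate offsets of 24.3, 38.4
and 40.3 nm.

What the phantom does *not* emulate: missing-wedge anisotropy, CTF
modulation, membrane curvature, and structured background from neighbouring
cell components. Passing recovery tests therefore demonstrates the
correctness and calibration of the measurement chain, not robustness to
every artefact of real tomograms. Two simplifications matter for
interpretation: sheet overlap pulls adjacent peak centres together by up to
~0.15 nm at the 5.6 nm layer gap (well inside the reported uncertainties),
and the noise model makes bins independent, which real reconstruction
filters would not.

Problem sizes were chosen to keep a full phantom study interactive:
96 × 40 × 40 voxel volumes at 1 nm, 50 noise replicates per geometry,
20 lattice images of 128 × 128 px.

# Gene-cluster stage classification

The F7 gene cluster passed through five characteristic arrangements
(`stage_templates()`), from the ancestral form (anti-sigma factor
antagonist, cheY, cheA, two cheW, aer2-like receptor, cheR, cheD, cheB,
mcpA-like receptor, second anti-sigma factor antagonist, serine
phosphatase) to the enteric form (flhD, flhC, motA, motB in front, a
duplicated tar-like receptor, and the F6-derived cheY/cheZ pair at the
back). `classify_stage()` drops background labels (anything outside the
union of template alphabets, configurable), then computes a token-level
Levenshtein distance against each template in both orientations. The call
is the minimal-distance stage; ties are reported as `ambiguous`, never
broken arbitrarily; a cluster without relevant labels is `none`. Unit edit
costs are the simplest model consistent with a narrative of single-gene
gains, losses and moves; nothing in the data motivates weighted costs.
Duplicated labels (two cheW, two tar, two cheY) are distinct only by
position, and no attempt is made to distinguish F7 cheY from F6-like cheY
inside the alphabet — that distinction is positional in stages 4 and 5.

Homolog families are built by `link_families()` as single-linkage
components over pairwise scores passing `e_value <= 1e-40` and query
coverage ≥ 0.95 (both inclusive; anti-sigma factor antagonists use the
relaxed 1e-5 / 0.50 thresholds). Any aligner that produces a BLAST
outfmt-6-like table feeds `read_pair_scores()`. Neighbourhood extraction
(`extract_neighborhood()`) uses gene-count windows (10 for the CheB/CheR
search, 15 for cluster display) truncated at replicon ends.

# Pentapeptide tether and C-terminal conservation

`scan_pentapeptide()` tests the final five residues against
`x-[HFYW]-x-x-[HFYW]`, the motif that tethers the methyltransferase CheR.
The motif is anchored to the exact C-terminus by default because the
tether is a terminal extension; `search_tail` widens the window for
tolerantly annotated sequences. Ambiguity codes never satisfy the aromatic
constraint (conservative matching). `cterm_logo()` reports per-column
residue frequencies (gaps excluded from the denominator, gap fraction
reported separately) and information content `log2(20) - H` without
small-sample correction.

# CheY group-differential conservation

`gen_group_alignments()` emulates the four CheY groups compared in the
flagellar-takeover analysis — CheY-F6 (62 sequences after removal of two
gap-opening ones), and the F6-like CheYs of stage-3 (22), stage-4 (27) and
stage-5 (24) genomes — as one gapless alignment with per-group consensus
overrides and a per-column conservation probability.

`differential_positions()` reports columns that are conserved in every
group, identical in consensus across the stage groups, and different in
the F6 group, mapped to reference numbering (`map_columns_to_reference()`,
E. coli CheY coordinates in practice) and labelled like `M45K`.
`charge_reversals()` relaxes the stage-identity requirement to
charge-sign opposition (K/R, optionally H, positive; D/E negative), so a
K117→E reversal with D in one stage group still qualifies.

"Highly conserved" has no operational definition in the literature this
implements, so the threshold on the modal residue frequency is exposed
(`threshold`, default 0.9) and recorded in the output. The default is
deliberately strict; for small groups it should be relaxed, because the
empirical modal frequency of a column whose true conservation is c
fluctuates as Binomial(n, c)/n. At n = 22 and c = 0.95, the empirical
frequency falls below 0.9 about 9% of the time, so a 0.9 cutoff randomly
drops genuinely conserved columns; at threshold 0.75 the per-column miss
probability is below 1e-3. Our acceptance-scale analyses with the 62/22/27/24
group sizes therefore use 0.75. Columns with more than 50% gaps are
disqualified regardless of modal frequency, matching common logo practice.

# Receptor architecture and layer correspondence

`parse_architecture()` normalises hyphen-separated domain strings (PAS,
HAMP, TM, MCPsignal and synonyms). `expected_height()` holds the
heptad-class/array-height correspondence as data, not code: 24 ± 3 nm for
40H receptors, 22 ± 3 nm for the two-TM 34H topology, and 37 ± 4 nm for
36H Aer2-like receptors — the last an envelope this package defines over
the four measured tall arrays (35.1, 35.5, 38.4, 40.3 nm) rather than a
printed constant, which is why the table is serialisable JSON.
`correlate_layers()` assigns measured layers to user-supplied domain
positions by greedy nearest neighbour within a tolerance (default 3 nm; the
correspondence has no natural published tolerance because it is assessed
visually in practice), and reports exact ties as ambiguous.

# Worked example

```{r phantom, eval = FALSE}
spec <- phantom_spec(
  dims = c(96, 40, 40), voxel_size = 1, membrane_position = 46,
  baseplate_offset = 37, layer_offsets = c(17.5, 24.5, 30.1),
  layer_sigma = 2, noise_sigma = 0.25, seed = 1
)
ph <- gen_layer_volume(spec)
profile <- collapse_profile(ph$volume, ph$trace, extent_nm = 45)
peaks <- label_peaks(detect_peaks(profile, min_prominence = 0.05,
                                  min_separation_nm = 4))
report <- measure_layers(peaks, reference_label = "AW")
tidy(report)
autoplot(profile, peaks = peaks)
```

# Known limitations

* One global membrane frame per trace: strongly curved membranes must be
  split into approximately planar traces.
* The stage classifier scores arrangements, not sequences; a cluster of
  paralogous but rearranged genes can sit equidistant from two templates
  and will be called ambiguous rather than resolved.
* Multiple cheB/cheR near one cheA are not adjudicated (such conflicts
  require manual curation); `extract_neighborhood()` hands back everything
  in the window.
* Structure mapping of differential CheY positions onto the CheA P1/P2
  interface is consumed as an annotation file, never computed from 3D
  coordinates.
* Chemosensory class labels and heptad classes are inputs (from upstream
  HMM pipelines), never recomputed.
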