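---
title: "Methods: DSI reconstruction, phantom design and statistical pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DSI reconstruction, phantom design and statistical pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsitract)
```

This vignette documents the models, the numerical choices and the synthetic
study design behind `dsitract`, in enough detail that every default can be
judged and every deviation from textbook formulations is visible.

## The q-space encoding scheme

Diffusion spectrum imaging samples the diffusion signal on a Cartesian grid
in q-space. The scheme used here has twelve weighted shells —
(b, number of directions) = 154/6, 308/12, 462/8, 615/6, 769/24, 923/24,
1231/12, 1384/30, 1538/24, 1692/24, 1846/8, 2000/24 s/mm² — plus one
unweighted measurement, 203 encoding points in total. These counts are
exactly the numbers of integer lattice sites at squared radii
r² ∈ {1..6, 8..13} (r² = 7 has no three-square representation), so the
scheme is reconstructed as *all* lattice sites in the ball of radius √13,
with the printed b-values attached shell by shell and directions given by
the normalized lattice vectors. Two consequences:

* The published sum of shell counts is 202; the 203rd point is taken to be
  the b = 0 measurement at the origin — standard DSI practice, and the only
  completion consistent with "grid points in a ball". Whether the original
  scanner table instead duplicated a weighted vector is unknowable from the
  published table; the b = 0 reading is a design decision, not a claim.
* The printed b-values are rounded versions of 2000·r²/13 (e.g. 1384 vs
  1384.6), so regridding by `q/q_max·√13` puts every point within 0.05
  lattice units of an integer site. The b ↔ q map uses the narrow-pulse
  relation `b = (2πq)²(Δ − δ/3)` with Δ/δ = 25/5 ms; it is not printed in
  the protocol but is forced by the q-space formalism once Δ and δ are
  given.

## Propagator and ODF reconstruction

Per voxel the chain is: place the 203 samples on an 11³ grid (half-width
`grid_radius = 5`, zero-padded keyhole; conjugate-symmetric completion
would fill mirror sites for half-ball schemes, and is a no-op for this
full-ball scheme) → radial Hanning window → centered 3D DFT, real part →
radial projection `ψ(u) = Σ_r r² P(r·u)` on 16 radii from 1 native cell to
the native grid edge, trilinear interpolation → gFA.

Three numerical choices deserve emphasis; all three were set by measuring
angular accuracy on noiseless single-fiber and 90°-crossing oracles, where
ground truth is exact:

* **Window support.** The Hanning window tapers to zero at the radius of
  the outermost *sampled* q-space site (√13 lattice units), not at the
  padded grid edge. A window matched to the grid edge under-apodizes the
  data boundary; with it, crossing fibers at 90° were frequently merged
  into single broad peaks, while the data-edge window resolves them
  reliably.
* **Propagator upsampling.** The q-grid is zero-padded threefold before the
  FFT (33³), which samples the same band-limited propagator at 1/3-cell
  spacing. Trilinear interpolation on the native 11³ grid distorted peak
  directions by up to ~20°, twice the tessellation resolution; on the
  upsampled grid the interpolation error becomes negligible. The radial
  projection range stays 1..5 *native* cells: extending radii into the
  padded far field adds r²-amplified truncation ringing and destroys
  orientation accuracy.
* **Fused volume operator.** For whole volumes the linear steps (regrid,
  window, DFT, radial projection) collapse into a single 321 × 203 matrix
  applied to the signal matrix, so reconstruction of a 40×40×20 volume
  takes seconds. The only nonlinearity in the per-voxel chain — clipping
  negative propagator ripple before projection — is thereby skipped; the
  resulting ODFs are clipped at zero instead. On windowed data the ripple
  is small: the unit tests bound the fused-vs-explicit discrepancy (< 5%
  of the ODF maximum pointwise, < 0.03 in gFA, identical argmax).

ODF directions are the vertices of a three-fold subdivided icosahedron
(K = 642, 321 per hemisphere, ~4–5° quantization); ψ is computed on one
hemisphere and mirrored, making antipodal symmetry exact. The 10° peak
tolerances quoted for the orientation-recovery tests follow from this
resolution.

**gFA conventions.** `gfa(ψ) = sd(ψ)/rms(ψ)` uses the population
(divide-by-K) standard deviation, so a one-hot ODF gives √(1 − 1/K) → 1 as
K grows; ψ enters raw (no min-subtraction or normalization), since
rescaling would change the statistic. Degenerate all-zero ODFs are an
error, not a zero.

## Peak extraction

Raw ODFs ride a large isotropic baseline (the r²-weighted projection of
the propagator bulk), so a "30% of global max" floor is vacuous — the
baseline alone exceeds it everywhere. Peaks are therefore strict-enough
local maxima on the tessellation neighbor graph (at least as large as
every neighbor, strictly larger than at least one: symmetric orientations
produce *exact* ties between adjacent vertices, and a purely strict rule
misses such plateau maxima entirely), with the 30% retention floor applied
to the min-subtracted profile (prominence relative to the ODF range), a
greedy minimum separation of 25°, and at most three peaks kept. A constant
ODF yields no peaks.

## The phantom module

The generator voxelizes geometric tubes ("bundles") onto a 40×40×20 grid
at 0.2×0.2×0.5 mm³ (the acquisition resolution; the grid size keeps a full
simulate–reconstruct–track cycle around ten seconds). Each voxel is
supersampled 3³-fold; subvoxel points belong to the nearest enclosing
bundle, giving partial-volume fractions that sum to one with the isotropic
background. The diffusion signal is the multi-tensor forward model
`S(b,g) = S0 Σᵢ fᵢ exp(−b gᵀDᵢg)` with axially symmetric tensors along the
local centerline tangent, followed by Rician noise (magnitude MR): default
SNR 30 on S0, i.e. σ = S0/30.

Scenario geometry (all in mm, deterministic; the seed controls only
noise):

* `healthy` — a single U-shaped bundle: left descending limb, callosal
  arc over the midline, right descending limb; plus one external-capsule
  arc per hemisphere. Bundle tensor λ = (1.7, 0.3, 0.3)×10⁻³ mm²/s,
  background 0.7×10⁻³ mm²/s — typical rodent white/gray-matter values.
* `remodeled` — the right limb displaced rostrally by 1.2 mm (the
  internal-capsule shift), and a periventricular strip: a vertical bundle
  between midline and limb that bends dorsally and merges tangentially
  into the arc. The strip tensor λ = (1.6, 0.35, 0.35)×10⁻³ was chosen
  from the noiseless forward model so the strip gFA (0.24) sits just below
  the bundle level (0.27), reproducing the remodeling-zone vs
  internal-capsule ratio of the in-vivo observations (0.22 vs 0.25) and
  staying above the 0.2 tracking threshold — as the real remodeling zone
  does.
* `severed_bridge` — the remodeled geometry with the arc centerline cut
  within 0.8 mm of the midline; with the 0.45 mm tube radius the material
  gap spans ≥ 3 in-plane voxels, wider than the tracking step.

The BOLD generator applies a boxcar (no hemodynamic convolution — the
analysis is a plain rest-vs-stimulation t-test, so a lagged response would
only calibrate the optional `label_shift` parameter, default 0) with
Gaussian noise. The 5-block paradigm (45 s rest / 15 s stimulation,
trailing 45 s rest) is laid out at 3 s per volume, giving the stated 115
volumes in 345 s; the acquisition TR of 2840 ms is inconsistent with
115 × TR = 326.6 s versus the stated 5 min 45 s total, and the 3 s spacing
is the choice that honors both the repetition count and the total time.

What the phantoms do *not* emulate: susceptibility distortion, motion,
gradient drift, spatially varying noise, fiber dispersion or bottleneck
configurations, gray-matter microstructure. Passing tests therefore
demonstrate correctness of the computational chain under the stated noise
model, not robustness to scanner physics.

## Tractography

Deterministic streamline tracking on precomputed voxel peaks: seeds are
drawn uniformly in the seed mask (voxel uniform, position uniform within
the voxel, fixed RNG seed), both signed senses of the seed voxel's
strongest peak are launched, and each half advances by 0.1 mm steps (half
the in-plane voxel) along the peak best aligned with the previous
direction. A step is accepted iff the new position lies inside the volume
in a voxel with at least one peak, the turn does not exceed the 63° angle
threshold (read as degrees per step; "50.000 seeds" is read with the
European decimal separator as fifty thousand), and the trilinearly
interpolated gFA at the new position is ≥ 0.2. gFA is interpolated but
peaks are nearest-voxel — the usual fidelity/speed balance. `max_steps`
(default 2000) guarantees halting.

Each merged streamline carries one termination reason. The two halves can
terminate differently; the recorded reason prefers interior causes over
volume exit (sharp_turn > low_gfa > no_signal > max_steps >
out_of_volume), since a bidirectional streamline that hits a sharp bend on
one side and the volume boundary on the other is scientifically a
"stopped at the bend" event. Both halves' reasons are retained alongside.

Two seeding strategies mirror the study design: the medial callosal slab
(|x − midline| ≤ 0.8 mm of the bridge) for general white-matter
organization, and the segmented high-gFA strip for the
reorganization-specific question. The interhemispheric count is the number
of streamlines with points strictly on both sides of the midsagittal plane
that also intersect the contralateral hemisphere mask.

## Segmentation and ROI statistics

The in-vivo workflow segmented the perturbation with a hidden-Markov-
random-field EM tool; replicating that binary is out of scope, and a
simpler two-class model is substituted: a two-Gaussian mixture fitted by
EM (`mclust`, unequal variances) on the gFA values inside an anatomical
search slab, falling back to an Otsu threshold if the fit degenerates,
keeping the largest 6-connected component of the high class. A
perturbation is declared only if the two classes are genuinely separated:
Ashman's D ≥ 2 *and* high/low mean ratio ≥ 2. The ratio guard matters
because EM (and, worse, a threshold split) happily cuts a unimodal noise
distribution into two overlapping classes whose D can spuriously exceed 2;
on healthy phantoms the observed ratio stays below ~1.4 while the true
strip gives ~5, so the criterion sits in a wide margin between the two
populations rather than on either's edge.

Homotopic mirroring reflects the ROI across the midsagittal plane in voxel
space (half-integer plane positions supported; reflections leaving the
grid are clipped with a warning; masks straddling the plane are an error).
ROI summaries are mean ± SEM with the sample (n−1) SD and NaN voxels
excluded from n.

Group comparisons use one-way ANOVA followed by all-pairs t-tests with the
pooled ANOVA error variance (df = N − k), Holm-Sidak step-down adjusted:
sorted ascending, `p_(k) → 1 − (1 − p_(k))^(m−k+1)`, running-maximum
monotonicity, decisions at α = 0.05. For two groups the F statistic equals
the squared pooled t. Zero-variance degenerate inputs are defined
explicitly (identical groups → F = 0, no rejections). The between-subject
design of the original study is emulated by simulating N phantom subjects
with per-subject seeds (master seed + index) and running the ANOVA on
per-subject ROI means — animal-level statistics, not voxel pooling.

## BOLD analysis

Voxelwise two-sample t (pooled variance) between stimulation and rest
volumes; percent change is 100·(mean_stim − mean_rest)/mean_rest. Voxels
with zero pooled variance and equal means are NaN-flagged and excluded;
zero variance with different means (the noiseless boxcar) is reported as
an infinite-t surrogate carrying the smallest representable p so it
survives any threshold. An ROI is called active iff it contains a
6-connected cluster of at least 4 voxels (a conventional smallness guard;
the displayed maps in the motivating work state no cluster rule) with
p < α and positive signal change. Voxelwise multiple-testing correction is
not applied by default — the activation call is ROI-level — but the
Holm-Sidak machinery can be applied per ROI by the user.

## Problem sizes and runtime

Defaults were sized so the full test suite (including nine complete
simulate→reconstruct→track cycles at 50,000 seeds and an eight-subject
group comparison) runs in minutes on one core: grid 40×40×20, K = 642
directions, 16 radii, 3× propagator padding. The voxelized geometry is
deterministic per scenario and is cached and shared across noise seeds.

## Known limitations

* Angular resolution is bounded by the b ≤ 2000 keyhole and the 642-vertex
  tessellation; crossings much shallower than 90° are not resolved, and
  peak directions carry ~3–5° quantization error.
* The propagator of slowly decaying signals (low diffusivity relative to
  the sampled q-range) is truncation-broadened; the analytic-Gaussian
  fidelity check in the tests uses free-water diffusivity, where the
  signal is well sampled.
* The EM/Otsu segmentation is a stand-in with a scalar intensity model; it
  has no spatial regularization and will fragment low-contrast
  perturbations.
* Tractography is deterministic and single-peak-per-step; it does not
  model fanning or probabilistic uncertainty, and — like the technique it
  implements — cannot say whether a reconstructed connection is
  functional.
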