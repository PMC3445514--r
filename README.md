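# dsitract

Diffusion spectrum imaging (DSI) reconstruction, deterministic streamline
tractography and block-design BOLD analysis for studying post-stroke
white-matter reorganization — exercised end to end on synthetic fiber
phantoms.

## The problem

After focal cerebral ischemia, the rodent brain can reorganize its white
matter: a zone of elevated diffusion anisotropy appears between the
ipsilesional ventricle and the lesion, the corpus-callosum-to-internal-capsule
junction shifts rostrally, and — in animals that fail to recover
somatosensory function — the transhemispheric callosal connection is lost.
Probing this requires three quantitative tools operating together:

1. **q-space reconstruction.** DSI samples the diffusion signal on a
   Cartesian grid of 203 q-space points (twelve b-value shells from 154 to
   2000 s/mm² plus one unweighted point; Δ/δ = 25/5 ms). Under the
   narrow-pulse relation `b = (2πq)²(Δ − δ/3)`, the 3D Fourier transform of
   the signal gives the displacement propagator `P(r)` per voxel, and the
   radially projected orientation distribution function
   `ψ(u) = Σ_r r² P(r·u)` carries the fiber geometry.
2. **Generalized fractional anisotropy.** `gFA = sd(ψ)/rms(ψ)`, the ODF
   extension of the tensor FA
   `FA = √(3/2)·√Σ(λᵢ − λ̄)² / √Σλᵢ²`; both lie in [0, 1] and are high in
   coherent white matter.
3. **Streamline tractography and fMRI.** Deterministic tracking along ODF
   peaks (gFA threshold 0.2, turning angle 63°, 50,000 seeds) assesses
   structural connectivity; a voxelwise rest-vs-stimulation t-test on a
   5-block forepaw paradigm (45 s rest / 15 s stimulation, 115 volumes)
   assesses function.

No animal data ship with this package. Instead, a first-class phantom module
generates multi-tensor diffusion volumes for three scenarios — `healthy`
(descending bundles joined by a midline callosal bridge), `remodeled`
(rostrally displaced right bundle plus a periventricular strip of
intermediate anisotropy) and `severed_bridge` (the remodeled geometry with
the bridge cut at the midline) — so every stage is testable, reproducible
and fast.

## Worked example

```r
library(dsitract)
report <- run_pipeline(run_config("severed_bridge", n_subjects = 3, seed = 10))
print(report)
```

```
Study report: severed_bridge scenario, 3 subjects (config 51514790 )
 subject       scenario seed gfa_strip gfa_contra gfa_internal_capsule
       1 severed_bridge   11 0.2228339 0.03366308            0.2360264
       2 severed_bridge   12 0.2204653 0.03529689            0.2371327
       3 severed_bridge   13 0.2214055 0.03409501            0.2335863
 interhemispheric_count activation_ipsi activation_contra failed
                      0           FALSE              TRUE  FALSE
                      0           FALSE              TRUE  FALSE
                      0           FALSE              TRUE  FALSE
One-way ANOVA: F(2,6) = 2.092e+04, p = 2.949e-12
            group n       mean          sem
 internal_capsule 3 0.23558181 0.0010476232
            strip 3 0.22156824 0.0006885890
    contralateral 3 0.03435166 0.0004887874
Holm-Sidak pairwise comparisons (alpha = 0.05 ):
           group1        group2         t        p_raw        p_adj reject
 internal_capsule         strip  12.75515 1.425234e-05 1.425234e-05   TRUE
 internal_capsule contralateral 183.15954 1.786992e-12 5.361045e-12   TRUE
            strip contralateral 170.40439 2.755393e-12 5.510703e-12   TRUE
```

Reading the output: each row is one simulated subject (per-subject seed =
master seed + index). The segmented high-gFA strip sits just below the
internal-capsule reference (0.22 vs 0.24) and far above its homotopic
contralateral region (0.03), and all pairwise differences survive the
Holm-Sidak adjustment. Because the callosal bridge is severed, tracking
seeded in the strip finds **zero** interhemispheric streamlines, and the
ipsilesional cortical ROI shows no BOLD activation while the contralesional
one does — the structural and functional signatures of the non-recovering
case. Running the same pipeline with `"healthy"` or `"remodeled"` gives
interhemispheric counts in the tens of thousands and bilateral activation.

A command-line front end with `simulate | reconstruct | track | roistats |
fmri | report` subcommands is installed under `inst/cli/dsitract`; it reads
and writes NIfTI volumes, plain-text b-tables and TrackVis `.trk`
tractograms, e.g.

```sh
inst/cli/dsitract simulate --scenario remodeled --subjects 1 --seed 1 --out sim
inst/cli/dsitract reconstruct --dwi sim/subject_01/dwi.nii.gz \
    --btable sim/scheme.btab --out-prefix rec
inst/cli/dsitract track --odf-prefix rec \
    --seed-mask sim/subject_01/mask_strip.nii.gz --seeds 50000 --out tracts.trk
```

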