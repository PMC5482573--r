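# tomocoat

Desk-scale subtomogram averaging, classification and difference-density
analysis for membrane-coat lattices, written for structural biologists who
want the complete cryo-electron tomography (cryo-ET) workflow — from tilt
series to a sharpened, FSC-validated average — as testable, scriptable R.

The scientific setting is the COPI-type coated vesicle: a sphere decorated
with C3-symmetric **triads**, each built from three copies of the
asymmetric unit (the **leaf**: one coatomer complex plus two Arf1
molecules), with an optional substoichiometric extra density (an ArfGAP
catalytic domain) bound to a subset of leaves. Raw tomograms of real
vesicles cannot ship with a package, so `tomocoat` includes a synthetic
scene generator with complete ground truth, and every stage of the pipeline
is validated against that truth.

## What is implemented

* **Synthetic scenes** — Gaussian-blob leaf phantoms on spherical
  membranes, C3 triads with membrane-normal axes, seeded and
  bit-reproducible; per-leaf ground-truth positions, poses and GAP labels
  (`phantom_spec()`, `build_vesicle_scene()`, `gap_assignment()`).
* **Acquisition simulation** — dose-symmetric tilt scheme (±60° in 3°
  steps), CTF (300 kV, underfocus −2..−5 µm), exposure-dependent dose
  filtering with the critical-exposure curve `Ne(k) = 0.245 k^-1.665 +
  2.81`, phase-flip CTF correction, ramp-weighted back-projection
  (`dose_symmetric_order()`, `project_scene()`, `dose_filter()`,
  `ctf_correct()`, `reconstruct_wbp()`, `wedge_mask()`).
* **Averaging engine** — missing-wedge constrained cross-correlation,
  hierarchical cone + in-plane rotation search with FFT translation,
  wedge-compensated averaging, Cn symmetrization, leaf-level expansion of
  triads, iterative refinement with a low-pass schedule (55/35/16 Å
  defaults), cc-threshold cleaning and distance deduplication
  (`constrained_cc()`, `align_particle()`, `iterate_alignment()`, ...).
* **Validation** — vesicle-level odd/even half-set splitting, gold-standard
  FSC with resolution at the 0.143 (or any) criterion, floating-window
  local resolution, B-factor sharpening (−1400 Å² default), soft masks and
  local masked refinement with map recombination.
* **Classification & difference density** — two-class multireference
  classification (3 iterations) for localizing substoichiometric ligands,
  molmap-style model density (σ = 0.225 × resolution, integral = mass),
  least-squares-scaled difference maps, connected-component segmentation
  ranked by volume, rigid-body fitting, strict below-35 Å cross-link
  screening, and the extended-linker length estimate
  (103 residues × 3.6 Å ≈ 370 Å).
* **Lattice linkages** — neighbor-pair relative poses and agglomerative
  clustering into linkage classes under a symmetrized rotation+translation
  metric.

The model at the core of the averaging is the constrained correlation

```
cc = Re Σ W² F₁F₂*  /  sqrt(Σ W²|F₁|² · Σ W²|F₂|²),   W = W₁W₂B,
```

computed over the intersection of the particle and reference wedges with an
optional band-pass, and the wedge-compensated average
`F_avg = Σ Wᵢ Fᵢ / max(Σ Wᵢ, 0.1 N)` over particles rotated back into the
reference frame. See the vignette (`vignettes/subtomogram-averaging.Rmd`)
for the full account of models, parameters and design decisions.

## Worked example

A two-vesicle scene, 41-tilt acquisition, reconstruction and two fully
independent half-set refinements:

```r
library(tomocoat)
res <- run_pipeline(list(
  seed = 1, output = "demo_run",
  scene = list(triads_per_vesicle = 3, min_separation_deg = 60),
  acquisition = list(noise_sigma = 0.2),
  alignment = list(cone_deg = c(10, 8), cone_step = c(10, 4),
                   inplane_range = c(180, 10), inplane_step = c(45, 5),
                   max_iterations = 2)
))
#> scene: 18 leaves on 2 vesicle(s)
#> reconstructed 112^3 tomogram from 41 tilts
#> picked 46 surface positions (spacing 9.2 vox)
#> half 1: 6 triads kept (18 leaves), mean cc 0.610
#> half 2: 5 triads kept (15 leaves), mean cc 0.610
#> FSC 0.143 resolution: 8.8 A
```

The printed resolution is the gold-standard FSC 0.143 crossing between the
two half-set averages (8.8 Å here, against a 8 Å Nyquist limit at
4 Å/voxel — the phantom is smooth, so the half maps agree almost to the
grid limit). `demo_run/` contains the tomogram, per-half references and
particle tables, the FSC curve (TSV), the sharpened map and a JSON run log
with every parameter and file checksum.

Pose-recovery against ground truth at realistic noise (SNR 0.3, ±60°
wedge):

```r
r <- leaf_recovery_study(n = 50, snr = 0.3, seed = 1)
#> median angular error: 2.55 deg (finest step 2.5 deg)
#> median shift error: 0.32 voxels
```

i.e. the hierarchical search recovers orientations to about one angular
grid step and positions to a fraction of a voxel.

A shell entry point wrapping the same pipeline is installed at
`inst/scripts/tomocoat` (`tomocoat run-all --config run.yaml --seed 1`).

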