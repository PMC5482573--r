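---
title: "Subtomogram averaging of synthetic coated vesicles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtomogram averaging of synthetic coated vesicles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`tomocoat` is a desk-scale re-implementation of the cryo-electron tomography
workflow used to solve membrane-coat lattice structures such as the COPI
coat: dose-symmetric tilt-series acquisition, exposure-dependent dose
filtering, CTF handling, weighted back-projection, missing-wedge-aware
subtomogram averaging with gold-standard half-set validation, multireference
classification for substoichiometric ligands (the ArfGAP-binding problem),
and model-versus-map difference-density analysis. Because raw tomographic
data of real coated vesicles cannot ship with an R package, the pipeline is
exercised end to end on synthetic coated-vesicle scenes generated by the
package itself, with full ground truth for every particle. The purpose of
the synthetic scenes is falsifiability: every downstream claim (pose
recovery, resolution behaviour, classification accuracy) is tested against
known truth.

# The forward model

## The leaf phantom

The asymmetric unit of the coat — the *leaf*, one coatomer complex plus two
Arf1 molecules — is modelled as a sum of isotropic 3D Gaussians:

$$\rho(\mathbf{x}) = \sum_b w_b \exp\left(-\frac{\lVert \mathbf{x} -
\mathbf{c}_b \rVert^2}{2\sigma_b^2}\right)$$

with blob centers $\mathbf{c}_b$ in Angstrom in the leaf frame (z = outward
membrane normal, origin on the membrane at the triad axis), widths
$\sigma_b$ of 5–7 Å and unitless peak weights $w_b$. The default layout
uses ten blobs spreading up to ~45 Å laterally and ~45 Å above the
membrane. Two properties of the layout matter and are tested:

* **asymmetry** — no nontrivial rotation maps the layout onto itself, so a
  particle's pose is identifiable;
* **long internal lever arms** — the blobs spread far from their common
  centroid. With a compact layout, a small rotation about the box center is
  almost exactly absorbed by a compensating translation (the cross-
  correlation landscape becomes degenerate along coupled rotation-shift
  directions), and pose recovery is ill-conditioned no matter how good the
  optimizer. This is a property of smooth blob models, not of the search.

A C3 *triad* is three leaves relatedby 120° rotations about the membrane
normal. An optional extra "GAP" blob (default: 6 Å wide, weight 0.8, near
the triad-proximal Arf1 site) stands in for the catalytic domain of an
ArfGAP bound to a subset of leaves.

## Scenes, acquisition, reconstruction

`build_vesicle_scene()` places spherical membrane shells (Gaussian radial
profile) in a cubic volume and decorates each with triads at rejection-
sampled directions separated by at least `min_separation_deg` (default 55°,
a desk-scale surface density; the true lattice spacing of a crowded coat is
denser but would require much larger boxes). Leaf axes are membrane-normal
by default with an optional tilt jitter. All randomness flows from one
integer seed through a locally scoped RNG.

`project_scene()` produces parallel-beam projections about the grid Y axis
at the tilt angles of `dose_symmetric_order()` (0, +3, −3, −6, +6, … up to
±60° by default), multiplies each image's spectrum by a standard CTF
(300 kV, Cs 2.7 mm, amplitude contrast 0.07, defocus drawn from −5..−2 µm,
underfocus-negative convention) and adds white noise. The total exposure
(default 85 e/Å²) is spread uniformly over the tilts in acquisition order;
`dose_filter()` attenuates each image by $\exp(-N/2N_e(k))$ with the
critical-exposure curve $N_e(k) = 0.245\,k^{-1.665} + 2.81$. CTF correction
is whole-image phase flipping: at these scene sizes the defocus gradient
across a tilted image is negligible, so strip-wise correction would change
nothing (a documented simplification). `reconstruct_wbp()` ramp-filters
along the axis perpendicular to the tilt axis and back-projects with
bilinear sampling in C++.

# The averaging engine

## Constrained cross-correlation

All scoring uses Fourier-space correlation restricted to the sampled region:
with particle wedge $W_1$, reference wedge $W_2$ and optional band-pass $B$,
$W = W_1 W_2 B$ is applied to both transforms and

$$\mathrm{cc} = \frac{\mathrm{Re}\sum_k W^2 F_1 F_2^*}
{\sqrt{\sum_k W^2 |F_1|^2}\sqrt{\sum_k W^2 |F_2|^2}},$$

the DC term excluded. This equals the real-space normalized dot product of
the two wedge-filtered maps (the oracle used in the tests).

## Search

`align_particle()` scans a rotation grid (cone offsets of the symmetry axis
crossed with in-plane offsets; `angular_grid()`) and finds the translation
per rotation at the peak of the FFT cross-correlation volume, restricted to
`shift_limit` voxels, with parabolic sub-voxel refinement.
`iterate_alignment()` runs the schedule: each iteration low-pass filters the
reference (55 Å for the initial external reference, 35 Å during early
iterations, 16 Å for final leaf-level passes are the defaults the field
uses and the pipeline adopts), aligns every particle, forms a new wedge-
compensated average, and applies Cn symmetry. Internally the iteration
pre-rotates each particle once into its current reference frame so that the
rotated-reference FFTs are shared by all particles; resampling uses
tricubic (Catmull-Rom) interpolation, which measurably reduces the
rotation-dependent interpolation ripple that otherwise biases the score on
smooth maps. Convergence is declared when the median angular change falls
below half the current angular step and the median shift change below
0.5 voxel (the printed criterion is "until convergence"; these numbers are
this package's operationalization, capped at `max_iterations`).

## Averaging, cleaning, deduplication

`average_particles()` accumulates $\sum_i W_i F_i$ over particles
back-rotated into the reference frame, dividing by the summed rotated wedge
coverage floored at $0.1N$ (to avoid amplifying frequencies seen by almost
no particle); uncovered frequencies are zeroed. `clean_by_cc()` removes
misaligned particles at an absolute or mean−k·SD threshold (default
mean−2SD; the source workflow does not print its threshold).
`remove_duplicates()` is greedy by descending cc with a strict
`min_distance` exclusion (default 0.8× the expected lattice spacing).

## Gold standard

`split_halves()` assigns odd-numbered vesicles to half-set 1 and even to
half-set 2; the pipeline processes the halves fully independently and reads
resolution from the masked FSC of the two half maps at the 0.143 criterion
(`fsc()`, `resolution_at()`, linear interpolation between 1-voxel shells;
shells with zero power in either map carry no information and are excluded
from the crossing search). `local_resolution()` repeats the FSC in a
soft-edged floating window (default 20 voxels, step 4): small windows have
few Fourier samples per shell, so per-window estimates are noisy — the
window must be several times the voxel size for the map to be meaningful.
`bfactor_sharpen()` applies $\exp(-Bk^2/4)$ (B = −1400 Å² is the
pipeline default) followed by a low-pass at the measured resolution; without
the post-filter a strongly negative B amplifies frequencies beyond the
resolution limit, and at extreme dynamic range (B·k² ≫ 100) double
precision itself becomes limiting.

# Classification and difference density

`multireference_classify()` aligns every particle against each reference
and assigns it to the argmax constrained cc (ties to the lowest index);
class averages are re-formed and the cycle repeated (default 2 classes ×
3 iterations). The study helper `gap_classification_study()` mirrors the
ligand-localization experiment: references are averages of independently
simulated "dataset" and "control" samples, the dataset reference carrying
the dataset's own GAP occupancy — for the null study (no GAP anywhere) both
references are therefore GAP-free and the classifier splits on noise, as it
should. The class-difference map is segmented and the largest component
compared against the planted blob position; a label-permutation control
(max over 20 permutations, a ~95% null bound) calibrates how large a
noise component can be. Two caveats of this null deserve emphasis. First,
maps destined for differencing must have matched missing-wedge coverage:
the seeding reference pair is built from samples sharing one orientation
set (same poses, independent noise), because a coverage mismatch leaves a
structured residual in the reference difference that the classifier locks
onto. Second, iterated multireference classification is self-reinforcing —
each round replaces the references with the class averages, so an initial
noise-driven split is amplified. On GAP-free data the observed largest
class-difference component therefore exceeds the permutation maximum for
roughly one random seed in five; this is an intrinsic property of
unsupervised classification on pure noise, and the permutation control
should be read as a calibration aid, not an exact test. Class differences between noisy averages are
segmented at 3σ of the difference map: at 1σ the suprathreshold set of a
noise-dominated map percolates into system-spanning components and the
"largest component" statistic stops being informative. Model-versus-map
difference maps (`difference_map()`, near noise-free) keep the 1σ default
of `segment_extra_densities()`.

`simulate_model_density()` renders atoms as Gaussians with
$\sigma = 0.225 \times$ resolution and integral equal to the atomic mass
(the molmap convention); `difference_map()` subtracts the model after
least-squares amplitude scaling over the mask (the scaling is this
package's explicit choice — the source workflow does not state one).
`crosslink_distances()` applies the strict below-35 Å criterion;
`max_linker_extension()` is the n·3.6 Å/residue contour-length estimate
(103 residues → 370.8 ≈ 370 Å).

# Lattice linkages

`neighbor_pairs()` enumerates particle pairs below a center-distance cutoff
with relative poses; `cluster_linkages()` groups them by average-linkage
agglomeration under a symmetrized metric (rotation geodesic in degrees
plus translation in voxels, 1° ≡ 1 voxel by default; each unordered pair
is scored in both traversal directions and the smaller distance used). The
four specific linkage geometries of the real coat come from prior work and
are deliberately not re-derived; the module's claim is generic planted-class
recovery, which the tests verify on synthetic lattices.

# Study conditions and problem sizes

The packaged studies run at sizes a laptop handles in minutes, chosen once
as the package's desk-scale study conditions:

* pose recovery: 200 leaves per seed, 5 seeds, 32³ boxes at 4 Å/voxel,
  ±60° wedge, SNR 0.3 (variance ratio after wedge filtering), hierarchical
  schedule 10°/5° then two 5°/2.5° passes (finest step 2.5°), shift limit
  3 voxels. Initial poses are the truth perturbed by ≤6° cone and ≤5°
  in-plane, emulating hand-off from a coarser preliminary stage. The
  declared acceptance thresholds are a median angular error of at most
  twice the finest step and a median shift error of at most 1 voxel.
* half-set FSC: 100 particles per half at SNR 0.5, resolution read at
  N = 10 and N = 100.
* classification: 60 leaves, GAP fraction 0.65, SNR 0.5, 2 × 3 iterations,
  24-particle seeding references.
* demo pipeline: two vesicles (one odd, one even) of 50 Å radius in a
  112³ box at 4 Å/voxel, 3–4 triads each, 41 tilts.

Study particles are rendered analytically (blobs evaluated at their posed
positions) rather than by resampling a phantom grid: resampling bakes an
orientation-dependent interpolation kernel into the data, which an aligner
can exploit or be biased by, and the analytic forward model removes that
artifact class entirely.

# What the synthetic data does and does not show

The generator reproduces the geometry and information structure of the real
experiment: C3 lattices on spheres, membrane-normal orientations, missing
wedge, dose-dependent band limitation, CTF, vesicle-level half-set
independence, substoichiometric ligand occupancy. It does not attempt
realistic lipid scattering, cargo, bud necks, per-frame motion, fiducial
alignment errors, or the crowding of a complete coat; particle noise is
white, whereas real tomographic noise is coloured by the CTF and detector.
Passing tests therefore demonstrate correctness of the algorithms under a
faithful geometric model, not performance on real micrographs; absolute
resolutions reported by the synthetic studies are properties of the phantom
and have no biological meaning.

# Numerical choices and limitations

* Rotational resampling: trilinear by default, tricubic where scoring
  accuracy matters (alignment); symmetry tests band-limit the map and use
  tricubic, where a ~1% maximum relative error remains — grid interpolation
  does not reach much below that without Fourier-space rotation.
* No phase-randomization correction for mask-induced FSC bias is applied;
  masks used here are soft and generous, but tight-mask resolutions would
  be optimistic.
* The pipeline's per-tilt dose schedule spreads the total dose uniformly in
  acquisition order; real schedules vary per frame.
* Euler convention is ZXZ intrinsic throughout; conversions are round-trip
  tested including gimbal cases.
* Tables are plain data.frames written as TSV (canonical) or STAR; maps are
  MRC2014 mode 2. Configuration files are YAML.
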