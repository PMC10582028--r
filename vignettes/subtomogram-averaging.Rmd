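---
title: "Missing-wedge-aware template matching and subtomogram averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-wedge-aware template matching and subtomogram averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomosta)
```

This vignette is the package's account of its science: the models and
procedures it implements, the conventions it freezes, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open.  It states no
empirical result that the test suite or `scripts/acceptance.R` do not
themselves compute.

## 1. Geometry and conventions

Everything downstream depends on a handful of frozen conventions, all
documented at the interfaces that use them:

* **Axes and centers.** Volumes are column-major with x fastest.  The
  rotation/geometry center of an axis of length `n` is voxel `floor(n/2)`
  (0-based).  The tilt axis is **y**: a stage tilt by θ actively rotates
  the specimen by `R_y(θ)`; the beam stays along z.
* **Euler angles.** `(tdrot, tilt, narot)` in degrees, ZXZ *active*:
  `R = Rz(tdrot) · Rx(tilt) · Rz(narot)`, the triplet convention of the
  plain-text particle tables this package reads and writes.  STAR export
  maps to ZYZ `rot/tilt/psi` through the rotation matrix, so the identity
  orientation exports as all-zero angles; the mapping is round-trip
  tested.
* **Positions.** Internally 0-based; the table dialect on disk is 1-based.
  Conversion happens only at the I/O boundary.
* **Rotation resampling.** Trilinear, with *periodic* sampling, which
  makes every multiple of 90° an exact grid permutation.  Rotation-based
  identities (symmetrization idempotence, rotate-and-compare checks) are
  then exact rather than boundary-polluted; zero-outside sampling remains
  in use where rays genuinely leave the data (projection,
  back-projection).

The orientation grid is a cone search (axis directions on a deterministic
equal-area spiral over the spherical cap of half-angle `cone_range/2` —
`cone_range` is the *full* opening angle, so 360 means the full sphere)
crossed with an in-plane sweep centered on zero.  The spiral is seedless
by construction, so grids are reproducible.  The axis count is
`ceiling(1.2 · cap_area / step²)`, a density at which the empirical
covering radius (checked by a brute-force property test over random
rotations) stays below the sampling step.  Cyclic symmetry collapses the
in-plane range to `360/n` exactly; other groups (octahedral) are reduced
by greedy duplicate removal at half the minimum sampling step, and the
identity orientation is always kept first.

The missing wedge is represented as a Fourier mask built from the tilt
list: each tilt contributes a central section of one Fourier-voxel
thickness normal to `(-sin θ, 0, cos θ)`; the union, optionally smoothed
by a cosine ramp, is the sampled region.  Nyquist bins alias `±n/2`, so
the section distance there is taken as the minimum over both sign
interpretations — this keeps the sampled mask exactly Hermitian, which the
test suite asserts.

## 2. Simulator: the stated world

The generator emulates a dose-symmetric single-axis acquisition of a
volume containing phantom copies at uniform random poses:

* tilt range −45° to +45° in 3° increments (31 images), dose-symmetric
  ordering `0, +3, −3, −6, +6, …` with a branch-group size of 2 (the
  scheme's group size is a parameter, since conventions differ), optional
  high-dose zero-tilt override for hybrid schemes with per-image
  pre-exposure bookkeeping;
* projections as parallel-beam line integrals (real-space ray sampling;
  chosen over Fourier slicing for simplicity and testability — the 0°
  projection equals the z-sum exactly, which anchors the oracle tests);
* optional CTF modulation per image (300 kV, Cs 2.7 mm, amplitude
  contrast 0.07, defocus ~3 µm by default — typical acquisition values)
  and additive white Gaussian noise calibrated to a target SNR defined as
  `var(signal)/var(noise)`;
* phantoms: a torus ("bagel") whose Gaussian tube cross-section puts the
  half-maximum surface exactly on the nominal torus (so voxel counts can
  be checked against `2π²Rr²`), a soft sphere, and an asymmetric
  Gaussian-blob sum; gold beads as solid spheres at 10× phantom density,
  default diameter matching 5 nm colloidal gold at typical pixel sizes.

Not emulated (documented limitation): beam-induced motion, detector MTF,
Poisson counting, thickness-dependent attenuation, dual-axis geometry.  A
green end-to-end test therefore establishes the correctness of the
*computational chain* under a faithful noise/wedge/CTF model — not
robustness to every physical artifact of real acquisitions.

Default fixture values follow the stated world of the workflow being
emulated: ±45°/3° tilts, SNR 0.5 tomograms for picking, 20-degree angular
search for matching, σ-threshold 7 for extraction, 3 classes of which 2
are noise traps, 3 classification iterations.

## 3. Reconstruction

WBP filters each image along x (perpendicular to the tilt axis) with a
ramp `|k|`, optionally Hamming-apodized (the apodization is configurable
since reference implementations differ), and gathers voxel-driven
bilinear samples along each tilt direction.  Because the ramp zeroes every
projection's DC, the volume's DC is undefined; the residual mean left by
discretization is removed explicitly.  Back-projection is linear by
construction, which the suite asserts to 1e-6.

Per-particle reconstruction cuts a window (1.6× box, rounded to an
FFT-friendly size) around the particle's tilt-projected location, applies
optional phase flipping at the height-aware per-particle defocus, ramp
filters, and back-projects with the sub-pixel window offsets.  Interior
particles reproduce the corresponding crop of a full-volume
reconstruction (correlation > 0.99 in the acceptance suite), which is the
storage-saving contract: unbinned tomograms never need to exist.
Particles whose windows leave any image are skipped with a message, not
an error — robust batch behavior.

Fourier-crop binning keeps the centered low-frequency block, preserving
the mean exactly and composing multiplicatively (bin2 of bin4 equals
bin8).  Denoising is the scalar Perona–Malik edge-stopping diffusion
(conductivity `1/(1+(|∇|/κ)²)`, conservative fluxes, `dt ≤ 0.15` enforced
for 3D stability) — deliberately the basic scalar variant, not a full
tensor-driven scheme.

## 4. CTF

The contrast factor is `−sqrt(1−A²)·sin χ − A·cos χ` with
`χ = πλf²Δz − (π/2)Cs λ³f⁴ + φ`, positive defocus meaning underfocus;
negative logged values are normalized with a message.  Phase flipping
inverts the Fourier components whose CTF sign differs from the
*first-band* sign.  This choice needs a note: inverting literally
wherever the CTF is negative would flip an entire image whose first zero
lies beyond Nyquist (the CTF is negative from DC onward in this sign
convention), so the band-relative rule is used — it leaves data below the
first zero untouched, conserves spectral power exactly, and is idempotent.
The corrected image then keeps the underfocus first-band polarity
(density-negative); the pipeline's CTF step multiplies by −1 afterwards so
tomograms correlate positively with density templates.

Tilted images are corrected in strips (default 256 px, 50% overlap,
cosine blending) with the defocus gradient
`Δz(x) = Δz + handedness · x_offset · pixel · tan θ`.  The handedness sign
is dataset-dependent in practice, so it is an explicit ±1 parameter,
never guessed.  The internal defocus estimator is a 1D rotational-average
grid search (no astigmatism): radially averaged power spectrum, low-order
polynomial background removal on the log scale, correlation against the
model CTF²; a fit score below 0.3 flags the estimate unreliable, which a
null test on CTF-free noise exercises.

## 5. The matching engine

For each grid orientation the template is rotated, wedge-filtered in
Fourier space (after rotation — the wedge is fixed in the tomogram frame),
mask-weighted, mean-freed and energy-normalized; correlation against the
tomogram uses fast local normalization with the mask-windowed sums of the
data and its square obtained from two convolutions computed once.  The
spherical mask is rotation-invariant, so the local statistics do not
depend on orientation; the variance denominator is floored at
`1e-6 ×` the global variance, and degenerate (constant) regions score
exactly 0, never NaN.  Correlations for two orientations are packed into
the real and imaginary lanes of a single complex FFT, halving the
dominant cost; the FFT itself is a lane-batched single-precision
mixed-radix Stockham transform written for this engine (sizes must be
13-smooth; volumes are padded with their mean otherwise).

Chunked execution uses an overlap of one template box and periodic
continuation of the full volume at chunk borders, so chunk interiors see
exactly the data the whole-volume circular computation sees; an axis fully
covered by a chunk is processed without a halo so even the wrap topology
matches.  The acceptance suite bounds the chunked-vs-unchunked difference
at 1e-5, which in practice is float roundoff (~1e-6).

Peak extraction computes the map statistics once, then greedily takes
descending-CC maxima with spherical non-maximum suppression until the
σ-threshold or the particle cap is hit; ties resolve to the lowest linear
voxel index.  Large suprathreshold islands (membranes, edges) can be
zeroed beforehand; the island size bound is a tuning knob with no
canonical value, defaulting to off in the pipeline configuration.  Gold
beads are erased by matched-filter detection (either polarity) and
local-background replacement; grid edges by largest border-touching
low-intensity component; image borders by cosine tapering to the mean,
bit-identical inside the band.

## 6. Classification, averaging, resolution

Constrained alignment correlates the rotated, wedge-filtered,
mask-weighted reference against the particle over a translation window
(default grid: 15°/45° cone and in-plane around the current pose;
parabolic sub-voxel peak interpolation clamped to the shift limit).  The
correlation is normalized per shift by the particle energy under the
shifted mask window, so an exact displaced copy scores exactly 1 at its
true shift — fixed-window normalization would bias peaks toward zero
shift by mask clipping.

Multi-reference classification assigns each particle to its
best-correlating reference each iteration and recomputes non-noise class
averages by wedge-compensated averaging,
`Σ F(aligned_i) / max(Σ W_i, 0.01·max)`; the denominator floor prevents
missing-wedge noise amplification.  Noise traps — Gaussian noise shaped
to the template's spectral envelope and in-mask amplitude — are kept
fixed across iterations by default (stable false-positive sinks;
regeneration is optional).  Recomputed class averages are low-pass
filtered between iterations (default 0.3× Nyquist, matching the trap and
template band): an average that kept its members' noise would attract
those members back by self-correlation, the classic MRA overfitting
mode.

Half-sets split even-odd by table row parity (deterministic; a seeded
random mode exists), after final class selection.  FSC uses 1-voxel
shells, an optional soft mask (5-voxel cosine edge, no phase-randomized
mask correction — out of scope and documented as such), and linear
interpolation to the 0.143 crossing, reporting `N·a/s*` in Angstrom or
the Nyquist bound flagged "not crossed".

## 7. Pipeline engine

Modules execute in configuration order, one folder per module, one
subfolder per item.  `SUCCESS` markers are written atomically
(write-then-rename) per item and globally per module; a re-run skips
marked items, deleting a global marker re-executes its module, and one
item's failure is recorded (with a `FAILURE` file) without aborting
siblings.  Configurations merge as *module defaults < general section <
user module section*, validated in full before anything runs — unknown
modules, unknown keys and type mismatches fail fast because unattended
runs are the point.  "Unset" optional parameters use numeric sentinels
(0) rather than JSON nulls, which R list semantics would silently drop.

Live mode polls a watch directory, closes a series when it reaches the
expected image count or when no file has arrived within the timeout
(per-series inactivity semantics; the threshold definition is ambiguous
in general, so this choice is documented), and reconstructs it through
the simplified path: Fourier-crop binning and WBP only, no motion or CTF
steps.

## 8. Numerical choices and known limitations

* Single-precision FFT in the matching/alignment cores only; all other
  spectral operations use R's double-precision FFT.  Normalization
  accumulations run in double.
* The feasibility pre-check of particle placement is deliberately coarse
  (exclusion volumes overlap, spill over borders and are clipped by thin
  slabs); the bounded-attempts error is the authoritative guard.
* The torus phantom is continuously symmetric about its axis, so
  orientation recovery for it is meaningful only as axis agreement; the
  acceptance scoring does exactly that.
* Global-drift motion correction, fiducial tilt-series alignment,
  astigmatism, dose weighting, GPU execution and external refinement
  packages are out of scope; the simulator emits aligned stacks.
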