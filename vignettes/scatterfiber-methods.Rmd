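---
title: "Methods: scattering-based fiber orientation analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scattering-based fiber orientation analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterfiber)
```

## The measurement model

Myelinated axons scatter both visible light (SLI) and X-rays (SAXS)
predominantly perpendicular to their in-plane axis. For each image pixel
the measurement is reduced to a *cyclic azimuthal profile* I(φ) on an
equally spaced grid over [0°, 360°):

* **Angular SLI**: the 24-slice intensity series of a pixel, one slice
  per illumination azimuth (15° steps at fixed polar angle θ = 45°), is
  the profile itself — no resampling.
* **SLI scatterometry**: a full scattering pattern per pixel, assembled
  from an 80 × 80 illumination grid; the profile sums the pattern over
  1° segments about the pattern center (the intensity argmax, ties
  towards the smallest row then column), each pixel counted once.
* **SAXS**: detector intensities with |q| inside a band around the
  myelin Bragg ring are summed in 5° segments about the beam center.
  Missing segments (detector gaps) are reconstructed from the pattern's
  center-symmetry: antipodal bins are averaged when both are valid and
  copied when only one is.
* **FOD**: a band-limited (even degrees, ℓmax = 8) real
  spherical-harmonic density sampled at 5° steps on the circle of unit
  directions in the section plane; antipodal symmetry makes the profile
  exactly 180°-periodic.

An in-plane fiber bundle at axial orientation φ appears as two profile
peaks at φ ± 90°. With out-of-plane inclination α the two SLI peaks
approach each other with separation Δ(α) < 180°, while SAXS peaks stay
180° apart but lose contrast. FOD profiles peak *along* the fiber, not
perpendicular to it, which the pairing step accounts for.

## Peak analysis

Peaks are cyclic local maxima (plateaus count once, at their center).
The *prominence* of a peak is the vertical distance between its top and
the higher of the two neighboring minima; only peaks with prominence
above 8% of the profile amplitude (max − min over valid bins) are
retained — this is the threshold the SLIX-style analysis uses to
suppress noise bumps, and it makes the decision scale-invariant. Widths
are measured at (height − prominence/2) with linear interpolation
between bins. Single-bin peak positions are refined with a 3-point
parabolic fit; on the 15° grid of angular SLI this carries the in-plane
accuracy below 1° for noiseless von Mises lobes (the residual is the
parabola/von-Mises shape mismatch, largest mid-bin).

Orientations come from pairing peaks whose cyclic separation lies in
180° ± 35°; each pair contributes the circular mid-position mod 180°
(plus 90° in FOD mode). With more than two peaks, all pairings are
enumerated; the one maximizing the number of pairs wins, tie-broken by
minimal total deviation from 180°. Leftover peaks yield no orientation —
profiles with an odd number of dominant peaks are not interpretable
without neighborhood context, so a three-peak pixel reports nothing
rather than guessing. At most three orientations are kept, ranked by
summed pair prominence.

The *peak distance* Δ is reported for pixels with at most two peaks
(one peak → Δ = 0, more than two → absent), and is converted to an
inclination estimate by inverse interpolation of a calibration curve.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `prominence_frac` | 0.08 | relative prominence threshold |
| `pair_tol_deg` | 35° | pairing tolerance around 180° |
| `n_azimuths` | 24 | SLI illumination azimuths (15° bins) |
| `bin_width_deg` (SAXS/FOD) | 5° | azimuthal segment width |
| `kappa` | 20 | von Mises lobe concentration of the forward model |
| `baseline` | 0.1 | isotropic background of the forward model |
| `noise_sd_frac` | 0.01 | Gaussian noise sd as fraction of dynamic range |
| calibration curve | 180·cos α | stand-in Δ(α), pluggable CSV |

`single_peak_orientation` (off by default) assigns `(peak + 90°) mod
180°` to one-peak pixels as a low-confidence orientation. This rule
presumes the lone peak is one of a perpendicular pair whose partner was
suppressed; it is *not* meaningful for the merged single lobe of a
near-through-plane fiber, which lies along the fiber's tilt azimuth —
hence the conservative default.

## The synthetic phantom generator

The generator is the package's ground truth. A phantom is a pixel grid
tiled by rectangular regions, each carrying up to three fiber
populations (φ, α, weight), emulating the configurations of a coronal
section: a unidirectional in-plane band (corpus-callosum-like), in-plane
crossings (corona-radiata-like), and inclined bundles (fornix- and
cingulum-like). Forward models:

* **SLI**: per population, two von Mises lobes (period 360°,
  concentration κ = 20, FWHM ≈ 31°, comparable to measured SLI peak
  widths and narrow enough that a 47° pair — α = 75° under the stand-in
  curve — remains resolvable on the 15° grid) centered at c ± Δ(α)/2
  with c = φ + 180° towards the population's tilt azimuth (a per-
  population sign flag selects the other side; for α = 0 the two
  choices coincide, and the lobe pair's mid-position equals φ).
* **SAXS**: an isotropic Gaussian ring at q = 2π/d (d = 17.5 nm by
  default) modulated by 180°-periodic von Mises lobes perpendicular to
  φ, with contrast decaying as cos α — a monotone stand-in for the
  qualitative "less pronounced with inclination"; the pattern is
  center-symmetric by construction.
* **FOD**: a mixture of Watson lobes along each population's 3D axis,
  projected onto the even real spherical-harmonic basis by
  Gauss–Legendre × uniform-azimuth quadrature.

Noise is Gaussian with σ = 1% of the noiseless dynamic range by default
(or Poisson at a configurable photon scale), always behind an explicit
seed; rendering is bit-reproducible and changing only the seed changes
only the noise realization.

What the phantoms do *not* emulate: optical point-spread and detector
flat-field effects, spatially varying baselines, partial-volume mixing
at region boundaries, non-linear section deformation, and the true
(simulated-optics) Δ(α) relation — the shipped 180·cos α curve has the
correct endpoints and monotonicity but not the measured shape, and is
pluggable precisely so a tabulated curve can replace it. Passing the
synthetic suite therefore demonstrates the correctness of the
*analysis* (peak logic, pairing, statistics, bookkeeping), not the
fidelity of any instrument model.

## Numerical choices

* Azimuths are measured from the +column axis towards the +row axis;
  pixels exactly on a segment edge go to the lower segment; the pattern
  center pixel has no azimuth and is excluded from SLI integration.
* Signed axial differences use the closed form ((a − b + 90) mod 180) −
  90, mapping exact ±90° to −90°.
* Sub-bin refinement offsets are clamped to ±half a bin; plateau peaks
  take the plateau center and skip the parabola.
* Inverse calibration on a flat curve segment returns the segment's
  midpoint inclination with a warning; out-of-range peak distances are
  an error, not clamped.
* Radial ring detection requires the most prominent interior maximum to
  exceed 5% of the radial range; flat patterns raise a ring-not-found
  error.
* Profiles with fewer than 8 valid bins are rejected; invalid bins
  interrupt peak neighborhoods and drop the affected peaks.
* The 8% amplitude reference uses valid bins only.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: an
exhaustive brute-force peak finder (explicit walk to neighboring
minima) on profiles up to 48 bins; an exhaustive-partition pairing
oracle; a spherical-harmonic basis built from an independent associated-
Legendre implementation; and closed-form FA/axial-difference cases.
Property tests cover shift equivariance, scale invariance, rotation
equivariance, conservation of azimuthal integration, idempotence of
center-symmetry completion, and invariance of map comparison under
joint rotation.

End-to-end recovery runs on a 64 × 64 phantom (unidirectional band plus
a 60° crossing, 24 azimuths, 1% Gaussian noise): every pixel is matched
and the maximum absolute in-plane error stays within the 2.4° accuracy
reported for SLI. The inclination analysis uses a six-band ramp
(α = 0°…75° in 15° steps): recovered peak distances decrease
monotonically and stay within two azimuth bins of the generator's
calibration curve. These sizes keep the whole suite in seconds on one
CPU while exercising every pixel class.

The cross-modality benchmark statistics printed for the brain-section
study (median absolute differences of a few degrees, the ~104% increase
of multi-orientation voxels in dMRI versus SAXS) require the deposited
full-resolution parameter maps; the corresponding acceptance check
reports their absence explicitly rather than passing vacuously.

## Known limitations

* Inclination from peak distance is ill-conditioned above α ≈ 60°
  (broad, low-contrast peaks); no error model is attached to Δ.
* Crossing pixels get no inclination estimate (the unidirectional
  filter excludes them, mirroring the study's evaluation rule).
* Registration between modalities is out of scope: maps must be
  co-registered externally, with only a global rotation angle applied
  to the angles.
* Phantom regions are rectangles; arbitrary polygonal layouts can be
  composed from multiple rectangles but curved boundaries cannot.
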