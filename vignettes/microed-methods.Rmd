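---
title: "Converting and calibrating continuous-rotation electron diffraction data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting and calibrating continuous-rotation electron diffraction data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microed)
```

## The problem this package addresses

Micro-electron diffraction (MicroED) collects crystallographic data from
sub-micrometre 3-D crystals in a transmission electron microscope.  In the
continuous-rotation mode the stage turns at a constant rate while the camera
reads out shutterlessly at fixed intervals, so each frame integrates a small
oscillation wedge of reciprocal space.  The camera stream, however, knows
nothing about the experiment: the files carry pixels, not geometry.  Before
any standard crystallographic integration package (DIALS, MOSFLM, XDS) can
process the sweep, someone must

* attach the full experimental geometry to every frame — wavelength, virtual
  sample–detector distance, beam centre, pixel size, and the oscillation
  start and range of that exposure — and write the result in a format those
  packages read (SMV: a fixed-length ASCII header plus unsigned 16-bit
  pixels);
* calibrate the quantities the instrument does not report: the detector gain,
  the positions of malfunctioning pixels, the true beam centre, and the
  effective camera length;
* judge quickly whether a sweep is worth processing at all.

`microed` implements that conversion and calibration layer, plus a synthetic
diffraction simulator with exhaustive ground truth so that every stage is
testable without instrument data.  Indexing, integration, scaling and
refinement are deliberately out of scope: they belong to the downstream
packages the SMV output feeds.

## Geometry model

**Wavelength.**  Electrons accelerated through a potential $V$ have the
relativistic de Broglie wavelength

$$\lambda = \frac{h}{\sqrt{2 m_e e V\,(1 + eV/2m_ec^2)}},$$

evaluated with CODATA constants: 0.0251 Å at 200 kV, 0.0197 Å at 300 kV
(conventionally quoted as 0.025 and 0.020).  The full-precision value is
kept internally; rounding is display-only.

**Rotation.**  A frame exposed at timestamp $t$ (relative to the sweep
start) with exposure $\Delta t$ under signed rate $R$ covers the oscillation
$[\,\varphi_0 + Rt,\ \varphi_0 + Rt + R\Delta t\,]$.  Timestamps are taken
as authoritative when the acquisition stream provides them; otherwise they
are reconstructed as $i\,(\Delta t + g)$ with $g$ the detector read-out gap.
Reconstruction lets any error in $R$ compound over the sweep, which is why
measured timestamps win when available.  The sign of $R$ is physically
meaningful and hard to recover from the data (the stage tilts both ways and
the short wavelength hides the handedness), so it is a required input with a
`flip_rotation_sign()` escape hatch.  Stills mode ($R = 0$) is represented
explicitly — downstream software must be told the truth rather than being
fed a fake tiny oscillation.

**Detector.**  A pixel at radius $r$ from the beam centre sees scattering
angle $2\theta = \arctan(r/D)$ and resolution $d = \lambda / 2\sin\theta$,
with $D$ the *virtual* sample–detector distance — the camera length of the
lensless-equivalent experiment implied by the post-sample magnification.
`resolution_at_radius()` and `radius_for_resolution()` are exact inverses.

**Tilt-limited completeness.**  The cryo-holder limits the stage to roughly
±70°.  For crystals with a preferred orientation (plates whose unique axis
is normal to the grid) this leaves a missing cone around that axis; assuming
all in-plane rotations are sampled (many crystals at random azimuths), the
observable fraction of reciprocal space is $\sin\alpha$ — 94% at ±70°.
`observable_fraction()` is the closed form; `reciprocal_coverage()` measures
the same number empirically through the simulator's crossing geometry, and
the two agree to within the lattice discreteness of the test crystal.

## Calibration procedures

**Gain** (`estimate_gain`).  After gain correction, integration programs
model detector noise as Poisson, for which variance equals mean.  The gain
is therefore the variance/mean ratio over a large background region.  The
default 1% two-sided trimming guards against stray spots; because symmetric
trimming deflates the variance, the estimate is corrected by the exact
Gaussian truncation factor $1 - 2z\phi(z)/(1-2\alpha)$ (background counts
are high enough for the Gaussian approximation to hold to well under a
percent).  Regions should be chosen beyond the highest-resolution ring —
the detector corners in practice; a constant or zero-mean region is a
classed error, never a silent `NaN`.

**Beam centre** (`refine_beam_center`).  A diffraction pattern is symmetric
under inversion through the direct beam (Friedel symmetry), so the centre is
the point about which the image best correlates with its own 180° rotation.
The autoconvolution identity $\sum_x I(x)\,I(s-x)$ peaks at $s = 2c$, which
scores *every* candidate centre on a half-pixel grid with three FFTs; the
peak is normalised to a true correlation and refined by quadratic
interpolation.  Two caveats are inherent to the method and surfaced rather
than hidden: a featureless image has no symmetry signal (classed
`no_signal` error), and a maximum on the search boundary means the true
centre may lie outside the window (`boundary_warning`).  Combination peaks
of the reciprocal lattice sit half a lattice spacing away from the true
centre and score roughly half as high — they only win if Friedel mates have
unequal intensities, which is why the simulator assigns mates a common
intensity, as physics does.

**Bad pixels** (`detect_bad_pixels`).  The camera does not flag dead, hot
or erratic pixels, but a stack of ≥ 3 frames reveals them through temporal
statistics: per-pixel medians against the detector-wide median and its
robust spread (hot, with an 80% persistence requirement), medians at the
floor while the detector is above it (dead), and temporal spreads exceeding
the Poisson expectation $\sqrt{g\,\tilde{x}}$ from the local signal level
(erratic).  The default threshold of 6 robust standard deviations is
deliberately conservative (the expected false-positive count on a 16 Mpixel
detector is far below one) and exposed in the interface, because such cuts
are inherently ad hoc.  Note that the statistics assume the stack is
background-dominated: run it on a spotless sweep or a dark series, not on
frames with strong Bragg spots, whose rocking profiles mimic erratic
behaviour at the spot positions.

**Camera length** (`fit_powder_rings`, `calibrate_distance`).  $D$ could be
derived from the nominal magnification, but is better calibrated against a
powder pattern of known spacings (gold, graphite).  The radial profile about
the beam centre is detrended with a running median, the strongest peaks are
picked with a minimum separation (gold 111/200 are only ~27 px apart at
typical geometries, which sets the default ridge half-width of 10 px), and
each ring's ridge is traced through 256 azimuthal sectors by per-sector
radial centroiding.  An ellipse is then fitted by direct least squares
(Fitzgibbon); the axis ratio doubles as an astigmatism check.  Each ring
yields $D_i = r_i/\tan(2\arcsin(\lambda/2d_i))$; the reported distance is
the residual-weighted mean, and a per-ring spread above 2% raises a
`calibration_inconsistent` warning, the signature of a wrong d-spacing
assignment.

## Conversion

Binning **sums** factor×factor blocks rather than averaging: downstream
software models gain-corrected counts as Poisson, and averaging would break
the variance/mean relation while discarding recorded quanta.  A pedestal
(default 512 counts, < 1% of the 16-bit range) is added before unsigned
storage so that small negative excursions from the camera's internal dark
subtraction survive the round trip; it is recorded as `IMAGE_PEDESTAL` so
integrators can subtract it.  Clipping at either end is counted and
reported — in the low-dose regime it is expected to be exactly zero.

The SMV header uses fixed decimal formats (4 places for millimetres,
degrees and seconds, 6 for the wavelength) so identical inputs produce
byte-identical files.  `BEAM_CENTER_X/Y` are written in millimetres as
pixel coordinate × pixel size, with a `swap_beam_axes` flag because
downstream packages disagree about the axis dialect; the convention is
documented in the header function rather than guessed.  The `DATE` field
defaults to a fixed placeholder — reproducibility is a property, and the
real acquisition time is metadata the caller can supply.  Oversized headers
are promoted to the next multiple of 512 bytes with `HEADER_BYTES`
updated, per the format's convention.

Raw input arrives as the documented internal stack format (magic,
dimensions, bit depth, frame count, optional timestamp table, concatenated
little-endian frames — a lossless, specified stand-in for proprietary
camera streams), as multi-frame TIFF, or as a minimal MRC subset (modes 1,
2, 6).  Output naming is 1-based and zero-padded to four digits, matching
the `frame_####.img` templates integration packages expect, and a
plain-text manifest records every parameter and per-frame angle.

## Screening

`find_spots` estimates the background from per-tile medians, thresholds
per-pixel significance under the gain-corrected Poisson model, and keeps
connected regions of at least 3 pixels — the size cut is what makes lone
noise excursions (expected at any threshold on a megapixel image)
harmless.  `assess_indexability` operationalises the practical rule that
five to ten images spanning a ~20° wedge support autoindexing without
prior cell knowledge: *sufficient* needs ≥ 5 qualifying frames (≥ 10 spots
each, a deliberately operational default — the literature gives no number)
spanning ≥ 18°; *marginal* means every criterion still passes at 80% of
its threshold; anything else is *insufficient*, with each failing criterion
named.  `extract_rocking_curve` integrates a box around a spot per frame,
subtracts the perimeter-median background (robust to a neighbouring spot's
tail), places each frame at its mid-exposure angle — the choice that makes
the curve exactly equivariant under rotation reversal — and fits a
Gaussian with constant offset, falling back to weighted moments if the fit
degenerates.  A curve confined to one frame reports its width only as
bounded by that frame's oscillation range.

## The simulator and what passing tests mean

The simulator is a geometry oracle, not a physics engine.  Reflections of a
`virtual_crystal` (triclinic-capable Busing–Levy $B$ matrix, orientation
$U$, mosaicity, resolution limit) cross the **flat** Ewald plane at angles
$\varphi^\* = \operatorname{atan2}(-q_z, q_y)$ under rotation about the
tilt axis; at 0.025 Å and 2 Å resolution the sphere's departure from the
plane is far below a pixel, and the flat-wedge approximation is exactly the
geometry the conversion layer assumes.  Each reflection's frame-integrated
intensity follows a Gaussian rocking profile (mosaicity ⊕ bandpass in
quadrature) so that partial intensities over contiguous frames sum to the
full intensity to numerical precision; full intensities are drawn from a
Wilson-like exponential, with Friedel mates sharing one value.  Spots are
rendered as 2-D Gaussians, Poisson noise is applied to signal plus
background, and the result is multiplied by the gain — making
variance/mean equal the gain by construction.  The seed is mandatory;
identical configurations are bit-identical.

One modelling point deserves emphasis: a crystal whose zone axis lies
exactly along the beam puts an entire reciprocal-lattice plane in the
Ewald plane at $\varphi = 0$, and the discrete crossing angles of an
aligned orthorhombic lattice leave degree-wide gaps with no reflections at
all.  Real crystals land on grids in generic orientations; simulations
should too (`axis_angle_rotation()` exists for exactly this), and the
package's test fixtures use a generic orientation throughout.

What the simulator does **not** model — structure factors, dynamical and
diffuse scattering, dose-dependent decay, solvent background structure,
beam-stop shadows — bounds what green tests prove: the package recovers
geometry, gain, defects and intensities *under the stated noise model*.
Recovery on real data additionally depends on effects outside this
package's claims, which is why every estimator also reports a quality
signal (scores, residuals, spreads, flags) instead of a bare number.

## Numerical choices and problem sizes

* Calibration tests run on 256²–512² detectors with 8–40-frame sweeps and
  lysozyme- to small-molecule-scale cells — sizes chosen so the full suite
  exercises every code path in about a minute while leaving estimator
  errors an order of magnitude below their tolerances.
* Gain: 10⁵ background pixels give a ~0.5% standard error on the
  variance/mean statistic; the 5% acceptance band is generous by design.
* Beam centre: the score grid has half-pixel pitch; quadratic interpolation
  brings synthetic recovery to ~0.01 px, against a 0.5 px requirement.
* Ring fitting needs ≥ 8 valid sectors for an ellipse; rings reaching into
  the detector corners are fitted from the arcs that remain, with the
  misfit reported in `residual` and down-weighted in the distance mean.
* Rocking fits start from weighted moments; `nls` refinement is attempted
  and silently abandoned in favour of the moment estimates if the gradient
  degenerates (e.g. near-flat curves).
* All angle interfaces are degrees; right-handed rotation about the stage
  x axis; pixel coordinates are 1-based with x along the fast axis.

## Known limitations

Per-frame gain variation is not modelled (one estimate per sweep by
default).  The bad-pixel statistics assume background-dominated stacks.
The beam-centre score assumes Friedel symmetry holds at least
approximately within a frame — very thick or strongly dynamical samples
weaken it.  Non-affine distortion fields, energy filters and beam-stop
auto-detection are out of scope; beam stops are handled by user-supplied
exclusion masks.
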