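---
title: "Quantifying hemolymph flow in insect wing veins with hemoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemolymph flow in insect wing veins with hemoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

## The measurement problem

Insect wings are living microfluidic devices: hemolymph circulates through
every vein of the wing, entering through the wide leading-edge conduits and
returning to the body through the trailing edge, pulled by accessory
thoracic "wing hearts". Quantifying these flows means tracking neutrally
buoyant fluorescent tracer particles (3 and 6 um polystyrene beads) in
time-lapse fluorescence movies of a restrained insect's wing, recorded at
10--100 frames per second, and converting the recovered trajectories into
per-region hemodynamic statistics.

hemoflow implements the complete measurement chain, plus a synthetic-scene
generator that stands in for the microscope so every stage can be validated
against a known ground truth:

1. **simulate** -- tracer motion through a stylized five-region wing vein
   network with pulsatile, aperiodic and leaky local flow behaviors;
2. **render** -- fluorescence image formation with photobleaching, uneven
   illumination and sensor noise;
3. **detect** -- per-frame particle segmentation via Hessian eigenmaps;
4. **track** -- multi-parametric frame-to-frame linking with a globally
   optimal assignment;
5. **analyze** -- per-trajectory velocity, smoothing, and pulse frequency;
6. **summarize** -- per-region aggregates and the dimensionless numbers
   Pe, Re and Wo.

## Flow quantities

For a trajectory with positions $(x_i, y_i)$ and per-step intervals
$t_i$, the instantaneous speed is

$$V_\mathrm{instant} = \frac{\sqrt{(x_i - x_{i+1})^2 + (y_i - y_{i+1})^2}}{t_i},$$

reported in mm/s. Speed series are smoothed with a centered moving mean of
window 5 whose end windows shrink (the first element of a window-5 mean
averages three elements), and the maximum and median of the smoothed
series characterize each trajectory. By default the extrema are taken on
the smoothed series; `trajectoryKinematics(useSmoothed = FALSE)` switches
to the raw series (the convention is not uniquely determined, so both are
available).

Pulse frequency is estimated by normalizing a speed trace by its maximum
and counting peaks whose *prominence* -- height above the higher of the
two flanking minima -- exceeds 0.3, divided by the observation window.
The 0.3 threshold is the classic peak-detection threshold for this assay;
implementing it as a prominence criterion makes the count robust to slow
baseline drift and suppresses the small secondary arches produced by
partial reversals (a reversal retracing less than 30% of the forward
pulse does not register as an extra pulse).

Per wing region, with mean vein radius $r$ (metres), mean maximum speed
$V_\mathrm{max}$ (m/s) and mean pulse frequency $f$ (Hz):

$$\mathrm{Pe} = \frac{r V_\mathrm{max}}{D_{O_2}}, \qquad
  \mathrm{Re} = \frac{\rho V_\mathrm{max} r}{\mu}, \qquad
  \mathrm{Wo} = r \sqrt{\frac{f \rho}{\mu}}.$$

Hemolymph is treated hydrodynamically as water: $\rho = 1000$ kg/m$^3$,
$\mu = 1.0518 \times 10^{-3}$ Pa s (18 °C), and
$D_{O_2} = 1.8\times 10^{-9}$ m$^2$/s for oxygen diffusing in water. The
diffusion coefficient deserves a note: the conventional tabulated value
is $1.8\times10^{-5}$ cm$^2$/s, which converts to $1.8\times10^{-9}$
m$^2$/s; this is the only reading consistent with the known magnitude of
O$_2$ diffusion in water and with a Péclet number near 1 at wing-tip
scales ($r = 15$ um, $V = 120$ um/s gives Pe $= 1.0$ exactly). The value
is a `fluidConstants()` default and can be overridden.

Dimensionless numbers are computed from region-mean quantities (matching
the "average per region" convention of the assay) rather than averaged
over per-trajectory values; computing them per trajectory and averaging
is possible by calling `peclet()`/`reynolds()`/`womersley()` on the
per-trajectory table directly.

## The synthetic scene generator

The generator exists so that detection, tracking and kinematics can be
scored against an imposed truth. It emulates the features of the real
recordings that stress the measurement chain, and its defaults encode the
study conditions used throughout the tests.

**Geometry.** `buildWingNetwork()` builds a stylized planar graph --
longitudinal veins running base to tip, orthogonal cross veins -- in
physical micrometres. It is *not* a tracing of real venation (no published
coordinates exist); what it preserves is the five-region structure and the
relative vein calibers: leading- and trailing-edge diameters of 170--250
um, strictly narrower tip and lattice veins. Region labels come from the
segment midpoint's position on the normalized region map, so network
geometry and region assignment stay consistent by construction.

**Local flow behaviors.** Each region carries one of three behaviors:

- *pulsatile*: the along-vein velocity is a sequence of forward half-sine
  pulses at `pulseFreqHz`; between pulses the particle stops or retraces a
  fraction `reversalFraction` $< 1$ of the forward pulse distance
  (waveform $v(t) = A\,\sin^+(2\pi f t) - rA\,\sin^-(2\pi f t)$), so net
  transport is always forward. Wing pulsation frequencies of 0.21--0.81 Hz
  are typical; body-side pumping reaches 2.1 Hz.
- *aperiodic*: strictly one-directional motion whose speed modulates
  sinusoidally with depth $< 1$, never reaching zero.
- *leaky*: a prescribed vein-to-sinus-to-vein path -- the particle exits
  its vein at the point nearest the sinus polygon's centroid, transits
  the sinus, and re-enters the nearest bounding vein. The exchange is
  kinematic, not pressure-driven: no membrane permeability is available
  to parameterize a porous-flow model, and the measurement chain only
  needs geometrically plausible out-of-vein trajectories.

**Rendering.** Particles become 2-D Gaussian spots whose integrated
intensity is proportional to particle volume (diameter cubed), with a
spot width combining the optical PSF and the particle's geometric size.
The renderer reproduces the named nuisance processes: per-frame
exponential photobleaching, a smooth low-order polynomial illumination
field (±20% by default, configurable -- the artifacts' magnitudes are
not documented, only their existence), Poisson shot noise and Gaussian
read noise. Pre-noise image formation is linear, and everything is
deterministic under a fixed seed.

**What the generator does not emulate**: vein wall autofluorescence
texture, hemocytes, tracheal shadows and compressions, focus drift, and
3-D motion through the lumen depth. Passing tests therefore demonstrate
correctness of the measurement chain under controlled conditions, not
robustness to every artifact of real microscopy; on real data the
detection thresholds and Canny parameters are the knobs to revisit.

## Detection

Each frame is preprocessed by temporal-median background subtraction
(static structure such as vein walls and the illumination pedestal is the
per-pixel median over up to `backgroundWindow` evenly spaced frames) and
a frame-wise linear intensity adjustment that maps the 99th intensity
percentile to full scale, saturating the top 1% of pixels -- this
compensates photobleaching frame by frame. Two numerical choices matter
here:

- the saturation quantile uses the inverse empirical CDF (quantile
  type 1), which makes the operation exactly idempotent;
- inside `detectParticles()` the rescale gain is capped so the divisor
  never falls below half the frame maximum. On frames where particles
  occupy far less than 1% of the pixels the raw percentile lands on the
  noise floor and would amplify read noise to full scale; the cap keeps
  the brightest structure at or just above full scale instead. On busy
  frames (signal occupying more than the saturation fraction) the cap is
  inactive and the mapping is the pure percentile rescale.

Candidate pixels are marked where the larger eigenvalue $\lambda_2$ of
the Gaussian-smoothed intensity Hessian is negative -- intensity locally
concave in every direction, the interior of a bright blob. The eigenvalue
ordering convention is not universal; here $\lambda_2$ is the *larger*
eigenvalue, so "$\lambda_2 < 0$" means negative-definite. The
`darkBlobs` flag flips the convention in one step.

Segmentation seeds are regional maxima of the smoothed frame inside the
candidate mask, gated by an intensity floor (the larger of an absolute
floor, default 0.2 of full scale, and median + 6 MAD of the smoothed
frame). Both gates exist to satisfy a hard requirement: on pure-noise
frames the detector must produce essentially no output (at most 0.1
false detections per frame), even after the saturation rescale has
amplified the noise. Each seed then grows a region over the pixels whose
intensity is at least `refineFraction` (default 25%) of that seed's peak,
halting at Canny edge pixels; where two seeds compete, pixels belong to
the nearer seed, so touching blobs split at their saddle with exactly one
region per intensity peak. This realizes the dynamic-erosion/dilation
refinement as a seeded constrained growth -- the outcome (one region per
regional maximum, bounded by the 25% level set and by edges) is the
specification; the erosion schedule itself is not observable in the
result.

Canny thresholds are absolute gradient magnitudes (default low 0.08,
high 0.2 per pixel on the [0, 1] scale) rather than fractions of the
frame's maximum gradient: in sparse synthetic frames the strongest
gradient is a particle's own flank, and relative thresholds would make
every isolated spot truncate itself. With absolute thresholds, sharp
structure boundaries (vein walls, saturation rims) fire while the smooth
flank of an unsaturated Gaussian spot stays below threshold. A
full-scale step can produce a discrete central-difference gradient of at
most about 0.3 after unit smoothing, which sets the scale of the
defaults.

Measured features per region: intensity-weighted centroid, pixel area,
equivalent-circle diameter $2\sqrt{A/\pi}$, mean intensity (brightness --
mean rather than integrated, so it is roughly size-invariant and
complements area as an independent feature), and principal-axis
orientation in $(-\pi/2, \pi/2]$ from second central moments.

## Tracking

Frame-to-frame correspondence combines the nearest-neighbor criterion
with the four photometric/shape features. The link cost is

$$c(a, b) = w_d \left(\frac{d(a,b)}{d_\mathrm{max}}\right)^2 +
  \sum_f w_f \frac{|\Delta f|}{s_f},$$

with links beyond the gate $d_\mathrm{max}$ forbidden, orientation
differences taken modulo $\pi$, and feature scales $s_f$ the robust MAD
over all observations in the stack. Two deliberate departures from the
obvious formulation:

- **The distance term is squared.** For co-moving particles on a common
  line, the *sum* of linear displacement costs is identical whether
  identities are kept or swapped, so a linear term cannot prefer the
  correct pairing; the squared term strictly favors equal small steps and
  eliminates this degeneracy.
- **Feature weights default to small values** (0.15 for brightness, area
  and diameter, 0.05 for orientation, against 1 for distance). With
  MAD-normalized dissimilarities, a homogeneous particle population turns
  every feature term into measurement noise of order one, which would
  outvote geometry and cause identity swaps between co-moving neighbors.
  Down-weighted features still decide exactly the situations they are
  for: where two candidates are geometrically equivalent (crossings), the
  distance terms tie and any feature contrast resolves the assignment.

Each frame pair is resolved by a globally optimal one-to-one assignment
(maximum cardinality, then minimum total cost), computed as a
maximum-weight bipartite matching with a cardinality-dominant offset;
a brute-force enumeration oracle verifies optimality on all small
instances in the test suite. Unmatched observations start or terminate
tracks. Gap closing is off by default (`maxGapFrames = 0`); when enabled,
the distance gate scales with the frame gap and elapsed time is used in
the velocity denominator.

Trajectories with fewer than 25 points are removed (a 25-point track is
retained, a 24-point track is not). Because some beads adhere to tissue,
tracks whose net displacement is below twice the centroid noise scale are
flagged as stuck and excluded from kinematics by default.

## Regions and classification

Trajectories are placed on normalized wing coordinates (span 0 at base,
1 at tip; chord 0 at leading edge, 1 at trailing edge) via an affine
frame built from four landmarks. The default region map is schematic:
a leading-edge band (chord < 0.18), the membranous sinus pocket at
roughly two-thirds span toward the leading edge, a distal wing-tip cap
(span > 0.85), a trailing-edge band (chord > 0.75) and the central
lattice. The polygons tile the unit domain without overlap; boundary
points resolve by a fixed priority order (leading edge, membrane, tip,
trailing edge, lattice). A trajectory is assigned the region of its
*starting* position -- the plotting convention of the original wing maps
-- with majority-occupancy assignment available for sensitivity analysis
by assigning per-point regions directly.

Local flow behavior is classified from the signed along-path velocity
(each step projected on the smoothed local motion direction): *pulsatile*
if the signed series touches zero or reverses sign (the near-zero floor
is 5% of the trajectory's maximum speed -- the verbal criterion "never
stops entirely" needs a numerical floor), *aperiodic* if the sign is
constant and the magnitude stays above the floor, *indeterminate* below
10 samples. Leakiness is an orthogonal geometric flag: a trajectory is
leaky when some point lies outside every vein channel and inside a sinus
polygon.

One reporting caveat: trailing-edge pulse frequencies have been stated
both within a 0.21--0.81 Hz pulsatility range and as "0.04 and 0.03 Hz"
in the same context; the unit basis of the latter pair is unclear
(possibly peaks per frame). hemoflow reports Hz throughout and does not
attempt to reconcile the discrepancy.

## Problem sizes and reproducibility

All validation scenes are sized to run on a single CPU in minutes while
leaving the governing ratios intact:

- velocity recovery: one particle at 2.6 mm/s, 100 fps, 1 um/px, rendered
  into a 64 x 3190 px strip for 100 frames. The strip is long because a
  2.6 mm/s particle at 1 um/px covers 26 px per frame, and the 25-point
  minimum track length demands about 2.8 mm of clear run -- a square
  512 um field would lose every track to the length filter;
- region-ratio recovery: two 2 mm veins, 20 particles each, 32 frames at
  50 fps and 2 um/px, with imposed inflow/outflow maximum-speed ratios of
  1.5 (forewing) and 1.3 (hindwing);
- the demo pipeline: a five-region 4 x 1.5 mm network, 12 particles, 60
  frames at 30 fps and 4 um/px, exercising all three flow behaviors.

Every stochastic stage takes an explicit integer seed, and identical
seeds give bit-identical ground truth, rendered stacks and downstream
tables. `scripts/acceptance.R` re-runs the whole battery from scratch.

## Limitations

- The simulator's vein channels are straight segments with constant
  radius; real veins taper and curve, and tip-region particles traverse
  junctions the segment-local simulator does not model.
- Saturated spots (a consequence of the 1%-saturation adjustment) carry a
  flattened brightness feature; size features carry the discrimination
  in mixed-size scenes.
- The pulse-frequency estimator counts peaks, so its resolution is one
  peak per observation window; short tracks quantize coarsely.
- Behavior classification assumes the tracked motion is along-vein;
  out-of-plane motion or strong Brownian jitter would need the
  floor fraction retuned.
```{r}
sessionInfo()
```
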