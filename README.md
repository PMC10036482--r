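# hemoflow

Fluorescent particle tracking velocimetry for hemolymph microcirculation
in insect wing veins.

Insect wings are living tissue: hemolymph (insect blood) circulates
through every vein, entering through the wide leading-edge conduits and
returning to the body through the trailing edge, pulled by accessory
thoracic wing hearts. hemoflow quantifies these flows from fluorescence
time-lapse recordings of injected neutrally buoyant tracer particles
(3 and 6 µm beads, 10–100 fps): it detects the particles frame by frame,
links them into trajectories, and turns the trajectories into per-region
hemodynamic statistics. A first-class synthetic-scene module simulates
tracer motion through a stylized five-region wing vein network — with
pulsatile, aperiodic and leaky local flow behaviors — and renders it to
realistic fluorescence stacks (photobleaching, uneven illumination,
sensor noise), so every stage of the measurement chain is testable
against a known ground truth.

## The method

For a trajectory with positions `(x_i, y_i)` and step intervals `t_i`:

    V_instant = sqrt((x_i − x_{i+1})² + (y_i − y_{i+1})²) / t_i

in mm/s, smoothed with a centered moving mean (window 5, shrinking ends).
Pulse frequency is the count of peaks of the max-normalized speed trace
whose prominence exceeds 0.3, divided by the observation window.
Per wing region, with mean vein radius `r`, mean maximum speed `V_max`
and mean pulse frequency `f`:

    Pe = r·V_max / D_O2        (advection vs diffusion)
    Re = ρ·V_max·r / µ         (inertia vs viscosity)
    Wo = r·sqrt(f·ρ/µ)         (pulsatility vs viscosity)

with water properties ρ = 1000 kg/m³, µ = 0.0010518 Pa·s (18 °C) and
D_O2 = 1.8×10⁻⁹ m²/s.

Detection marks pixels where the larger eigenvalue of the smoothed
intensity Hessian is negative (bright blob interiors), grows one region
per intensity peak down to 25 % of that peak or up to a Canny edge, and
measures brightness, area, equivalent diameter and orientation. Linking
resolves each frame pair by a globally optimal one-to-one assignment
whose cost combines gated squared distance with the four feature
dissimilarities; trajectories shorter than 25 points are removed and
stuck particles are screened out.

## Worked example

Run the shipped demo — a 4 × 1.5 mm five-region wing network, 12
particles, all three flow behaviors, rendered at 30 fps and 4 µm/px with
bleaching, uneven illumination and read noise — end to end:

```r
library(hemoflow)
rep <- runPipeline()          # simulate → render → detect → track →
                              # analyze → summarize, seed = 1
rep$regionSummary
```

```
        region n_trajectories v_max_mm_s v_median_mm_s pulse_freq_hz    Pe      Re      Wo
  leading_edge              2      0.707         0.340         0.254 41.23 0.07056 0.05162
      membrane              1      0.550         0.501         0.000 15.28 0.02615 0.00000
      wing_tip              5      0.219         0.179         0.102  1.83 0.00313 0.00466
       lattice              3      0.424         0.334         0.000  8.84 0.01512 0.00000
 trailing_edge              1      1.092         0.221         0.508 63.68 0.10898 0.07301
```

Reading the table: the pulsatile edge regions carry the fastest flows
(the imposed trailing-edge peak speed is 1.1 mm/s — recovered as 1.092)
and nonzero pulse frequencies; the wing tip is slowest, with a Péclet
number near 1, meaning advective and diffusive oxygen transport balance
there; every Reynolds number is far below 1 — a purely viscous flow
regime. The membrane row is a leaky trajectory that left its vein,
crossed the membranous sinus and re-entered the network.

Individual stages are ordinary functions on ordinary objects
(`detectParticles()`, `trackParticles()`, `trajectoryKinematics()`,
`summarizeRegions()`, …); `inst/cli/hemoflow.R` wraps them in a thin
command-line front end, and TIFF/CSV/YAML readers and writers are
provided for all interchange formats.

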