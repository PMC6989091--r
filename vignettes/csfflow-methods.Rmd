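---
title: "Models and methods behind csfflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind csfflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfflow)
```

# The physical picture

In the central canal of the zebrafish embryo — a roughly cylindrical,
CSF-filled channel about 9 µm across — motile cilia line mainly the ventral
wall, beat at tens of hertz with a caudal tilt, and drive a steady
*bidirectional* flow: caudad along the ventral side, rostrad along the
dorsal side, with no net flux through any cross-section because the canal is
closed. `csfflow` implements the homogenized hydrodynamic model of this
flow, a numerical Stokes solver for spatially structured ciliary forcing,
the shear-enhanced (Taylor–Aris) transport theory that follows from the
flow, and the microscopy-video analyses (kymograph velocimetry, beat
frequency mapping) used to measure these quantities — together with
synthetic-data generators that plant known ground truth for every analysis
stage.

# The two-region model

At these scales (µm, µm/s) inertia is irrelevant and the Stokes limit
applies. The ciliated layer of height $h$ is homogenized into a constant
volume force density $f_v$ (N/m³) acting along the canal axis $x$; the
dorsal region is passive. With $y$ the dorso-ventral coordinate
($y=0$ ventral wall, $y=d$ dorsal wall, positive velocity caudad) the axial
momentum balance reduces to

$$\frac{dP}{dx} - f_v = \mu\, v_v''(y) \;\; (0<y<h), \qquad
  \frac{dP}{dx} = \mu\, v_d''(y) \;\; (h<y<d),$$

whose solutions are two parabolas with integration constants $y_A$, $y_B$
and an unknown common pressure gradient. Three conditions close the system:
continuity of velocity and of shear rate at $y=h$, and zero net flux
$\int_0^d v\,dy = 0$. Although the constants enter bilinearly, the
substitution $A=(dP/dx - f_v)\,y_A$, $B=(dP/dx)\,y_B$ linearizes the system,
which `solve_two_region()` solves exactly as a nondimensionalized 3×3 linear
system for *any* ciliated fraction $h/d$ — the celebrated symmetric case
$h=d/2$, where $y_A=d/4$, $y_B=3d/4$ and $dP/dx=f_v/2$, is kept as an exact
regression anchor rather than hard-coded. The resulting profile is the
symmetric "biparabolic" flow with extrema $\pm f_v d^2/(64\mu)$ at $y=d/4$
and $y=3d/4$.

The force density itself comes from dimensional analysis,
$f_v = \alpha\,\mu f/h$, with $f$ the mean beat frequency and $\alpha$ a
dimensionless factor of order unity. Default parameter values:

| parameter | default | meaning |
|---|---|---|
| $\alpha$ | 0.5 | force factor (the model's single fitting parameter) |
| $\mu$ | $10^{-3}$ Pa·s | CSF dynamic viscosity (water-like) |
| $f$ | 40 Hz | mean ciliary beat frequency |
| $d$ | 8.9 µm | canal diameter |
| $h$ | $d/2$ | ciliated-layer height |

With $h = 5$ µm these give $f_v = 4000$ N/m³, a pressure gradient of
2000 N/m³, and extremal speeds that round to ±5 µm/s. All internal units are
SI; only the reporting layer speaks µm/s. The solver accepts $h$ anywhere in
$(\varepsilon, d-\varepsilon)$ with $\varepsilon = 10^{-6} d$: the
two-region idealization is meaningless at the limits.

# The numerical Stokes solver

`solve_stokes()` handles ciliary force patterns that vary along the canal:
periodic patches ("sparse cilia"), unequal per-segment amplitudes
(frequency heterogeneity), and a linear-in-$y$ force profile. The
discretization exploits the geometry: the domain is periodic in $x$ over an
integer number of pattern periods, so the force is expanded in Fourier
modes along $x$. The $k=0$ mode is the mean flow — a two-point boundary
problem $\mu u_0'' = G - \bar f(y)$ whose free global pressure gradient $G$
is fixed by the zero-net-flux constraint (this is how the closed-canal
condition enters, mirroring the analytic closure). Each $k\neq 0$ mode
solves the streamfunction biharmonic equation
$\mu\,(D^2-k^2)^2\hat\psi = -\partial_y \hat f$ with clamped walls
($\hat\psi=\hat\psi'=0$), discretized with 2nd-order finite differences and
ghost-node elimination. Pressure is recovered mode-wise from the axial
momentum balance.

Numerical choices worth knowing:

* Force steps are *half-weighted* on grid nodes that sit exactly on the
  $y=h$ interface, and active-segment edges in $x$ are represented by exact
  per-cell coverage fractions. This keeps the discrete step centred and the
  solver effectively exact for the uniform case (it reproduces the
  piecewise-parabolic closed form to machine precision, since the finite
  difference of a parabola is exact).
* Default grid: 65 nodes across $d$ (64 intervals; odd counts put the
  mid-plane on a node) and 48 columns per pattern period; halving the
  spacing changes the maximal velocity by well under 1%.
* The section-averaged pressure slope is measured by exact one-period
  differencing, because a plain straight-line fit is biased by the
  sawtooth-like within-period pressure variation.

**Vortex detection.** The streamfunction of a pure bidirectional
through-flow has a flat ridge, not closed cells, so "a local maximum of
$\psi$" is not a usable vortex definition. `detect_recirculation()` finds
plateau-tolerant regional extrema (8-connectivity, periodic in $x$) and, for
each, bisects for the most extreme level whose enclosing level-set component
is still *closed* — touching no wall and not spanning every $x$ column. The
excursion from the extremum to that level, as a fraction of the global
$\psi$ range, is the vortex *prominence*; candidates below 2% are numerical
ripples and discarded. Plateau handling matters: piecewise-uniform forcing
(the heterogeneous-frequency case) produces genuinely flat streamfunction
tops over the stronger segments.

The "through-flow metric" — how much directed flow survives between
ciliated patches — is the maximal $|u|$ on the mid-cross-section of a
passive stretch. When the passive extension exceeds the canal diameter, the
metric falls below 10% of the uniform-forcing maximum and essentially all
streamlines close into vortices.

One measured discrepancy is recorded here deliberately: replacing the
constant force profile by a linear-in-$y$ profile of equal total force
changes the velocity profile by ≈30% in relative $L^2$ norm (peak ratio
≈1.2) while preserving the single sign change — the bidirectional
*structure* is robust, the amplitude less so. The test suite asserts the
structural claim and reports the computed difference.

# Transport: shear-enhanced dispersion

Particles of radius $r$ diffuse with the Stokes–Einstein coefficient
$D = k_B T/(6\pi r \mu)$ (default $T = 301$ K, the rearing temperature;
$k_B$ at its CODATA value). Advection by $v(y)$ couples to cross-channel
diffusion and enhances the *axial* spreading: over times long compared with
the cross-channel diffusion time $d^2/D$, the transport is again diffusive
with

$$D_\mathrm{eff} = D\left(1 + C\,\mathrm{Pé}^2\right), \qquad
  \mathrm{Pé} = \frac{V d}{D},$$

where $V$ is the profile maximum. The constant is a pure functional of the
profile shape, $C = \int_0^1 G(\xi)^2 d\xi$ with
$G(\xi)=\int_0^\xi v(sd)/V\,ds$; for the biparabolic profile the normalized
shape is $\tilde v(\xi) = 8\xi-16\xi^2$ on $[0,\tfrac12]$ (antisymmetric
beyond), giving exactly

$$C = \frac{13}{315}, \qquad \frac{1}{C} = \frac{315}{13} \approx 24.2,$$

conventionally quoted as $D_\mathrm{eff} \approx D(1+\mathrm{Pé}^2/24)$.
`taylor_aris_constant()` evaluates $C$ by quadrature for any profile, and
the test suite pins the 13/315 value against an independent double
quadrature.

**The simulator.** `simulate_transport()` integrates
$\partial_t c + v(y)\partial_x c = D(\partial_x^2 + \partial_y^2)c$ with
Strang splitting: because $v$ depends only on $y$, advection and axial
diffusion are applied *exactly* in Fourier space (each $x$-harmonic of each
row is multiplied by $e^{-(ikv_j + Dk^2)\Delta t}$), and transverse
diffusion uses Crank–Nicolson with conservative no-flux walls. There is
therefore no numerical axial diffusion to bias dispersion estimates, and
mass is conserved to machine precision. The time step is bounded at
$0.05\,d^2/D$ — not for stability (the scheme is unconditionally stable)
but so the splitting resolves the shear–diffusion coupling; the default is
$0.01\,d^2/D$. The default grid is 32 cells across the diameter and a
periodic axial domain sized so the boundaries stay empty at the end time,
with the initial condition a Gaussian plug (default width $d/2$) uniform
across the section.

Conventions pinned where the underlying articles leave them loose:

* **Front definition:** the furthest position at which the $x$-marginal
  exceeds 5% of its instantaneous peak. The threshold moves prefactors, not
  the $t^{1/2}$ exponent that is asserted.
* **Front-slope fit window:** $t \ge 1.5\,d^2/D$, at least 10 points over
  at least one decade.
* **Propagation time over a distance $L$:** $t = L^2/(4 D_\mathrm{eff})$
  with flow, $L^2/(4D)$ without — a transparent convention; only orderings
  and shapes are asserted against it.
* **Deff fit:** half the slope of marginal variance against time for
  $t \ge 3\,d^2/D$.

Production problem sizes: dispersion fits use 10 cross-diffusion times at
Pé ∈ {5, 10, 20} (a few seconds each); front-exponent runs use 15. At those
sizes the fitted $1/C$ is 23.9 — rounding to the conventional 24 and within
1.5% of 315/13.

# Kymograph velocimetry

The measurement chain from a bead movie (default: 10 Hz for 30 s, 189 nm
pixels) to a dorso-ventral velocity profile:

1. **Align and crop** (`preprocess_video()`): the canal axis is made
   horizontal (auto-estimated from the principal axis of the thresholded
   time-mean image if no angle is given) and the stack cropped to the
   canal. Right-angle rotations are exact array operations.
2. **Denoise** (`denoise()`): per-frame 2D Haar decomposition, soft
   thresholding of all detail subbands at the universal threshold
   $\sigma\sqrt{2\ln N}$ with $\sigma$ estimated robustly (MAD) from the
   finest diagonal subband — the only subband that is essentially pure
   noise; estimating $\sigma$ per subband would let signal inflate the
   coarse-level thresholds and destroy structure. The nominal level-6
   decomposition applies to frames of a few hundred pixels; smaller crops
   automatically use fewer levels.
3. **Re-slice** (`build_kymograph()`): the intensity at one dorso-ventral
   row, averaged over 3 adjacent rows (this partial averaging of the
   Brownian wander is what makes traces long enough to segment), as a
   time × position image. Each time sample is divided by its spatial mean
   (removing global flicker and photobleaching — a per-position
   normalization alone cannot remove a temporal decay) and each position by
   its temporal mean (removing illumination gain).
4. **Trace extraction** (`extract_traces()`): pixels above the average,
   8-connected components, ellipse-equivalent moments, and the four
   filters: area ≥ 15 px, eccentricity > 0.9, and $|\cos\theta|$ and
   $|\sin\theta|$ ≥ 0.1 — the last two reject stuck beads (vertical lines)
   and global flickers (horizontal lines). Velocity is
   $\tan\theta \cdot \mathrm{px}/\Delta t$, $\theta$ measured from the time
   axis, caudal positive. Counts are *traces*, not unique beads: a bead
   wandering across rows is counted again, by design.
5. **Profile and landmarks** (`velocity_profile()`,
   `profile_landmarks()`): per-row mean ± SEM; normalized positions use the
   event-support rule — position 0 is the most ventral row with ≥ 5 events
   and mean velocity > +0.4 µm/s, position 1 the most dorsal row with ≥ 5
   events and mean < −0.4 µm/s (the threshold is applied symmetrically on
   both sides; the asymmetric phrasing in the original description is
   treated as a typo). `measured_profile_extrema()` estimates profile
   extrema from a count-weighted 5-row running mean, because the plain
   maximum over ~45 noisy row means is upward-biased.

`track_particles()` provides the complementary minimal PTV: per-frame
detection with 3-point log-Gaussian subpixel refinement, and frame-to-frame
linking by *exact* optimal assignment (an O(n³) Hungarian solve of the
total squared displacement, gated at 5 px/frame, bridging single missing
frames). Exact assignment replaces the fragile heuristic linking typical of
memory-bound PTV codes and is testable against brute-force enumeration.

## What recovery tests show — and their limits

With the planted ±4.95 µm/s biparabolic flow the pipeline recovers the
extrema within a few percent *when traces are resolvable*, i.e. when the
per-frame Brownian step is below the PSF footprint (bead diffusivity
$D \lesssim 0.2$ µm²/s at 10 Hz). For faster-diffusing beads two intrinsic
biases appear, both properties of the algorithm class rather than of this
implementation: (i) at intermediate $D$ the ellipse-orientation estimate of
a jagged trace is inflated by the errors-in-variables geometry of PCA
orientation (velocities overestimated); (ii) once the per-frame step
exceeds the trace width, kymograph regions only connect across frames when
a bead happens to move little, and conditioning on that connectivity biases
slopes toward zero (velocities attenuated, by ~40–60% at the
Stokes–Einstein diffusivity of a 20 nm-radius bead in water, 11 µm²/s).
The acceptance suite deliberately runs the recovery test at that pinned
Stokes–Einstein diffusivity and documents the failure: the imaging
conditions and free-solution Brownian theory are mutually inconsistent for
this method — second-long bead traces, which the method needs, imply an
effective in-vivo diffusivity orders of magnitude below the free-water
value. Passing module tests therefore demonstrate algorithmic correctness
in the resolvable-trace regime, not that the method defeats arbitrary
Brownian noise.

# Contractions and flow transients

`detect_contractions()` finds bursts in the absolute frame-to-frame
derivative of the mean canal intensity (threshold 4 on the normalized
derivative, configurable); an event's strength is the sum of its
supra-threshold derivative values, mixing amplitude and duration.
`post_contraction_flux()` integrates the section-averaged flow over a
window after each onset — default 2.5 s, exposed as a parameter since both
2.5 s and 5 s windows appear in the source descriptions — and flags events
truncated by the end of the recording.

# Ciliary beat-frequency mapping

`frequency_map()` applies a 4×4 spatial sliding average, then a plain
temporal Fourier transform per pixel (no window: spectral leakage is
absorbed by the 5 Hz bands; magnitude rather than power spectral density,
the two having been found equivalent for this purpose). The dominant non-DC
peak above 2 Hz (drift exclusion) and below Nyquist defines the pixel's
frequency and amplitude. `segment_cilia_regions()` masks pixels whose peak
amplitude clears a robust noise floor (median + 3 MAD of the amplitude
map), bins the rest into 5 Hz bands, and keeps 8-connected components of at
least 200 px (≈3 µm across). Per region, the ellipse-equivalent moments
give the cilium length (major axis), the signed tilt $\Theta$ from the
dorso-ventral axis (positive = caudal, for a cilium extending from its base
wall into the canal), and the beating height $L|\cos\Theta|$; the side is
the centroid's side of the midline.

Two caveats the synthetic tests made explicit. A cilium whose beat spans a
band edge is split between bands — the band-of-dominant-frequency rule is
kept and the behaviour documented rather than patched. And pixels in the
middle of the swept arc are crossed twice per beat, so their spectra peak
at $2f$; with fewer than ~5 frames per beat this frequency doubling can
fragment the fundamental-frequency region. This is a genuine property of
per-pixel Fourier beat mapping, visible in real data as a doubled-frequency
fringe inside sweep regions.

# The synthetic-data generators

Every analysis stage is validated against generators with planted ground
truth (`make_bead_video()`, `make_cilia_video()`, `make_canal_phantom()`,
`make_contraction_series()`, `make_front_series()`), all strictly
reproducible from a mandatory seed. The bead generator advects beads with
the planted profile, adds per-axis Gaussian Brownian steps of variance
$2D\Delta t$, reflects at the walls, wraps periodically in $x$, and renders
Gaussian spots (PSF σ = 1.2 px) over read noise. Defaults emulate the
acquisition settings throughout: 10 Hz/30 s bead movies at 189 nm/px in an
8.9 µm canal; 100 Hz/3 s cilia movies; 60 beads per 30 µm field of view
(well below the overlap-warning density).

What the generators deliberately do *not* emulate: tissue background and
autofluorescence, out-of-plane (3D) bead motion and defocus, non-rigid
cilium waveforms (the rendered cilium is a rigid rod swinging
sinusoidally ±12°), metachronal coordination, and detector nonlinearity.
Tests passing on these synthetics therefore certify the algorithms and
their conventions — axis conventions, filter behaviour, unit arithmetic,
statistical scalings — not performance on raw microscope output.

# Known limitations

* The flow model is 2D; the true canal is roughly cylindrical, and the
  cylindrical dispersion constant differs from the planar 13/315.
* The homogenized steady force cannot represent time-resolved stroke
  dynamics or cilium–cilium interactions; only the steady mean flow is
  predicted.
* The kymograph method's accuracy degrades with bead diffusivity as
  analysed above; it is a trace-statistics method, not a per-particle
  tracker.
* `propagation_time()` is a convention, not a measurement: use it for
  orderings and scalings.
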