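---
title: "Droplet-microfluidic crystallization and micromixing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Droplet-microfluidic crystallization and micromixing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropxtal)
```

dropxtal models the preparation of uniform protein microcrystals in
monodisperse microfluidic droplets and the millisecond micromixing of
crystals with substrates inside transported droplets, for serial and
time-resolved crystallography. This vignette records the models, their
assumptions, the tunable parameters, and the numerical and design choices,
so the package can be audited and extended.

## Unit conventions

All user-facing quantities use one fixed system: volumes in picolitres
(1 pl = 1000 µm³), lengths and diameters in micrometres, densities in
per-nanolitre, frequencies in kHz, velocities in mm s⁻¹ (equal to µm ms⁻¹),
times in ms, concentrations in mg ml⁻¹. Converters are centralized in the
geometry functions; nothing else rescales units.

## Encapsulation statistics

Random encapsulation of dilute particles (crystals or seeds) into droplets
of volume $V$ at bulk density $\rho_n$ gives a Poisson-distributed
occupancy with mean $\lambda = \rho_n V$:

$$P(K = k) = \frac{e^{-\lambda}\lambda^k}{k!}, \qquad
P(K = 1 \mid K \ge 1) = \frac{\lambda e^{-\lambda}}{1 - e^{-\lambda}}.$$

The Poisson form is an assumption: occupancy data report only the mean.
It is the standard model for dilute random loading, and it is consistent
with the deep single-occupancy regime observed at sub-picolitre volumes
($\lambda \sim 10^{-2}$). The conditional single-occupancy fraction tends
to 1 as $\lambda \to 0^+$ and decreases strictly with $\lambda$; the
function requires $\lambda > 0$ and documents the limit instead of
silently returning it.

`fit_lambda()` estimates $\lambda$ from per-droplet counts by the Poisson
MLE (the sample mean). The default confidence interval is the exact
Poisson-mean (Garwood) interval from chi-square quantiles of the total
count, chosen because the interesting regimes are small-count
($\lambda \le 0.1$, mostly empty droplets) where Wald-type intervals
misbehave; a nonparametric bootstrap is available for populations that
are suspected not to be Poisson. Note that for $n = 500$ droplets at
$\lambda = 0.1$ the sampling standard deviation of $\hat\lambda$ is
$\sqrt{\lambda/n} \approx 0.014$, i.e. 14% relative — point-estimate
closeness is therefore not a sound test at this size, and the package's
property tests check *interval coverage* instead.

Droplets are treated as spheres: $d = (6V/\pi)^{1/3}$, SA:V $= 6/d$. Real
channel-confined droplets can be plugs; the sphere-equivalent convention is
the one used when diameters are quoted for generated volumes, and it is
applied uniformly. Generation frequency is flow over volume,
$f = Q_{aq}/V$, which expresses why throughput rises ~50-fold as droplets
shrink from 754 pl to 0.89 pl at the flows used.

## Mass-balance crystal sizing

Crystal size in a droplet is set by the protein the droplet contains.
With final (post-mixing) protein concentration $c_0$, residual solubility
$c_s$, crystal protein packing density $\rho$, and $k$ crystals sharing
the droplet, the per-crystal volume is

$$v = \frac{V (c_0 - c_s)}{\rho\, k},$$

and with a square-prism habit of aspect $a$ (length:width),
$L = (v a^2)^{1/3}$, $W = L/a$. Length scales exactly as $V^{1/3}$ at
fixed $k$ — the lever that turns droplet volume into crystal size.

Defaults, all configurable and never hard-coded into results:

* `crystal_packing_density_mg_ml = 800` — typical of tetragonal lysozyme;
  the value is not measurable from the study inputs, so it must be explicit.
* `residual_solubility_mg_ml = 0` — high-salt lysozyme conditions leave
  little protein in solution; for other systems set $c_s > 0$.
* `habit_aspect = 2.7` — between the elongated 7 × 2 µm batch habit and the
  near-equant micro-habits seen in droplets.

With the 1:4 lysozyme recipe (20 mg ml⁻¹ stock, $c_0 = 4$ mg ml⁻¹) these
defaults put a single crystal from a 0.89 pl droplet at ≈3.2 µm and
fifteen crystals sharing 194 pl at ≈7.8 µm, bracketing the observed sizes;
the acceptance tests sweep $a \in [2, 3.5]$ to show the bracket is not an
artifact of one habit choice.

Seed dilution follows the same mass balance: diluting seeds $x$-fold
leaves $x$-fold more protein per seed, so $L = L_0 x^{1/3}$. This is
deliberately an *upper bound*: it assumes complete depletion and a seed
count exactly inversely proportional to dilution. Observed lengths at 10-
and 100-fold dilution fall short of the bound (≈18 vs 23.7 µm, ≈30 vs
51.1 µm), consistent with incomplete depletion or seed-count
nonlinearity; the model is documented as a bound and is not tuned to the
observations. `fit_length_diameter()` provides the empirical linear
length-vs-diameter fit with no fixed coefficients.

Confinement: a crystal cannot elongate past the droplet diameter;
`axial_ratio_cap()` truncates the intrinsic length at $d$ and reports the
realized axial ratio, which therefore decreases in small droplets.

Into-crystal substrate transport is modelled as diffusion into a slab of
half-thickness equal to the travel distance (e.g. 1 µm for a 2 µm
crystal), faces held at the external concentration, centre initially
empty; the centre reaches a fraction $f$ (default 0.5) of the face
concentration at the time solved from the Fourier-series solution, with
$t \propto \mathrm{travel}^2 / D_{\mathrm{eff}}$. Slab rather than sphere
geometry matches the travel-distance framing and is conservative. The
series is summed to 60 terms (vastly more than needed; terms decay like
$e^{-(2n+1)^2}$) and inverted by `uniroot` on the dimensionless time.
`diffusivity_from_time()` inverts the same series, e.g. a 400 µs
half-saturation over 1 µm implies $D_{\mathrm{eff}} \approx 950$ µm² s⁻¹,
the small-ligand scale that motivates micrometre crystals.

## Synthetic microscopy

The generator emulates the statistical structure the measurement pipeline
assumes, not optics: monodisperse droplet fields (normal diameters at a
configured CV, default 3%, matching the <4% monodispersity of flow
focusing), Poisson crystal counts, rod crystals with normal lengths and a
fixed aspect, uniform orientations on [0°, 180°). Droplets are placed
without overlap by rejection sampling (bounded retries, then a clear
"too crowded" error); rods are confined to the droplet interior and placed
disjointly where geometry permits. Rendering uses flat grey levels
(mid-grey oil, bright interior, darker rim, darker crystals) with 3 × 3
supersampled anti-aliased edges, each droplet composited over its own
coverage only; additive Gaussian noise is applied last. One integer seed
drives every stochastic draw through R's global generator, so identical
seeds give bit-identical images and truth tables.

Deliberately not modelled: point-spread function, depth of field,
illumination gradients, polydisperse emulsion failure modes, crystal
birefringence. Passing recovery tests on these images therefore shows the
measurement chain is correct and unbiased on clean, in-focus data; it
does not certify performance on degraded real micrographs.

Mixing sequences are rendered from stored simulation fields by an affine
map (dye absorbs: higher concentration → darker), one simulation cell per
pixel, with the noise-free intensity-CV series and its threshold crossing
kept as ground truth. Because the affine map has an offset, the intensity
CV is not numerically equal to the concentration CV; each analysis path is
tested against its own truth.

## Droplet and crystal measurement

Detection is unsupervised and parameter-driven (the original workflow was
supervised; a reproducible re-implementation must not be): global Otsu
threshold, refined to the midpoint between the background and the object
edge level — Otsu alone sits above the half-coverage level of the
anti-aliased edge and biases diameters low by ~1% — then hole filling,
distance-transform watershed to split touching droplets, and a
circularity filter (moment-based: equivalent-area diameter over
moment major-axis length, ≥0.8 by default). Diameters are
equivalent-area-circle diameters in µm. Droplets touching the frame edge
are excluded by default to avoid truncated diameters; the original study
does not state its handling of partial droplets, so this is a documented
default, not a reconstruction.

Crystals are segmented inside each droplet mask (eroded to exclude the
rim) as pixels below 0.75 of the droplet's median intensity, labelled,
filtered at a 4 px² minimum area, and measured by the rotated minimum-area
bounding box (rotating calipers over the convex hull): length = major
extent, width = minor extent, orientation = long-axis angle; +1 px
converts centre-to-centre extents to pixel extents. Coordinates are
0-based, x right, y down, pixel centres at integers.

`summarize_population()` reports droplet diameter mean/CV, crystal length
mean/CV, the occupancy histogram and $\hat\lambda$ with its interval. A
single measured crystal leaves the length CV *undefined and flagged* —
never silently 0 — because a one-crystal population carries no
uniformity information.

## In-droplet mixing simulation

The simulator is a 2-D surrogate for a 3-D droplet in transit. The domain
is the disk of the sphere-equivalent diameter, in the co-moving frame.
Transport induces two counter-rotating recirculation lobes, prescribed
analytically by the stream function

$$\psi = A\, y \left(1 - \frac{r^2}{R^2}\right),$$

which vanishes on the rim (the boundary is a streamline) and whose
amplitude is scaled so the peak internal speed is $\alpha U$. The
circulation strength inside a real droplet is not known from first
principles, so $\alpha$ (default 0.5) is an explicit calibration constant:
*orderings and trends are the reproducible claims; absolute times are
calibration-dependent* and the package makes no attempt to match the
experimental 1.7–7 ms values beyond order of magnitude.

A steady planar vortex pair cannot homogenize a droplet: it only averages
dye along closed streamlines, leaving cross-streamline transport to
diffusion, and the CV plateaus at the streamline-averaged variance. Real
transported droplets do not see a steady interior flow — channel turns and
junction wakes periodically reorient the circulation, which is what makes
droplets effective mixers. The simulator therefore swaps the lobe axis by
90° with period `swap_period_ms` (default two turnover times, $4R/\alpha U$;
`Inf` recovers the steady field), the classic blinking-vortex route to
chaotic advection. Each instantaneous field is still the analytic two-lobe
recirculation.

Numerics: conservative finite-volume advection with face velocities taken
as corner differences of $\psi$, so the discrete velocity field is exactly
divergence-free and the advective fluxes are *never masked* — masking rim
faces would leave rim cells with spurious divergence acting as permanent
variance sources (this failure mode is why the scheme is built this way).
Fluxes use minmod-limited second-order upwinding (TVD); diffusion is an
operator-split explicit step with no-flux walls on the active mask. Total
dye mass is conserved to machine precision and tracked (`mass_drift`);
the shipped stability bounds are CFL 0.4 for advection and 0.2 for
diffusion, checked at configuration time with a hard error for
user-supplied unstable steps. The grid must resolve the droplet with at
least 64 cells across.

Initial conditions: *generation* mode folds the two liquids into
`n_lamellae` (default 4) alternating bands with widths in ratio
$\varphi : (1-\varphi)$, a surrogate for the stream thinning that droplet
generation performs; *fusion* mode fills a contiguous side of the disk to
area fraction $\varphi$ with no pre-thinning, which is why fused droplets
mix more slowly at matched conditions. In simulation, $t = 0$ is the
lamellar (or fused) initial condition — a stated convention; the
experimental time zero is the stream-combination landmark.

The mixing measure is the spatial CV of concentration over the droplet
pixels, and the mixing time is the first linearly interpolated crossing
of the 5% threshold (0 if already below; `NA` sentinel if never crossed,
not an exception). A suspended crystal is represented as a small interior
region excluded from the CV statistic only — crystals are advected with
the interior flow, so transport is left unchanged — and the paired
`crystal_passivity_check()` verifies the measured mixing time is
insensitive to a 1–2% exclusion, mirroring the observed null effect.

Dye diffusivity defaults to 400 µm² s⁻¹, the scale of a ~570 Da organic
dye in water; it is the parameter to change for other substrates.

Reproduced behaviours (each a test): mass conservation; CV → 0 at long
times; diffusion-only runs agree with an independent finite-difference
oracle within 5%; mixing time decreases strictly as the dye volume
fraction rises from 0.1 to 0.5 (the entropy-of-mixing effect); mixing
time decreases strictly as velocity rises 60 → 300 mm s⁻¹ with the
accompanying droplet shrinkage 126 → 39 pl; fusion is slower than
generation at matched conditions.

## Problem sizes and seeds

Test and acceptance workloads are sized for a single CPU while remaining
statistically meaningful: mixing runs use the minimum 64-cell grid on
small (4–126 pl) droplets; end-to-end recovery uses 500-droplet fields at
$\lambda = 0.1$, 15 µm droplets at 3 px µm⁻¹, three seeds; estimator
coverage uses 20 seeds at $n = 500$. All randomness flows from explicit
integer seeds; reruns are bit-identical.

## Known limitations

* The mixing model is 2-D with a prescribed flow; no interface or
  surfactant dynamics, no droplet-pairing hydrodynamics, no injection
  physics, and absolute mixing times depend on the $\alpha$ and
  `swap_period_ms` calibration.
* The size model has no nucleation kinetics or growth time course; it is
  a depletion endpoint. Seed-dilution predictions are upper bounds.
* The SA:V correlation with crystal-density loss is treated as empirical;
  no mechanistic interface model is provided.
* Synthetic imagery omits optics; measurement accuracy on real
  micrographs must be validated separately.
* SSX accounting is count arithmetic only; computed rates are reported
  unrounded, and where published tables round inconsistently with their
  own count ratios, the computed values take precedence.
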