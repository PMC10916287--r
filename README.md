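# dropxtal

Quantitative toolkit for droplet-microfluidic preparation of protein
microcrystals and in-droplet micromixing, aimed at serial and time-resolved
crystallography practitioners who need to *design* droplet experiments
(what droplet volume, what seed density, what crystal size will result) and
to *measure* their outcomes (droplet and crystal sizing from micrographs,
occupancy statistics, mixing times from high-speed image sequences).

## What it computes

**Encapsulation statistics.** Random loading of crystals or seeds into
droplets of volume *V* at bulk density *ρₙ* is Poisson with mean
λ = ρₙV:

    P(K = k) = e^{−λ} λ^k / k!,   P(K = 1 | K ≥ 1) = λe^{−λ} / (1 − e^{−λ})

Driving λ below ~0.1 makes nearly every occupied droplet single-crystal,
which is the route to uniform crystal slurries. `fit_lambda()` estimates λ
from counted droplets with an exact (Garwood) Poisson-mean interval.
Droplet geometry uses the sphere convention d = (6V/π)^{1/3}, SA:V = 6/d,
and generation frequency f = Q/V.

**Mass-balance crystal sizing.** A droplet's protein content sets its
crystal size: with final concentration c₀, residual solubility c_s,
packing density ρ and k crystals sharing the droplet,

    L = ( V (c₀ − c_s) a² / (ρ k) )^{1/3}

for a square prism of aspect a — so length scales as V^{1/3}, and seed
dilution x grows crystals as x^{1/3} (an upper bound). Into-crystal
substrate diffusion times come from the slab Fourier-series solution.

**Synthetic microscopy with ground truth.** `gen_droplet_field()` renders
monodisperse droplet fields with Poisson-loaded rod crystals and returns
the exact truth tables; `gen_mixing_frames()` renders homogenizing dye
fields. These benchmark the measurement chain end to end.

**Image analysis.** `detect_droplets()` (threshold + watershed +
circularity filter), `measure_crystals()` (rotated minimum-area box), and
`summarize_population()` (diameter/length CVs, occupancy histogram, λ̂).

**Mixing simulation and statistic.** `run_mixing_sim()` advects a dye
scalar in a 2-D droplet disk with an analytic two-lobe recirculation
(periodically reoriented, the blinking-vortex mechanism of chaotic
mixing), conservative flux-limited finite volumes, mass conserved to
machine precision. The mixing measure is the pixel-intensity CV over the
droplet; the mixing time is the first crossing of the 5% threshold
(`mixing_time()`, `mixing_time_stats()`, `extract_kymograph()`).

**SSX accounting.** `ssx_rates()` recomputes hit and indexing percentages
from collected/hit/indexed image counts.

## Worked example

```r
library(dropxtal)

# Occupancy design: batch crystal density 80 nl^-1 encapsulated in 194 pl
lambda_from_density(80, 194)
#> [1] 15.52                      # the multi-crystal regime (high size CV)
single_occupancy_fraction(0.1)
#> [1] 0.9508332                  # at lambda 0.1, 95% of occupied droplets hold one crystal

# Size design: 1:4 lysozyme recipe (4 mg/ml) in a 0.89 pl droplet
lys <- crystallization_recipe(20, 1, 4)
predict_crystal_length(0.89, lys, k = 1)
#> Predicted crystal (1 of 1 sharing 0.89 pl): 3.19 x 1.18 um (4.45 um^3)

# Synthetic field -> detection -> population summary
im  <- imaging_config(pixel_size_um = 0.5, image_size = c(900, 900),
                      noise_sd = 0.01, seed = 11)
fld <- gen_droplet_field(100, 20, size_cv = 0.03, lam = 0.5, imaging = im)
det <- detect_droplets(fld$image, 0.5)
cry <- measure_crystals(fld$image, det, 0.5)
summarize_population(det, cry)
#> Population of 100 droplets, 62 crystals
#>   droplet diameter: 19.9 um (CV 2.7%)
#>   crystal length: 3.06 um (CV 18.7%)
#>   lambda-hat = 0.62, 95% CI [0.4754, 0.7948]

# Mixing in a 39 pl droplet transported at 300 mm/s
sim <- run_mixing_sim(mixing_sim_config(39, 300, dye_volume_fraction = 0.5,
                                        grid_n = 64, t_max_ms = 8))
sim
#> In-droplet mixing simulation: 39 pl (d = 42.1 um), U = 300 mm/s, D = 400 um^2/s
#>   init: generation, phi = 0.50; grid 64, dt = 0.00175 ms
#>   mixing time (CV <= 5%): 5.17 ms; mass drift 1.4e-16
```

The summary recovers the generator's parameters (20 µm droplets at 3% CV,
λ = 0.5 within sampling error); the mixing time is millisecond-scale and
decreases with dye volume fraction and droplet velocity — the orderings
the simulator is designed to reproduce.

A command-line interface wrapping the same functions is installed at
`exec/dropxtal` (subcommands: `design occupancy|size|volume-for-length`,
`generate field`, `analyze-droplets`, `simulate-mixing`, `analyze-mixing`,
`ssx-rates`, `run`).

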