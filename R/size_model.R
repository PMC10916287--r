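#' Describe a batch/droplet crystallization recipe
#'
#' Captures the mass-balance inputs that set crystal size: the protein stock
#' concentration, how it is diluted against mother liquor (and seed) on
#' mixing, the residual protein solubility left in solution when growth
#' stops, the protein packing density of the crystal form, and the crystal
#' habit expressed as the length:width aspect of a square prism.
#'
#' Defaults suit tetragonal lysozyme grown in a high-salt condition: packing
#' density 800 mg/ml, residual solubility 0 (strong supersaturation, near
#' complete depletion), aspect 2.7.
#'
#' @param protein_stock_mg_ml Protein stock concentration, mg/ml.
#' @param mix_parts_protein,mix_parts_other Volumetric mixing parts of protein
#'   stock vs everything else (mother liquor, seed stock).
#' @param residual_solubility_mg_ml Protein left in solution at the end of
#'   growth, mg/ml.
#' @param crystal_packing_density_mg_ml Protein mass per crystal volume, mg/ml.
#' @param habit_aspect Length:width of the square-prism habit (>= 1).
#' @return An object of class `crystallization_recipe`.
#' @examples
#' # one part 20 mg/ml lysozyme to four parts mother liquor
#' lys <- crystallization_recipe(20, 1, 4)
#' final_concentration(lys)  # 4 mg/ml
#' @export
crystallization_recipe <- function(protein_stock_mg_ml,
                                   mix_parts_protein = 1,
                                   mix_parts_other = 0,
                                   residual_solubility_mg_ml = 0,
                                   crystal_packing_density_mg_ml = 800,
                                   habit_aspect = 2.7) {
  stopifnot(protein_stock_mg_ml > 0, mix_parts_protein > 0,
            mix_parts_other >= 0, residual_solubility_mg_ml >= 0,
            crystal_packing_density_mg_ml > 0, habit_aspect >= 1)
  r <- structure(list(protein_stock_mg_ml = protein_stock_mg_ml,
                      mix_parts_protein = mix_parts_protein,
                      mix_parts_other = mix_parts_other,
                      residual_solubility_mg_ml = residual_solubility_mg_ml,
                      crystal_packing_density_mg_ml = crystal_packing_density_mg_ml,
                      habit_aspect = habit_aspect),
                 class = "crystallization_recipe")
  if (residual_solubility_mg_ml > final_concentration(r)) {
    warning("residual solubility exceeds the final concentration: no growth possible")
  }
  r
}

#' @export
print.crystallization_recipe <- function(x, ...) {
  cat(sprintf(
    "Crystallization recipe: %.3g mg/ml stock, %g:%g mix -> c0 = %.3g mg/ml\n",
    x$protein_stock_mg_ml, x$mix_parts_protein, x$mix_parts_other,
    final_concentration(x)))
  cat(sprintf("  residual solubility %.3g mg/ml, packing %.3g mg/ml, aspect %.2f\n",
              x$residual_solubility_mg_ml, x$crystal_packing_density_mg_ml,
              x$habit_aspect))
  invisible(x)
}

#' Final protein concentration after mixing
#'
#' @param recipe A [crystallization_recipe()].
#' @return Concentration in mg/ml: `stock * parts_protein / (parts_protein + parts_other)`.
#' @export
final_concentration <- function(recipe) {
  stopifnot(inherits(recipe, "crystallization_recipe"))
  total <- recipe$mix_parts_protein + recipe$mix_parts_other
  if (total <= 0) stop("total mixing parts must be positive")
  recipe$protein_stock_mg_ml * recipe$mix_parts_protein / total
}

#' Predict crystal size from droplet volume by mass balance
#'
#' Crystal size in a droplet is set by the protein the droplet holds: the
#' crystallizable mass `V * (c0 - cs)` is shared by the `k` crystals in the
#' droplet and packed at the crystal density `rho`, giving a per-crystal
#' volume `V (c0 - cs) / (rho k)`. Length follows from the square-prism habit
#' `L = (volume * a^2)^(1/3)`, `W = L / a`, so length scales as the cube root
#' of droplet volume at fixed occupancy.
#'
#' @param volume_pl Droplet volume in picolitres.
#' @param recipe A [crystallization_recipe()].
#' @param k Number of crystals sharing the droplet (>= 1).
#' @return An object of class `crystal_prediction`: `crystal_volume_um3`,
#'   `length_um`, `width_um`, `k`, and a `no_growth` flag set when the final
#'   concentration does not exceed the residual solubility.
#' @examples
#' lys <- crystallization_recipe(20, 1, 4)   # c0 = 4 mg/ml
#' predict_crystal_length(0.89, lys, k = 1)  # ~3 um crystal in a 0.89 pl droplet
#' @export
predict_crystal_length <- function(volume_pl, recipe, k = 1) {
  stopifnot(inherits(recipe, "crystallization_recipe"),
            volume_pl >= 0, k >= 1, k == round(k))
  c0 <- final_concentration(recipe)
  cs <- recipe$residual_solubility_mg_ml
  no_growth <- c0 <= cs
  # V[pl] * 1000 um^3/pl * (mg/ml over mg/ml) -> um^3
  vol_um3 <- if (no_growth) 0 else volume_pl * 1000 * (c0 - cs) /
    recipe$crystal_packing_density_mg_ml / k
  a <- recipe$habit_aspect
  len <- (vol_um3 * a^2)^(1 / 3)
  structure(list(crystal_volume_um3 = vol_um3, length_um = len,
                 width_um = len / a, k = k, no_growth = no_growth,
                 recipe = recipe, volume_pl = volume_pl),
            class = "crystal_prediction")
}

#' @export
print.crystal_prediction <- function(x, ...) {
  if (x$no_growth) {
    cat("No growth: final concentration does not exceed residual solubility\n")
  } else {
    cat(sprintf(
      "Predicted crystal (%g of %d sharing %.3g pl): %.3g x %.3g um (%.3g um^3)\n",
      1, x$k, x$volume_pl, x$length_um, x$width_um, x$crystal_volume_um3))
  }
  invisible(x)
}

#' Droplet volume needed for a target crystal length
#'
#' Closed-form inverse of [predict_crystal_length()].
#'
#' @param target_length_um Desired crystal length, micrometres.
#' @inheritParams predict_crystal_length
#' @return Droplet volume in picolitres.
#' @export
volume_for_length <- function(target_length_um, recipe, k = 1) {
  stopifnot(inherits(recipe, "crystallization_recipe"), target_length_um >= 0)
  c0 <- final_concentration(recipe)
  cs <- recipe$residual_solubility_mg_ml
  if (c0 <= cs) stop("recipe permits no growth (c0 <= residual solubility)")
  a <- recipe$habit_aspect
  crystal_vol_um3 <- target_length_um^3 / a^2
  crystal_vol_um3 * recipe$crystal_packing_density_mg_ml * k / (c0 - cs) / 1000
}

#' Crystal length scaling under seed dilution
#'
#' Diluting the seed stock `x`-fold leaves `x`-fold more protein per seed, so
#' at constant protein supply the crystal length grows as the cube root of
#' the dilution. This is a mass-balance upper bound: it assumes complete
#' depletion and a seed count exactly inversely proportional to dilution, and
#' observed lengths can fall short of it.
#'
#' @param base_length_um Length at dilution 1, micrometres.
#' @param dilution_factor Fold dilution of the seed stock (>= 1).
#' @return Predicted length in micrometres, `L0 * dilution^(1/3)`.
#' @export
seed_dilution_length <- function(base_length_um, dilution_factor) {
  stopifnot(base_length_um >= 0)
  if (any(dilution_factor < 1)) stop("dilution factor must be >= 1")
  base_length_um * dilution_factor^(1 / 3)
}

#' Cap an elongated crystal at the droplet diameter
#'
#' A crystal cannot elongate past the droplet that confines it: needles and
#' elongated prisms grow to the droplet diameter and stop, lowering the
#' realized axial ratio in small droplets.
#'
#' @param intrinsic_length_um Unconfined length, micrometres.
#' @param width_um Crystal width, micrometres.
#' @param droplet_diameter_um Droplet diameter, micrometres.
#' @return List with `length_um` (= `min(intrinsic, diameter)`), `axial_ratio`
#'   (= length/width) and logical `capped`.
#' @export
axial_ratio_cap <- function(intrinsic_length_um, width_um, droplet_diameter_um) {
  stopifnot(intrinsic_length_um > 0, width_um > 0, droplet_diameter_um > 0)
  len <- pmin(intrinsic_length_um, droplet_diameter_um)
  list(length_um = len, axial_ratio = len / width_um,
       capped = intrinsic_length_um > droplet_diameter_um)
}

# Fractional concentration at the centre of a slab of half-thickness L with
# faces held at c0 and zero initial interior, at dimensionless time
# theta = D t / L^2 (Fourier series; terms decay like exp(-(2n+1)^2 ...)).
slab_center_fraction <- function(theta, n_terms = 60) {
  n <- 0:(n_terms - 1)
  sapply(theta, function(th) {
    1 - (4 / pi) * sum((-1)^n / (2 * n + 1) * exp(-(2 * n + 1)^2 * pi^2 * th / 4))
  })
}

#' Time for substrate to diffuse into the centre of a crystal
#'
#' Models the crystal as a slab of half-thickness `travel_um` whose faces are
#' held at the external substrate concentration, interior initially
#' substrate-free, and asks when the centre reaches a given fraction of the
#' face concentration. Solved from the Fourier-series solution of the
#' diffusion equation; the result scales as `travel^2 / D_eff`. With an
#' effective diffusivity appropriate for small ligands in a crystal lattice
#' this gives the sub-millisecond to millisecond into-crystal transport times
#' that motivate micrometre-scale crystals for time-resolved work.
#'
#' @param travel_um Half-thickness of the slab (centre-to-face travel), um.
#' @param d_eff_um2_s Effective in-crystal diffusivity, um^2/s.
#' @param center_fraction Target fraction of the face concentration at the
#'   centre, in (0, 1); default 0.5.
#' @return Time in milliseconds.
#' @examples
#' diffusion_time_into_crystal(1, 1000, 0.5)  # ~0.38 ms
#' @export
diffusion_time_into_crystal <- function(travel_um, d_eff_um2_s,
                                        center_fraction = 0.5) {
  stopifnot(travel_um > 0, d_eff_um2_s > 0)
  if (center_fraction <= 0 || center_fraction >= 1) {
    stop("center_fraction must be in (0, 1)")
  }
  theta <- slab_center_theta(center_fraction)
  1000 * theta * travel_um^2 / d_eff_um2_s
}

# Dimensionless time at which the slab centre reaches `fraction`.
slab_center_theta <- function(fraction) {
  stats::uniroot(function(th) slab_center_fraction(th) - fraction,
                 lower = 1e-8, upper = 50, tol = 1e-12)$root
}

#' Effective diffusivity implied by an into-crystal diffusion time
#'
#' Inverse of [diffusion_time_into_crystal()]: given an observed or quoted
#' time for the crystal centre to reach a fraction of the face concentration,
#' back out the effective diffusivity.
#'
#' @param time_ms Observed time, milliseconds.
#' @inheritParams diffusion_time_into_crystal
#' @return Effective diffusivity in um^2/s.
#' @examples
#' diffusivity_from_time(0.4, 1, 0.5)  # ~950 um^2/s for a 400 us, 1 um travel
#' @export
diffusivity_from_time <- function(time_ms, travel_um, center_fraction = 0.5) {
  stopifnot(time_ms > 0, travel_um > 0)
  if (center_fraction <= 0 || center_fraction >= 1) {
    stop("center_fraction must be in (0, 1)")
  }
  theta <- slab_center_theta(center_fraction)
  1000 * theta * travel_um^2 / time_ms
}

#' Linear fit of crystal length against droplet diameter
#'
#' Convenience wrapper around [stats::lm()] for the empirical linear scaling
#' of crystal length with droplet diameter seen in seeded single-occupancy
#' populations. No coefficients are assumed; the fit is always data-driven.
#'
#' @param length_um Crystal lengths, micrometres.
#' @param diameter_um Matching droplet diameters, micrometres.
#' @return An `lm` object for `length_um ~ diameter_um`.
#' @export
fit_length_diameter <- function(length_um, diameter_um) {
  stopifnot(length(length_um) == length(diameter_um), length(length_um) >= 2)
  stats::lm(length_um ~ diameter_um,
            data = data.frame(length_um = length_um, diameter_um = diameter_um))
}
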