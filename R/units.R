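#' Percentage-weighted mean phospholipid molecular weight
#'
#' Alveolar phospholipid is a mixture of species (PC, PE, PS, PG, SM, CL in the
#' default composition); its effective molecular weight is the arithmetic mean
#' of the species molecular weights weighted by their percentage of total
#' alveolar PL.
#'
#' @param composition data frame with columns `name`, `molecular_weight`
#'   (g/mol) and `percent` (summing to 100).
#' @return Mean molecular weight in g/mol.
#' @examples
#' mean_phospholipid_mw(default_pl_composition())
#' @export
mean_phospholipid_mw <- function(composition) {
  stopifnot(is.data.frame(composition),
            all(c("molecular_weight", "percent") %in% names(composition)))
  if (any(composition$percent < 0)) {
    stop("negative percentage in phospholipid composition")
  }
  if (any(composition$molecular_weight <= 0)) {
    stop("non-positive molecular weight in phospholipid composition")
  }
  if (abs(sum(composition$percent) - 100) > 1e-9) {
    stop("phospholipid percentages must sum to 100")
  }
  sum(composition$molecular_weight * composition$percent) / 100
}

#' Rate constant from a fractional loss over a duration
#'
#' Converts a statement of the form "x percent lost over T minutes" to a
#' first-order rate constant by linear division `fraction / duration`. The
#' linear (not exponential) conversion reproduces the airway-loss constant
#' 2.083e-5 / min from 3 percent over 24 h.
#'
#' @param fraction dimensionless fraction lost, in `[0, 1)`.
#' @param duration_min duration in minutes, positive.
#' @return Rate constant in 1/min.
#' @export
rate_from_fractional_loss <- function(fraction, duration_min) {
  stopifnot(fraction >= 0, fraction < 1)
  if (any(duration_min <= 0)) stop("duration must be positive")
  fraction / duration_min
}

#' Rate constant from a mass flux and a pool size
#'
#' Converts a flux in nmol/h per g lung acting on a pool in umol per g lung to
#' a first-order rate constant in 1/min.
#'
#' @param flux_nmol_h flux in nmol/h per g lung.
#' @param pool_umol pool size in umol per g lung, positive.
#' @return Rate constant in 1/min.
#' @export
rate_from_flux <- function(flux_nmol_h, pool_umol) {
  if (any(pool_umol <= 0)) stop("pool must be positive")
  (flux_nmol_h / 1000) / pool_umol / 60
}

#' Molar density from a mass density
#'
#' @param density_mg_ml mass density in mg/ml.
#' @param mw molecular weight in g/mol, positive.
#' @return Molar density in umol/ml.
#' @export
mass_to_molar_density <- function(density_mg_ml, mw) {
  if (any(mw <= 0)) stop("molecular weight must be positive")
  density_mg_ml * 1000 / mw
}

#' Alveolar fluid volume from body weight
#'
#' Uses the allometric rule of 10 ml of alveolar lining fluid per kg body
#' weight.
#'
#' @param body_weight_g body weight in g, positive.
#' @param ml_per_kg fluid volume coefficient, default 10 ml/kg.
#' @return Alveolar fluid volume in ml.
#' @export
alveolar_fluid_volume <- function(body_weight_g, ml_per_kg = 10) {
  if (any(body_weight_g <= 0)) stop("body weight must be positive")
  ml_per_kg * body_weight_g / 1000
}

#' Particle number from a mass dose
#'
#' Number of monodisperse spheres of a given diameter and material density in
#' a mass of particles.
#'
#' @param mass_ug particle mass in ug.
#' @param diameter_nm particle diameter in nm, positive.
#' @param density_g_cm3 material density in g/cm^3, positive.
#' @return Particle count (dimensionless).
#' @export
np_number_from_mass <- function(mass_ug, diameter_nm, density_g_cm3) {
  if (any(diameter_nm <= 0)) stop("diameter must be positive")
  if (any(density_g_cm3 <= 0)) stop("density must be positive")
  # sphere volume in cm^3: pi/6 d^3, d in cm (1 nm = 1e-7 cm)
  vol_cm3 <- pi / 6 * (diameter_nm * 1e-7)^3
  mass_g <- mass_ug * 1e-6
  mass_g / (density_g_cm3 * vol_cm3)
}
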