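# Nanoparticle-surfactant binding: Michaelis-Menten depletion of interfacial
# phospholipid by free particle surface area, and the area/coating
# bookkeeping that couples particle number to PL mass.

#' Free particle surface area per ml of fluid
#'
#' @param n number density of uncoated particles, count/ml.
#' @param diameter_nm particle diameter, nm.
#' @return Surface area in m^2/ml (`n * pi * d^2 * 1e-18`).
#' @export
free_area <- function(n, diameter_nm) {
  if (any(n < 0) || any(diameter_nm < 0)) stop("inputs must be non-negative")
  n * pi * diameter_nm^2 * 1e-18
}

#' Phospholipid depletion rate by particle binding
#'
#' Michaelis-Menten in the free particle surface area `A`:
#' `V_A * A / (K_A + A)`, saturating at `V_A` (mg of PL per second per ml).
#'
#' @param area free particle surface area, m^2/ml, >= 0.
#' @param spec a `particle_spec` (fields `V_A`, `K_A`), or any list with
#'   those fields.
#' @return PL mass binding rate in mg/s per ml.
#' @export
pl_depletion_rate <- function(area, spec) {
  if (any(area < 0)) stop("negative surface area")
  spec$V_A * area / (spec$K_A + area)
}

#' Convert a bound-PL mass rate to molar units
#'
#' @param rate_mg_s rate in mg/s per ml.
#' @param mw_pl mean phospholipid molecular weight, g/mol.
#' @return Rate in umol/min per ml.
#' @export
pl_rate_to_umol_min <- function(rate_mg_s, mw_pl) {
  rate_mg_s * 60 * 1000 / mw_pl
}

#' Particle surface area released per unit of unbound phospholipid
#'
#' The coat on the particle surface has thickness `delta` and molar density
#' `rho`; losing `dPL` umol/ml of free PL consumes `dA = dPL * 1000 /
#' (delta * rho)` m^2/ml of free particle area (the factor 1000 converts
#' between ml/m^2 and nm).
#'
#' @param d_pl phospholipid amount, umol/ml.
#' @param delta_nm coating thickness, nm, > 0.
#' @param rho_umol_ml surfactant molar density, umol/ml, > 0.
#' @return Area in m^2/ml.
#' @export
area_loss_from_pl_loss <- function(d_pl, delta_nm, rho_umol_ml) {
  if (any(delta_nm <= 0) || any(rho_umol_ml <= 0)) {
    stop("coating thickness and molar density must be positive")
  }
  d_pl * 1000 / (delta_nm * rho_umol_ml)
}

# inverse of area_loss_from_pl_loss
pl_loss_from_area_loss <- function(d_area, delta_nm, rho_umol_ml) {
  d_area * delta_nm * rho_umol_ml / 1000
}

#' Per-particle phospholipid coat capacity
#'
#' Surface area of one particle times coating thickness times molar density;
#' a particle counts as coated once its full capacity of PL is bound.
#'
#' @param spec a `particle_spec`.
#' @param delta_nm coating thickness, nm.
#' @param rho_umol_ml surfactant molar density, umol/ml.
#' @return Capacity in umol of PL per particle.
#' @export
coat_capacity <- function(spec, delta_nm, rho_umol_ml) {
  pl_loss_from_area_loss(free_area(1, spec$diameter_nm), delta_nm, rho_umol_ml)
}

#' Derivatives of the interface/fluid particle number densities
#'
#' Naked particles arrested at the interface are coated by interfacial PL
#' (at the particle-number rate implied by [pl_depletion_rate()] and the
#' per-particle [coat_capacity()], throttled by the availability of
#' interfacial PL) and transfer to the alveolar fluid: coated particles at a
#' fast first-order rate standing in for the per-breath surfactant exchange,
#' naked ones at the fraction `f` per minute. Particle number is conserved
#' exactly.
#'
#' @param np named vector with entries `naked_int`, `coated_int`, `naked_af`,
#'   `coated_af` (count/ml).
#' @param spec a `particle_spec`.
#' @param f naked-particle transfer rate, 1/min.
#' @param k_coated coated-particle transfer rate, 1/min.
#' @param cap per-particle coat capacity, umol.
#' @param mw_pl mean PL molecular weight, g/mol.
#' @param int_pl interfacial PL amount, umol/g lung (availability throttle).
#' @param avail_eps softness of the availability throttle, umol/g lung.
#' @return List with `deriv` (named derivatives, count/ml/min),
#'   `coat_rate` (particles coated, count/ml/min) and `pl_sink_ml`
#'   (PL bound, umol/min per ml).
#' @export
np_interface_rhs <- function(np, spec, f, k_coated, cap, mw_pl,
                             int_pl = Inf, avail_eps = 1e-3) {
  if (any(np < 0)) np <- pmax(np, 0)
  area <- free_area(np[["naked_int"]], spec$diameter_nm)
  avail <- if (is.finite(int_pl)) int_pl / (int_pl + avail_eps) else 1
  pl_sink_ml <- pl_rate_to_umol_min(pl_depletion_rate(area, spec), mw_pl) * avail
  coat_rate <- pl_sink_ml / cap

  d <- c(
    naked_int = -coat_rate - f * np[["naked_int"]],
    coated_int = coat_rate - k_coated * np[["coated_int"]],
    naked_af = f * np[["naked_int"]],
    coated_af = k_coated * np[["coated_int"]]
  )
  list(deriv = d, coat_rate = coat_rate, pl_sink_ml = pl_sink_ml)
}
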