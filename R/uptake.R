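# Cellular uptake of nanoparticles by alveolar type I / type II cells and
# macrophages: adhesion probability, Michaelis-Menten endocytosis /
# phagocytosis, deposition fractions, first-order elimination.

# piecewise-linear interpolant over knots, clamped to the end values
knot_interp <- function(knots, x) {
  stats::approx(knots$x, knots$f, xout = x, rule = 2)$y
}

#' Cell-type properties from the config
#'
#' @param params a `nanolung_params` list.
#' @param type one of `"AT1"`, `"AT2"`, `"Mph"`.
#' @return List of class `cell_type` with porosity `phi`, `diameter_um`,
#'   `gamma`, uptake `V_max`/`K_m`, `count` per lung and the affinity knot
#'   tables.
#' @export
cell_type_props <- function(params, type = c("AT1", "AT2", "Mph")) {
  type <- match.arg(type)
  cc <- params$cells[[type]]
  if (identical(cc$count, "from_morphology")) {
    cc$count <- switch(type,
      AT2 = params$morphology$at2_count_per_g_lung * params$morphology$total_lung_mass_g,
      Mph = params$morphology$macrophage_count,
      stop("no morphology census for ", type))
  }
  cc$label <- type
  structure(cc, class = c("cell_type", "list"))
}

#' Size affinity of particle adhesion
#' @param cell a `cell_type`.
#' @param diameter_nm particle diameter, nm.
#' @return Relative affinity in `[0, 1]`.
#' @export
f_size <- function(cell, diameter_nm) knot_interp(cell$F_size_knots, diameter_nm)

#' Zeta-potential affinity of particle adhesion
#' @param cell a `cell_type`.
#' @param zeta_mV particle surface zeta potential, mV.
#' @return Relative affinity in `[0, 1]`.
#' @export
f_zeta <- function(cell, zeta_mV) knot_interp(cell$F_zeta_knots, zeta_mV)

#' Adhesion probability of a particle onto a cell
#'
#' `P = clamp(gamma (1 - phi) / d_c * F_size(d_p) * F_zeta(zeta), 0, 1)`,
#' where `phi` is the tissue porosity, `d_c` the cell diameter (um) and the
#' scale constant of the underlying adhesion model is absorbed into `gamma`.
#' Surfactant-coated particles carry the corona zeta potential (-39.2 mV by
#' default) instead of the bare-surface value.
#'
#' @param cell a `cell_type`.
#' @param spec a `particle_spec`.
#' @param coated logical; use the coated zeta potential.
#' @return Adhesion probability in `[0, 1]`.
#' @export
adhesion_probability <- function(cell, spec, coated = FALSE) {
  zeta <- if (coated) spec$zeta_coated_mV else spec$zeta_mV
  p <- cell$gamma * (1 - cell$phi) / cell$diameter_um *
    f_size(cell, spec$diameter_nm) * f_zeta(cell, zeta)
  min(max(p, 0), 1)
}

#' Per-cell particle uptake rate
#'
#' Michaelis-Menten endocytosis/phagocytosis gated by adhesion:
#' `P_adh * V_max * n / (K_m + n)` particles per minute per cell.
#'
#' @param n_af particle number density in the alveolar fluid, count/ml.
#' @param cell a `cell_type`.
#' @param p_adh adhesion probability.
#' @return Uptake rate, particles/min/cell.
#' @export
uptake_rate <- function(n_af, cell, p_adh) {
  if (any(n_af < 0)) stop("negative particle density")
  p_adh * cell$V_max * n_af / (cell$K_m + n_af)
}

#' Dose reaching the alveolar model entry
#'
#' Intratracheal instillation passes the pulmonary-entry fraction (52.18%
#' by default); inhalation of 15 nm particles passes the alveolar deposition
#' fraction (40.26%).
#'
#' @param dose_ug administered dose, ug.
#' @param route `"intratracheal"` or `"inhalation"`.
#' @param deposition deposition block of the config.
#' @return Mass reaching the alveolar region, ug.
#' @export
deposited_alveolar_dose <- function(dose_ug, route = c("intratracheal", "inhalation"),
                                    deposition = nanolung_params()$deposition) {
  if (any(dose_ug < 0)) stop("dose must be non-negative")
  route <- match.arg(route)
  frac <- switch(route,
    intratracheal = deposition$intratracheal_pulmonary_fraction,
    inhalation = deposition$inhalation_alveolar_fraction_15nm)
  dose_ug * frac
}

#' First-order elimination sink
#'
#' Lumped removal of particles from the alveolar region (mucociliary,
#' lymphatic and systemic routes) at rate `K_El`.
#'
#' @param n_af particle number density, count/ml.
#' @param k_el elimination rate constant, 1/min, >= 0.
#' @return Elimination rate, particles/min per ml.
#' @export
elimination_sink <- function(n_af, k_el) {
  if (any(k_el < 0)) stop("negative elimination rate constant")
  if (any(n_af < 0)) stop("negative particle density")
  k_el * n_af
}
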