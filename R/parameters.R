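#' Load and validate the packaged parameter set
#'
#' Reads the YAML parameter file shipped with the package (or a user-supplied
#' one with the same layout), checks its structural invariants, and returns a
#' validated nested list of class `nanolung_params`.
#'
#' Validated invariants include: phospholipid percentages summing to 100,
#' strictly positive morphology, non-negative rate constants with no direct
#' secretion for PL and SA, non-negative regulatory constants and reference
#' amounts, porosities in `[0, 1]`, and deposition fractions in `[0, 1]`.
#'
#' @param path path to a YAML parameter file; default is the packaged file.
#' @return A `nanolung_params` list.
#' @export
nanolung_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parameters.yaml", package = "nanolung")
  }
  if (!nzchar(path) || !file.exists(path)) stop("parameter file not found: ", path)
  p <- yaml::read_yaml(path)
  validate_params(p)
  class(p) <- c("nanolung_params", "list")
  p
}

species_names <- function() c("PL", "SA", "C")
compartment_names <- function() c("AT2", "LB", "AF", "Int", "Loss")

need <- function(p, keys) {
  for (k in keys) {
    if (is.null(p[[k]])) stop("parameter file missing required key: ", k)
  }
}

validate_params <- function(p) {
  need(p, c("body_weight_g", "phospholipid_composition", "morphology",
            "regulation", "rates", "rates_literature", "reference_state",
            "film", "surfactant_density", "coating_thickness_nm", "binding",
            "np_transport", "elimination", "deposition", "cells", "particles",
            "cpm_coupling", "solver", "sensitivity_census"))

  comp <- pl_composition_df(p)
  if (abs(sum(comp$percent) - 100) > 1e-9) {
    stop("phospholipid percentages must sum to 100")
  }
  if (any(comp$molecular_weight <= 0)) stop("molecular weights must be positive")

  morph <- p$morphology
  num <- morph[setdiff(names(morph), "units")]
  if (any(unlist(num) <= 0)) stop("morphological parameters must be strictly positive")

  for (proc in c("K_Sec", "K_CSec", "K_LB", "K_Re", "K_Ad", "K_Des", "K_Deg", "K_AW")) {
    row <- p$rates[[proc]]
    if (is.null(row)) stop("rates block missing process ", proc)
    for (sp in species_names()) {
      v <- row[[sp]]
      if (is.null(v)) stop("rates.", proc, " missing species ", sp)
      if (!identical(v, "calibrate") && (!is.numeric(v) || v < 0)) {
        stop("rate constant rates.", proc, ".", sp, " must be >= 0")
      }
    }
  }
  if (p$rates$K_CSec$PL != 0 || p$rates$K_CSec$SA != 0) {
    stop("direct secretion K_CSec exists only for collectins (must be 0 for PL, SA)")
  }

  reg <- p$regulation
  kreg <- unlist(reg[setdiff(names(reg), c("units", "concentration_scale"))])
  if (any(kreg < 0)) stop("regulatory constants must be >= 0")
  if (!reg$concentration_scale %in% c("mol_per_ml", "umol_per_ml")) {
    stop("regulation.concentration_scale must be mol_per_ml or umol_per_ml")
  }

  for (cm in c("AT2", "LB", "AF", "Int")) {
    for (sp in species_names()) {
      v <- p$reference_state[[cm]][[sp]]
      if (is.null(v) || v < 0) stop("reference_state.", cm, ".", sp, " must be >= 0")
    }
  }

  for (surf in c("oxidized", "non_oxidized")) {
    b <- p$binding[[surf]]
    if (b$V_A <= 0 || b$K_A <= 0) stop("binding V_A and K_A must be positive")
  }

  dep <- p$deposition
  fr <- c(dep$intratracheal_pulmonary_fraction, dep$inhalation_alveolar_fraction_15nm)
  if (any(fr < 0 | fr > 1)) stop("deposition fractions must lie in [0, 1]")

  for (ct in c("AT1", "AT2", "Mph")) {
    cc <- p$cells[[ct]]
    if (is.null(cc)) stop("cells block missing cell type ", ct)
    if (cc$phi < 0 || cc$phi > 1) stop("tissue porosity must lie in [0, 1]")
    if (cc$diameter_um <= 0) stop("cell diameter must be positive")
    for (kn in c("F_size_knots", "F_zeta_knots")) {
      k <- cc[[kn]]
      if (any(k$f < 0 | k$f > 1)) stop(ct, " ", kn, " values must lie in [0, 1]")
      if (is.unsorted(k$x, strictly = TRUE)) stop(ct, " ", kn, " x must be increasing")
    }
  }
  invisible(TRUE)
}

#' Phospholipid composition as a data frame
#' @param params a `nanolung_params` list.
#' @return data frame with columns name, molecular_weight, percent.
#' @export
pl_composition_df <- function(params) {
  sp <- params$phospholipid_composition$species
  data.frame(
    name = vapply(sp, `[[`, "", "name"),
    molecular_weight = vapply(sp, `[[`, 0, "molecular_weight"),
    percent = vapply(sp, `[[`, 0, "percent")
  )
}

#' Default phospholipid composition
#' @return data frame of the packaged six-species composition.
#' @export
default_pl_composition <- function() pl_composition_df(nanolung_params())

#' Write a parameter set back to YAML
#'
#' Values round-trip exactly: numbers are emitted with 17 significant digits so
#' re-reading reproduces the identical doubles.
#'
#' @param params a `nanolung_params` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  writeLines(yaml::as.yaml(unclass(params), precision = 17), path)
  invisible(path)
}

#' Look up a particle specification
#'
#' @param params a `nanolung_params` list.
#' @param name particle name in the config (e.g. "nAg", "CB").
#' @return list of class `particle_spec` with fields `material`, `diameter_nm`,
#'   `density_g_cm3`, `zeta_mV`, `zeta_coated_mV`, `oxidized`, `V_A`, `K_A`.
#' @export
particle_spec <- function(params, name) {
  ps <- params$particles[[name]]
  if (is.null(ps)) stop("unknown particle: ", name)
  surf <- if (isTRUE(ps$oxidized)) "oxidized" else "non_oxidized"
  ps$V_A <- params$binding[[surf]]$V_A
  ps$K_A <- params$binding[[surf]]$K_A
  ps$name <- name
  if (ps$diameter_nm <= 0) stop("particle diameter must be positive")
  structure(ps, class = c("particle_spec", "list"))
}

# Conversion factor from amount (umol/g lung) to AF concentration (umol/ml).
af_concentration_factor <- function(params) {
  v_af <- alveolar_fluid_volume(params$body_weight_g,
                                params$morphology$alveolar_fluid_ml_per_kg_bw)
  params$morphology$total_lung_mass_g / v_af
}

# get/set a dotted path like "rates.K_Deg.PL" in a nested list
get_by_path <- function(x, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) x <- x[[k]]
  x
}
set_by_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(keys) == 1) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1]]] <- set_by_path(x[[keys[1]]], paste(keys[-1], collapse = "."), value)
  x
}
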