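# One-at-a-time local sensitivity analysis: normalized elasticities of the
# alveolar-fluid outputs with respect to the model constants.

#' Normalized local sensitivity index
#'
#' `S = ((V_changed - V_orig)/V_orig) / ((p_changed - p_orig)/p_orig)`:
#' the relative output change per relative parameter change (elasticity).
#'
#' @param v_changed,v_orig output values with changed / original parameter.
#' @param p_changed,p_orig changed / original parameter values.
#' @param name optional parameter name for error messages.
#' @return Sensitivity index (dimensionless).
#' @export
sensitivity_index <- function(v_changed, v_orig, p_changed, p_orig,
                              name = "parameter") {
  if (any(v_orig == 0)) stop("zero baseline output for ", name)
  if (any(p_orig == 0)) stop("zero baseline value for ", name)
  if (any(p_changed == p_orig)) stop("degenerate (zero) perturbation for ", name)
  ((v_changed - v_orig) / v_orig) / ((p_changed - p_orig) / p_orig)
}

sensitivity_outputs <- function(sim, output_time_min) {
  s <- sim$series
  i <- which.min(abs(s$time - output_time_min))
  c(PL_AF = s$PL_AF[i], SA_AF = s$SA_AF[i], C_AF = s$C_AF[i], NP_AF = s$np_af[i])
}

# Apply a multiplicative perturbation to one census parameter inside a built
# context. Post-calibration constants are perturbed directly (Gen, the derived
# M_eq and K_Deg values are model constants at simulation time); morphology
# perturbations rebuild the derived transport quantities without recalibrating.
perturb_context <- function(ctx, path, factor) {
  scn <- ctx$scn
  if (startsWith(path, "rates.")) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    ctx$model$K[[parts[2]]][[parts[3]]] <-
      ctx$model$K[[parts[2]]][[parts[3]]] * factor
  } else if (startsWith(path, "regulation.")) {
    key <- sub("regulation.", "", path, fixed = TRUE)
    ctx$model$reg[[key]] <- ctx$model$reg[[key]] * factor
  } else if (startsWith(path, "M_eq.")) {
    sp <- sub("M_eq.", "", path, fixed = TRUE)
    ctx$model$M_eq[[sp]] <- ctx$model$M_eq[[sp]] * factor
  } else if (path == "elimination.K_El") {
    ctx$k_el <- ctx$k_el * factor
  } else if (path == "np_transport.f_naked") {
    ctx$f_naked <- ctx$f_naked * factor
  } else if (startsWith(path, "particle.")) {
    key <- sub("particle.", "", path, fixed = TRUE)
    ctx$spec[[key]] <- ctx$spec[[key]] * factor
    scn$spec <- ctx$spec
    ctx <- rebuild_derived(ctx, scn)
  } else if (startsWith(path, "morphology.")) {
    key <- sub("morphology.", "", path, fixed = TRUE)
    params <- ctx$params
    params$morphology[[key]] <- params$morphology[[key]] * factor
    ctx$params <- params
    ctx$model$conc_factor <- af_concentration_factor(params)
    ctx <- rebuild_derived(ctx, scn)
  } else {
    stop("unknown sensitivity parameter path: ", path)
  }
  ctx
}

# recompute quantities derived from params/spec, keeping the calibrated model
rebuild_derived <- function(ctx, scn) {
  params <- ctx$params
  ctx$v_af <- alveolar_fluid_volume(scn$body_weight_g,
                                    params$morphology$alveolar_fluid_ml_per_kg_bw)
  ctx$lung_mass <- params$morphology$total_lung_mass_g
  ctx$cells <- lapply(c(AT1 = "AT1", AT2 = "AT2", Mph = "Mph"),
                      function(ct) cell_type_props(params, ct))
  ctx$cap <- coat_capacity(ctx$spec, params$coating_thickness_nm, ctx$rho_umol_ml)
  ctx$deposited_mass_ug <- deposited_alveolar_dose(
    scn$dose_ug_per_g * scn$body_weight_g, scn$route, params$deposition)
  ctx$n0 <- np_number_from_mass(ctx$deposited_mass_ug, ctx$spec$diameter_nm,
                                ctx$spec$density_g_cm3) / ctx$v_af
  ctx
}

# baseline value of a census parameter, for reporting
census_value <- function(ctx, path) {
  if (startsWith(path, "rates.")) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    return(ctx$model$K[[parts[2]]][[parts[3]]])
  }
  if (startsWith(path, "regulation.")) {
    return(ctx$model$reg[[sub("regulation.", "", path, fixed = TRUE)]])
  }
  if (startsWith(path, "M_eq.")) {
    return(ctx$model$M_eq[[sub("M_eq.", "", path, fixed = TRUE)]])
  }
  if (path == "elimination.K_El") return(ctx$k_el)
  if (path == "np_transport.f_naked") return(ctx$f_naked)
  if (startsWith(path, "particle.")) {
    return(ctx$spec[[sub("particle.", "", path, fixed = TRUE)]])
  }
  if (startsWith(path, "morphology.")) {
    return(ctx$params$morphology[[sub("morphology.", "", path, fixed = TRUE)]])
  }
  stop("unknown sensitivity parameter path: ", path)
}

#' Census of sensitivity parameters
#'
#' @param params a `nanolung_params` list.
#' @return Data frame with columns `parameter` and `group` (physiological,
#'   biochemical, particle-specific); 10 + 30 + 6 = 46 rows by default.
#' @export
sensitivity_census <- function(params = nanolung_params()) {
  cen <- params$sensitivity_census
  data.frame(
    parameter = c(cen$physiological, cen$biochemical, cen$particle_specific),
    group = rep(c("physiological", "biochemical", "particle-specific"),
                c(length(cen$physiological), length(cen$biochemical),
                  length(cen$particle_specific)))
  )
}

#' One-at-a-time local sensitivity analysis
#'
#' Runs the default dosing scenario once at baseline and once per perturbed
#' parameter (one forward simulation each, post-calibration constants
#' perturbed multiplicatively), and evaluates the sensitivity index of four
#' alveolar-fluid outputs — free PL, SA and C amounts and the particle number
#' density — at the output time.
#'
#' @param params a `nanolung_params` list.
#' @param perturbation relative perturbation (default +10%).
#' @param output_day output time, days post dose.
#' @param particle,dose_ug_per_g scenario of interest (defaults: nAg at
#'   0.5 ug/g, the high-dose silver scenario).
#' @param parameters optional character subset of census parameter paths.
#' @param output_step_min output grid for the underlying runs.
#' @return Data frame of class `sensitivity_result`: one row per parameter x
#'   output with columns `parameter`, `group`, `output`, `S`, `perturbation`,
#'   `output_time_min`, and `note` ("ok" or the failure reason).
#' @export
run_sensitivity <- function(params = nanolung_params(), perturbation = 0.1,
                            output_day = 3, particle = "nAg",
                            dose_ug_per_g = 0.5, parameters = NULL,
                            output_step_min = 60) {
  if (perturbation == 0) stop("zero perturbation fraction is degenerate")
  census <- sensitivity_census(params)
  if (!is.null(parameters)) {
    census <- census[census$parameter %in% parameters, , drop = FALSE]
    if (nrow(census) == 0) stop("no census parameters match the subset")
  }
  scn <- scenario(particle = particle, dose_ug_per_g = dose_ug_per_g,
                  post_days = output_day, output_step_min = output_step_min,
                  params = params)
  ctx0 <- scenario_context(scn)
  t_out <- output_day * 1440
  base <- sensitivity_outputs(run_scenario(scn, ctx = ctx0), t_out)

  rows <- list()
  for (i in seq_len(nrow(census))) {
    path <- census$parameter[i]
    p0 <- census_value(ctx0, path)
    S <- rep(NA_real_, 4)
    note <- "ok"
    res <- tryCatch({
      ctx1 <- perturb_context(ctx0, path, 1 + perturbation)
      out1 <- sensitivity_outputs(run_scenario(scn, ctx = ctx1), t_out)
      if (p0 == 0) {
        note <- "zero baseline parameter; index undefined"
      } else {
        S <- sensitivity_index(out1, base, p0 * (1 + perturbation), p0, path)
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) note <- res
    rows[[i]] <- data.frame(parameter = path, group = census$group[i],
                            output = names(base), S = unname(S),
                            perturbation = perturbation,
                            output_time_min = t_out, note = note)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_result", "data.frame")
  out
}

#' Write a sensitivity table to CSV
#' @param result a `sensitivity_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
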