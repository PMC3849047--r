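# Shared fixtures, computed once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_params <- function() cached("params", nanolung_params())

default_model <- function() cached("model", surf_model(default_params()))

# 10 ug/g (0.5 ug per g BW) nAg scenario over 7 days, the default exposure
default_sim <- function() cached("sim_nag_high", {
  run_scenario(scenario("nAg", dose_ug_per_g = 0.5, post_days = 7,
                        params = default_params()))
})

low_dose_sim <- function() cached("sim_nag_low", {
  run_scenario(scenario("nAg", dose_ug_per_g = 0.05, post_days = 7,
                        params = default_params()))
})

cb_sim <- function() cached("sim_cb_high", {
  run_scenario(scenario("CB", dose_ug_per_g = 0.5, post_days = 7,
                        params = default_params()))
})

# conversion factor amount (umol/g lung) -> AF concentration (umol/ml)
conc_factor <- function(params = default_params()) {
  params$morphology$total_lung_mass_g /
    (params$morphology$alveolar_fluid_ml_per_kg_bw * params$body_weight_g / 1000)
}

table4_state <- function(model = default_model()) {
  m <- rbind(model$ref, Loss = c(0, 0, 0))
  x <- as.vector(m[c("AT2", "LB", "AF", "Int", "Loss"), ])
  names(x) <- as.vector(outer(c("AT2", "LB", "AF", "Int", "Loss"),
                              c("PL", "SA", "C"),
                              function(cm, sp) paste(sp, cm, sep = "_")))
  x
}

non_loss <- function(x) x[!grepl("_Loss$", names(x))]
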