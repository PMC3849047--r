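# Five-compartment, three-species surfactant mass-balance model.
#
# Species: PL (phospholipids), SA (surface-active proteins SP-B/SP-C),
# C (collectins SP-A/SP-D). Compartments: AT2 (type II cell pool), LB
# (lamellar bodies), AF (alveolar fluid / hypophase), Int (air-liquid
# interface), Loss (absorbing sink for degradation + airway loss).
# Amounts in umol per g lung, time in minutes.

state_names <- function() {
  as.vector(outer(compartment_names(), species_names(),
                  function(cm, sp) paste(sp, cm, sep = "_")))
}

# Assemble a named 15-state vector from a 5 x 3 layout (compartment x species)
make_state <- function(mat) {
  stopifnot(nrow(mat) == 5, ncol(mat) == 3)
  x <- as.vector(mat)
  names(x) <- state_names()
  x
}

state_matrix <- function(state) {
  matrix(state, nrow = 5, ncol = 3,
         dimnames = list(compartment_names(), species_names()))
}

#' Effective rate constant under linear regulation
#'
#' Delivery processes are modulated by regulator concentrations through
#' linear-in-concentration factors: activation multiplies the base rate by
#' `1 + sum(k * conc)`, inhibition divides by the same factor (which keeps
#' inhibited rates positive). With all regulator concentrations zero the base
#' rate is returned unchanged.
#'
#' @param base base rate constant (1/min), >= 0.
#' @param mode `"activation"` or `"inhibition"`.
#' @param conc regulator concentrations (umol/ml), non-negative vector.
#' @param k regulatory constants (per umol/ml), non-negative vector matching
#'   `conc`.
#' @return Effective rate constant (1/min).
#' @export
regulated_rate <- function(base, mode = c("activation", "inhibition"), conc, k) {
  mode <- match.arg(mode)
  stopifnot(base >= 0, length(conc) == length(k))
  if (any(conc < 0)) stop("negative regulator concentration")
  if (any(k < 0)) stop("negative regulatory constant")
  factor <- 1 + sum(k * conc)
  if (mode == "activation") base * factor else base / factor
}

#' Adsorption flux of a surfactant component onto the interface
#'
#' Bulk surfactant adsorbs onto the air-liquid interface at a rate
#' proportional to the bulk amount, throttled linearly by film occupancy:
#' `K_Ad * M_bulk * max(0, 1 - M_surf / M_eq)`. `M_eq` is the equilibrium
#' surface amount at which the film saturates (minimum surface tension);
#' the flux is never negative.
#'
#' @param bulk bulk (hypophase) amount, umol/g lung.
#' @param surface current surface amount, umol/g lung.
#' @param m_eq equilibrium surface amount, umol/g lung, > 0 (may be `Inf`).
#' @param rate adsorption rate constant, 1/min.
#' @return Flux in umol/min per g lung.
#' @export
adsorption_flux <- function(bulk, surface, m_eq, rate) {
  if (any(m_eq <= 0)) stop("equilibrium surface amount must be positive")
  rate * bulk * pmax(0, 1 - surface / m_eq)
}

# Regulator concentration values as they enter the regulation factors.
# `scale` is 1e-6 when factors are evaluated on the mol/ml scale.
regulator_conc <- function(model, af_amounts) {
  af_amounts * model$conc_factor * model$reg_scale
}

# Starred (regulated) rate constants at given AF amounts (umol/g, named).
regulated_rates <- function(model, af_amounts) {
  cc <- regulator_conc(model, af_amounts)
  reg <- model$reg
  f_sec <- 1 + reg$k_secretion_inhibition_C * cc[["C"]]
  f_ad  <- 1 + reg$k_adsorption_SA * cc[["SA"]] + reg$k_adsorption_C * cc[["C"]]
  f_re  <- 1 + reg$k_recycle_activation_C * cc[["C"]]
  list(K_Sec = model$K$K_Sec / f_sec,
       K_Ad  = model$K$K_Ad * f_ad,
       K_Re  = model$K$K_Re * f_re)
}

#' Generation closure for the type II cell balance
#'
#' The generation term is chosen so that the AT2 pool is stationary at the
#' reference state: `Gen_i = (K_Sec_i* + K_CSec_i) AT2_i - K_Re_i* AF_i`,
#' with the starred rates regulated at the reference alveolar-fluid
#' concentrations. A negative closure (net consumption) triggers a warning
#' but is returned as computed.
#'
#' @param model a `surf_model` (see [surf_model()]).
#' @param ref optional 4 x 3 reference matrix (AT2, LB, AF, Int rows); default
#'   the model's reference state.
#' @return Named per-species generation fluxes, umol/min per g lung.
#' @export
generation_closure <- function(model, ref = model$ref) {
  star <- regulated_rates(model, ref["AF", ])
  gen <- (star$K_Sec + model$K$K_CSec) * ref["AT2", ] - star$K_Re * ref["AF", ]
  if (any(gen < 0)) {
    warning("generation closure negative for: ",
            paste(names(gen)[gen < 0], collapse = ", "))
  }
  gen
}

#' Build a calibrated surfactant model
#'
#' Assembles the rate table, regulatory constants, reference state and derived
#' quantities into a simulation-ready object. Calibration steps:
#' \itemize{
#'   \item Degradation constants marked `calibrate` in the config are closed
#'     from the alveolar-fluid steady-state balance (with the lamellar-body
#'     pool treated as pass-through): `K_Deg = Gen/AF_ref - K_AW`.
#'   \item `Gen` is closed from the AT2 balance ([generation_closure()]).
#'   \item `M_eq` is closed from the interface balance where the film factor
#'     `K_Des Int / (K_Ad* AF)` is below 1; otherwise it falls back to
#'     `m_eq_fallback_ratio` times the reference interface amount.
#' }
#'
#' @param params a `nanolung_params` list (default: packaged parameters).
#' @param m_eq optional per-species override of the equilibrium interface
#'   amounts (may be `Inf` to linearise the adsorption term).
#' @param gen optional per-species override of the generation fluxes.
#' @param regulation_off set all regulatory constants to zero.
#' @return An object of class `surf_model`.
#' @export
surf_model <- function(params = nanolung_params(), m_eq = NULL, gen = NULL,
                       regulation_off = FALSE) {
  sp <- species_names()
  K <- lapply(params$rates[c("K_Sec", "K_CSec", "K_LB", "K_Re", "K_Ad",
                             "K_Des", "K_Deg", "K_AW")], function(row) {
    v <- vapply(sp, function(s) {
      x <- row[[s]]
      if (identical(x, "calibrate")) NA_real_ else as.numeric(x)
    }, 0)
    v
  })

  reg <- params$regulation
  if (regulation_off) {
    reg$k_adsorption_SA <- reg$k_adsorption_C <- 0
    reg$k_secretion_inhibition_C <- reg$k_recycle_activation_C <- 0
  }
  ref <- sapply(sp, function(s) {
    c(AT2 = params$reference_state$AT2[[s]], LB = params$reference_state$LB[[s]],
      AF = params$reference_state$AF[[s]], Int = params$reference_state$Int[[s]])
  })

  model <- list(
    K = K,
    reg = reg,
    reg_scale = if (identical(reg$concentration_scale, "umol_per_ml")) 1 else 1e-6,
    conc_factor = af_concentration_factor(params),
    ref = ref,
    params = params
  )

  # close degradation from the AF balance where requested
  star <- regulated_rates(model, ref["AF", ])
  gen_cl <- (star$K_Sec + model$K$K_CSec) * ref["AT2", ] - star$K_Re * ref["AF", ]
  kdeg <- model$K$K_Deg
  needs <- is.na(kdeg)
  if (any(needs)) {
    cand <- gen_cl / ref["AF", ] - model$K$K_AW
    if (any(cand[needs] < 0)) {
      warning("calibrated K_Deg negative for: ",
              paste(sp[needs & cand < 0], collapse = ", "), "; flooring at 0")
      cand <- pmax(cand, 0)
    }
    kdeg[needs] <- cand[needs]
    model$K$K_Deg <- kdeg
  }

  model$Gen <- if (is.null(gen)) generation_closure(model) else gen

  if (is.null(m_eq)) {
    occ <- model$K$K_Des * ref["Int", ] / (star$K_Ad * ref["AF", ])
    m_eq <- ifelse(occ < 1, ref["Int", ] / (1 - occ),
                   params$film$m_eq_fallback_ratio * ref["Int", ])
    names(m_eq) <- sp
  }
  model$M_eq <- m_eq

  class(model) <- c("surf_model", "list")
  model
}

#' Time-derivatives of the 15 surfactant states
#'
#' Mass balances, per species i:
#' \deqn{dAT2/dt = Gen + K_{Re}^* AF - (K_{Sec}^* + K_{CSec}) AT2}
#' \deqn{dLB/dt  = K_{Sec}^* AT2 - K_{LB} LB}
#' \deqn{dAF/dt  = K_{LB} LB + K_{CSec} AT2 + K_{Des} Int - J_{Ad}
#'                - (K_{Re}^* + K_{Deg} + K_{AW}) AF}
#' \deqn{dInt/dt = J_{Ad} - K_{Des} Int - J_{NP}}
#' \deqn{dLoss/dt = (K_{Deg} + K_{AW}) AF}
#' with \eqn{J_{Ad}} the [adsorption_flux()] and \eqn{J_{NP}} an optional
#' nanoparticle-binding sink on interfacial PL. Summed over all five
#' compartments the derivatives equal `Gen` exactly (Loss is absorbing).
#'
#' @param state named 15-vector (see `surf_steady_state` for the layout).
#' @param model a `surf_model`.
#' @param np_sink_int per-species sink on the interface pool (umol/min/g),
#'   default zero.
#' @return Named vector of 15 derivatives, umol/min per g lung.
#' @export
surfactant_rhs <- function(state, model, np_sink_int = c(PL = 0, SA = 0, C = 0)) {
  if (length(state) != 15) stop("state must have exactly 15 entries")
  m <- state_matrix(pmax(state, 0))
  star <- regulated_rates(model, m["AF", ])
  K <- model$K

  j_ad <- adsorption_flux(m["AF", ], m["Int", ], model$M_eq, star$K_Ad)
  d <- matrix(0, 5, 3, dimnames = dimnames(m))
  d["AT2", ] <- model$Gen + star$K_Re * m["AF", ] -
    (star$K_Sec + K$K_CSec) * m["AT2", ]
  d["LB", ] <- star$K_Sec * m["AT2", ] - K$K_LB * m["LB", ]
  d["AF", ] <- K$K_LB * m["LB", ] + K$K_CSec * m["AT2", ] +
    K$K_Des * m["Int", ] - j_ad -
    (star$K_Re + K$K_Deg + K$K_AW) * m["AF", ]
  d["Int", ] <- j_ad - K$K_Des * m["Int", ] - np_sink_int[species_names()]
  d["Loss", ] <- (K$K_Deg + K$K_AW) * m["AF", ]
  make_state(d)
}

#' Constructed steady state of a calibrated model
#'
#' Returns the fixed point implied by the calibration: AT2 and AF at their
#' reference amounts, LB at its pass-through value `K_Sec* AT2 / K_LB`, Int at
#' the root of the interface balance, Loss at zero. For a model with
#' closure-derived `Gen` and `K_Deg` all non-Loss balances vanish exactly at
#' this state (Loss is absorbing and accumulates).
#'
#' @param model a `surf_model`.
#' @return Named 15-vector, umol/g lung.
#' @export
surf_steady_state <- function(model) {
  ref <- model$ref
  star <- regulated_rates(model, ref["AF", ])
  a <- star$K_Ad * ref["AF", ]
  int_star <- ifelse(is.finite(model$M_eq),
                     a * model$M_eq / (model$K$K_Des * model$M_eq + a),
                     a / model$K$K_Des)
  m <- rbind(AT2 = ref["AT2", ],
             LB = star$K_Sec * ref["AT2", ] / model$K$K_LB,
             AF = ref["AF", ],
             Int = int_star,
             Loss = c(0, 0, 0))
  make_state(m)
}

#' Integrate the surfactant model
#'
#' Stiff integration (lsoda) with the packaged tolerances. Fluxes are
#' evaluated on the non-negative part of the state, which guards the
#' trajectories against negative amounts.
#'
#' @param model a `surf_model`.
#' @param times output times in minutes.
#' @param init initial named 15-vector; defaults to [surf_steady_state()].
#' @param rtol,atol solver tolerances; default from the config.
#' @return A matrix with a `time` column and the 15 state columns.
#' @export
surf_simulate <- function(model, times, init = surf_steady_state(model),
                          rtol = model$params$solver$rtol,
                          atol = model$params$solver$atol) {
  rhs <- function(t, y, parms) list(surfactant_rhs(y, model))
  out <- deSolve::lsoda(y = init, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) {
    stop("surfactant integration failed at t = ", utils::tail(out[, 1], 1))
  }
  unclass(out)
}
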