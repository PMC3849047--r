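# Steady-state estimation of non-identifiable rate constants and constrained
# refinement of the full rate table.

#' Estimate non-identifiable rate constants from the reference steady state
#'
#' Desorption, degradation and (for collectins) the direct-secretion constant
#' are not available from the literature; they are closed from the
#' steady-state balances of the alveolar fluid and the interface at the
#' reference amounts. The lamellar-body pool is treated as pass-through
#' (its throughput equals AT2 secretion), since it has no biological steady
#' state. Per species the balances are:
#' \itemize{
#'   \item AF: `(K_Sec* + K_CSec) AT2 = (K_Re* + K_Deg + K_AW) AF`
#'   \item Int: `K_Ad* AF (1 - Int/M_eq) = K_Des Int`
#' }
#' `K_Deg` is solved from the AF balance, except for collectins when a
#' literature `k_deg_C` is supplied, in which case `K_CSec` is solved instead.
#' `K_Des` is solved from the Int balance given `M_eq` (or `M_eq` from the
#' balance given `K_Des` when `m_eq` is `NULL` and `k_des` supplied).
#'
#' @param model a `surf_model` carrying the known rates and regulation; its
#'   `K_Deg`/`K_Des` entries are ignored for the estimated species.
#' @param ref 4 x 3 reference matrix (AT2, LB, AF, Int rows); default from the
#'   model.
#' @param m_eq per-species equilibrium interface amounts used in the Int
#'   balance; if `NULL`, `k_des` must be given and `M_eq` is solved for.
#' @param k_des known desorption constant(s) (recycled to 3), used when
#'   `m_eq` is `NULL`.
#' @param k_deg_C optional literature degradation constant for collectins;
#'   when given, the collectin AF balance is solved for `K_CSec` instead.
#' @return List with per-species `K_Des`, `K_Deg`, `M_eq` and scalar
#'   `K_CSec_C` (NA unless solved).
#' @export
estimate_missing_rates <- function(model, ref = model$ref, m_eq = NULL,
                                   k_des = NULL, k_deg_C = NULL) {
  sp <- species_names()
  star <- regulated_rates(model, ref["AF", ])
  at2 <- ref["AT2", ]; af <- ref["AF", ]; int <- ref["Int", ]
  if (any(af <= 0)) stop("AF balance singular: zero alveolar-fluid reference amount")

  inflow <- (star$K_Sec + model$K$K_CSec) * at2
  k_deg <- inflow / af - star$K_Re - model$K$K_AW
  k_csec_c <- NA_real_

  if (!is.null(k_deg_C)) {
    # collectin AF balance solved for direct secretion instead
    k_deg[["C"]] <- k_deg_C
    k_csec_c <- ((star$K_Re[["C"]] + k_deg_C + model$K$K_AW[["C"]]) * af[["C"]] -
                   star$K_Sec[["C"]] * at2[["C"]]) / at2[["C"]]
    if (k_csec_c < 0) {
      stop("AF balance for collectins inconsistent: implied K_CSec is negative")
    }
  }
  if (any(k_deg < 0)) {
    stop("AF balance inconsistent: implied K_Deg negative for ",
         paste(sp[k_deg < 0], collapse = ", "))
  }

  ad_max <- star$K_Ad * af
  if (is.null(m_eq)) {
    if (is.null(k_des)) stop("supply either m_eq or k_des for the Int balance")
    k_des <- rep_len(k_des, 3); names(k_des) <- sp
    occ <- k_des * int / ad_max
    if (any(occ >= 1)) {
      stop("Int balance infeasible: desorption outflow exceeds maximal ",
           "adsorption inflow for ", paste(sp[occ >= 1], collapse = ", "))
    }
    m_eq <- int / (1 - occ)
  } else {
    m_eq <- rep_len(m_eq, 3); names(m_eq) <- sp
    k_des <- ad_max * pmax(0, 1 - int / m_eq) / int
  }
  list(K_Des = k_des, K_Deg = k_deg, M_eq = m_eq, K_CSec_C = k_csec_c)
}

# Stationarity residuals of the non-Loss balances at `ref_state`, expressed
# as relative drift per day (dimensionless, O(1) when visibly non-stationary).
stationarity_residuals <- function(model, ref_state) {
  d <- surfactant_rhs(ref_state, model)
  keep <- !grepl("_Loss$", names(d))
  scale <- pmax(abs(ref_state[keep]), 1e-6)
  1440 * d[keep] / scale
}

#' Constrained refinement of the rate table
#'
#' Minimises the squared stationarity residuals of the 12 non-Loss balances
#' at a reference state (each expressed as relative drift per day, so the
#' residual scale is dimensionless), plus a quadratic penalty on log-deviation
#' from the initial estimates, over the positive rate constants within
#' multiplicative bounds. Generation and equilibrium amounts are held at
#' their closure values from the initial model. Optimisation is L-BFGS-B on
#' the log-rates.
#'
#' @param model a `surf_model` whose rates provide the initial point.
#' @param ref_state named 15-vector at which stationarity is enforced;
#'   default [surf_steady_state()] of the initial model.
#' @param bounds multiplicative bounds `c(lower, upper)` around the initial
#'   rates.
#' @param lambda weight of the log-deviation penalty.
#' @return List with the refined `model`, `objective` at start and optimum,
#'   optimiser `convergence` code and `residual` (root-sum-square
#'   stationarity residual at the optimum).
#' @export
refine_parameters <- function(model, ref_state = surf_steady_state(model),
                              bounds = c(0.1, 10), lambda = 1e-2) {
  procs <- c("K_Sec", "K_CSec", "K_LB", "K_Re", "K_Ad", "K_Des", "K_Deg", "K_AW")
  init <- unlist(model$K[procs])
  free <- init > 0                      # structural zeros stay zero
  theta0 <- log(init[free])

  rebuild <- function(theta) {
    v <- init
    v[free] <- exp(theta)
    m <- model
    for (p in procs) {
      m$K[[p]] <- v[paste(p, species_names(), sep = ".")]
      names(m$K[[p]]) <- species_names()
    }
    m
  }
  objective <- function(theta) {
    m <- rebuild(theta)
    sum(stationarity_residuals(m, ref_state)^2) + lambda * sum((theta - theta0)^2)
  }

  f0 <- objective(theta0)
  opt <- stats::optim(theta0, objective, method = "L-BFGS-B",
                      lower = theta0 + log(bounds[1]),
                      upper = theta0 + log(bounds[2]),
                      control = list(maxit = 500))
  if (opt$value > f0 + 1e-12) {
    # never return a worse point than the initial estimates
    opt$par <- theta0
    opt$value <- f0
  }
  refined <- rebuild(opt$par)
  res <- sqrt(sum(stationarity_residuals(refined, ref_state)^2))
  if (opt$convergence != 0 && res > 1e-6) {
    warning("refinement did not converge (code ", opt$convergence,
            "); final stationarity residual ", signif(res, 4))
  }
  list(model = refined, objective = c(initial = f0, optimum = opt$value),
       convergence = opt$convergence, residual = res)
}
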