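# Constant Phase Model of respiratory impedance, its surfactant-coupled
# modification, spectrum fitting and synthetic-spectrum generation.
#
# Z(omega) = R + i omega I + (G - iH) / omega^alpha,
# alpha = (2/pi) atan(H/G): the tissue term has frequency-independent phase.

#' Constant-phase exponent from tissue damping and elastance
#'
#' @param G tissue damping, cmH2O/ml, > 0.
#' @param H tissue elastance, cmH2O/ml, >= 0.
#' @return `alpha = (2/pi) atan(H/G)`, in `[0, 1)`.
#' @export
cpm_alpha <- function(G, H) {
  if (any(G <= 0)) stop("tissue damping G must be positive")
  if (any(H < 0)) stop("tissue elastance H must be non-negative")
  (2 / pi) * atan(H / G)
}

#' Constant Phase Model parameter set
#'
#' @param R Newtonian (airway) resistance, cmH2O.s/ml.
#' @param I inertance, cmH2O.s^2/ml.
#' @param G tissue damping, cmH2O/ml.
#' @param H tissue elastance, cmH2O/ml.
#' @param peep optional PEEP level, cmH2O (metadata).
#' @param k_R,k_G,k_H surfactant coupling coefficients (dimensionless).
#' @return List of class `cpm_params` (with derived `alpha`).
#' @export
cpm_params <- function(R, I, G, H, peep = NA_real_,
                       k_R = 0, k_G = 0, k_H = 0) {
  stopifnot(G >= 0, H >= 0)
  structure(list(R = R, I = I, G = G, H = H,
                 alpha = if (G > 0) cpm_alpha(G, H) else 0,
                 peep = peep, k_R = k_R, k_G = k_G, k_H = k_H),
            class = c("cpm_params", "list"))
}

#' Forward impedance spectrum of the Constant Phase Model
#'
#' @param freq_hz strictly positive, increasing oscillation frequencies (Hz);
#'   converted internally to angular frequency `omega = 2 pi f` (rad/s).
#' @param params a `cpm_params`.
#' @return Data frame of class `impedance_spectrum` with columns
#'   `frequency_hz`, `re_z`, `im_z` (cmH2O.s/ml).
#' @export
cpm_impedance <- function(freq_hz, params) {
  if (any(freq_hz <= 0)) stop("frequencies must be strictly positive")
  if (is.unsorted(freq_hz, strictly = TRUE)) stop("frequencies must be increasing")
  w <- 2 * pi * freq_hz
  a <- params$alpha
  tis <- if (params$G == 0 && params$H == 0) 0 else w^(-a)
  structure(
    data.frame(frequency_hz = freq_hz,
               re_z = params$R + params$G * tis,
               im_z = w * params$I - params$H * tis),
    class = c("impedance_spectrum", "data.frame"))
}

#' Respiratory resistance and elastance from an impedance spectrum
#'
#' `Rrs = Re Z`; `Ers = -omega Im Z`, so that a positive tissue elastance
#' yields positive Ers at low frequency (for the CPM,
#' `Ers = H omega^(1-alpha) - omega^2 I`).
#'
#' @param spectrum an `impedance_spectrum`.
#' @return Data frame with `frequency_hz`, `rrs`, `ers`.
#' @export
rrs_ers <- function(spectrum) {
  w <- 2 * pi * spectrum$frequency_hz
  data.frame(frequency_hz = spectrum$frequency_hz,
             rrs = spectrum$re_z,
             ers = -w * spectrum$im_z)
}

# inverse of rrs_ers
rrs_ers_to_spectrum <- function(df) {
  w <- 2 * pi * df$frequency_hz
  structure(data.frame(frequency_hz = df$frequency_hz,
                       re_z = df$rrs, im_z = -df$ers / w),
            class = c("impedance_spectrum", "data.frame"))
}

#' Surfactant-modified CPM parameters
#'
#' A deficit in interfacial surfactant raises the tissue parameters linearly:
#' `X* = X (1 + k_X dCs)` for `X` in `R, G, H`, where
#' `dCs = (Cs_ref - Cs)/Cs_ref` is the relative interfacial phospholipid
#' deficit versus the control steady state (zero at control, positive under
#' depletion). `alpha` is recomputed from the modified `G`, `H`.
#'
#' @param params a `cpm_params` with coupling coefficients.
#' @param d_cs dimensionless surfactant deficit.
#' @return Modified `cpm_params`.
#' @export
surfactant_modified_params <- function(params, d_cs) {
  stopifnot(is.finite(d_cs))
  cpm_params(R = params$R * (1 + params$k_R * d_cs),
             I = params$I,
             G = params$G * (1 + params$k_G * d_cs),
             H = params$H * (1 + params$k_H * d_cs),
             peep = params$peep,
             k_R = params$k_R, k_G = params$k_G, k_H = params$k_H)
}

#' Fit the Constant Phase Model to a measured impedance spectrum
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the stacked real and
#' imaginary residuals over frequency, with unit weights, for the four free
#' parameters R, I, G, H (`alpha` derived from G and H throughout).
#'
#' @param spectrum an `impedance_spectrum` with at least 4 frequencies.
#' @param start starting `cpm_params` (or list with R, I, G, H); default is a
#'   crude moment-based guess from the spectrum.
#' @param lower,upper named bounds on `c(R, I, G, H)`.
#' @return Object of class `cpm_fit`: fitted parameters (`coef()`), the
#'   input spectrum, fitted values, residuals and convergence information.
#' @export
cpm_fit <- function(spectrum, start = NULL,
                    lower = c(R = 0, I = 0, G = 1e-8, H = 0),
                    upper = c(R = Inf, I = Inf, G = Inf, H = Inf)) {
  if (nrow(spectrum) < 4) {
    stop("spectrum underdetermined: need >= 4 frequencies for 4 parameters")
  }
  if (is.null(start)) {
    w <- 2 * pi * spectrum$frequency_hz
    re <- spectrum$re_z
    start <- list(R = max(min(re), 1e-3),
                  I = max(utils::tail(spectrum$im_z, 1) / utils::tail(w, 1), 1e-6),
                  G = max(diff(range(re)), 0.1), H = max(-spectrum$im_z[1] * w[1], 0.1))
  }
  obs <- c(spectrum$re_z, spectrum$im_z)
  resid_fun <- function(p) {
    pr <- cpm_params(p[["R"]], p[["I"]], p[["G"]], p[["H"]])
    z <- cpm_impedance(spectrum$frequency_hz, pr)
    c(z$re_z, z$im_z) - obs
  }
  p0 <- unlist(start[c("R", "I", "G", "H")])
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun,
                            lower = lower[names(p0)], upper = upper[names(p0)],
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit$info == 0 || fit$info == 9) {
    warning("CPM fit did not converge (info ", fit$info, "), residual norm ",
            signif(sqrt(fit$deviance), 4))
  }
  cf <- fit$par
  pars <- cpm_params(cf[["R"]], cf[["I"]], cf[["G"]], cf[["H"]])
  zfit <- cpm_impedance(spectrum$frequency_hz, pars)
  structure(list(params = pars, spectrum = spectrum, fitted = zfit,
                 residuals = resid_fun(cf), deviance = fit$deviance,
                 start = p0, info = fit$info),
            class = "cpm_fit")
}

#' @export
coef.cpm_fit <- function(object, ...) {
  with(object$params, c(R = R, I = I, G = G, H = H, alpha = alpha))
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat("Constant Phase Model fit (", nrow(x$spectrum), " frequencies)\n", sep = "")
  print(signif(coef(x), 6))
  cat("residual norm:", signif(sqrt(x$deviance), 4), "\n")
  invisible(x)
}

#' @export
summary.cpm_fit <- function(object, ...) {
  out <- list(coef = coef(object),
              rss = object$deviance,
              rmse = sqrt(object$deviance / length(object$residuals)),
              n_freq = nrow(object$spectrum))
  class(out) <- "summary.cpm_fit"
  out
}

#' @export
print.summary.cpm_fit <- function(x, ...) {
  cat("CPM fit over", x$n_freq, "frequencies\n")
  print(signif(x$coef, 6))
  cat("RSS:", signif(x$rss, 4), " RMSE:", signif(x$rmse, 4), "\n")
  invisible(x)
}

#' @export
predict.cpm_fit <- function(object, newdata = NULL, ...) {
  freq <- if (is.null(newdata)) object$spectrum$frequency_hz else newdata$frequency_hz
  cpm_impedance(freq, object$params)
}

#' @export
residuals.cpm_fit <- function(object, ...) object$residuals

#' Fit surfactant coupling coefficients from paired control/treated fits
#'
#' Given fitted CPM parameters for control and treated groups at matching
#' time points and the surfactant deficit trajectory, estimates each
#' coupling coefficient as the least-squares slope through the origin of
#' `X*/X - 1` against `dCs`.
#'
#' @param control,treated data frames with columns `day`, `R`, `G`, `H`
#'   (fitted parameters per day).
#' @param d_cs numeric vector of surfactant deficits per day (matching rows).
#' @return Named vector `c(k_R, k_G, k_H)`.
#' @export
fit_coupling_coefficients <- function(control, treated, d_cs) {
  stopifnot(nrow(control) == nrow(treated), length(d_cs) == nrow(control))
  if (all(d_cs == 0)) stop("all-zero surfactant deficit: coefficients unidentifiable")
  k <- vapply(c("R", "G", "H"), function(X) {
    y <- treated[[X]] / control[[X]] - 1
    sum(d_cs * y) / sum(d_cs^2)
  }, 0)
  names(k) <- paste0("k_", c("R", "G", "H"))
  k
}

#' Generate a synthetic impedance spectrum
#'
#' Forward CPM evaluation plus i.i.d. Gaussian noise on the real and
#' imaginary parts. Deterministic given `seed`; the global RNG state is
#' restored on exit.
#'
#' @param params a `cpm_params`.
#' @param freq_hz frequency grid, Hz.
#' @param noise_sd noise standard deviation, cmH2O.s/ml, >= 0.
#' @param seed integer seed.
#' @return An `impedance_spectrum`.
#' @export
generate_synthetic_spectrum <- function(params, freq_hz, noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0)
  z <- cpm_impedance(freq_hz, params)
  if (noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
    z$re_z <- z$re_z + stats::rnorm(nrow(z), sd = noise_sd)
    z$im_z <- z$im_z + stats::rnorm(nrow(z), sd = noise_sd)
  }
  z
}

#' Read an impedance spectrum file
#'
#' CSV with columns `frequency_hz`, `re_z`, `im_z` and optional metadata
#' columns `peep_cmh2o`, `day`, `group`.
#'
#' @param path CSV path.
#' @return An `impedance_spectrum` data frame.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frequency_hz", "re_z", "im_z")
  if (!all(need %in% names(df))) {
    stop("spectrum file must carry columns: ", paste(need, collapse = ", "))
  }
  structure(df, class = c("impedance_spectrum", "data.frame"))
}

#' Write an impedance spectrum file
#' @param spectrum an `impedance_spectrum`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
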