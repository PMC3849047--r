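phys_params <- function(seed) {
  set.seed(seed)
  cpm_params(R = runif(1, 0.2, 1.5), I = runif(1, 0.001, 0.02),
             G = runif(1, 2, 8), H = runif(1, 10, 60))
}

test_that("the constant-phase exponent follows (2/pi) atan(H/G)", {
  expect_equal(cpm_alpha(3, 3), 0.5)
  expect_equal(cpm_alpha(5, 0), 0)
  expect_equal(cpm_alpha(1, 10), 2 / pi * atan(10))
  expect_equal(cpm_alpha(1, 10), 0.93655, tolerance = 1e-5)
  expect_error(cpm_alpha(0, 5), "positive")
})

test_that("forward impedance reduces to R + i omega I without tissue and matches the modulus identity", {
  f <- c(1, 2, 5, 10, 20)
  w <- 2 * pi * f
  z0 <- cpm_impedance(f, cpm_params(R = 0.5, I = 0.01, G = 0, H = 0))
  expect_equal(z0$re_z, rep(0.5, 5))
  expect_equal(z0$im_z, w * 0.01)

  pr <- phys_params(1)
  z <- cpm_impedance(f, pr)
  expect_equal(sqrt(z$re_z^2 + z$im_z^2), Mod(complex(real = z$re_z, imaginary = z$im_z)))
  expect_error(cpm_impedance(c(0, 1), pr), "positive")
})

test_that("the tissue term has frequency-independent phase over four decades", {
  pr <- phys_params(2)
  w <- 10^seq(-1, 3, length.out = 41)
  tis <- complex(real = pr$G, imaginary = -pr$H) / w^pr$alpha
  phase <- Arg(tis)
  expect_lt(max(abs(phase - phase[1])), 1e-12)
})

test_that("resistance/elastance conversion is sign-correct and invertible", {
  f <- c(0.5, 1, 3, 9, 20)
  pr <- cpm_params(R = 0.4, I = 0, G = 4, H = 30)
  re <- rrs_ers(cpm_impedance(f, pr))
  w <- 2 * pi * f
  expect_true(all(re$ers > 0))
  expect_equal(re$ers, pr$H * w^(1 - pr$alpha))   # I = 0 closed form
  # Rrs does not depend on inertance
  pr2 <- cpm_params(R = 0.4, I = 0.05, G = 4, H = 30)
  expect_equal(rrs_ers(cpm_impedance(f, pr2))$rrs, re$rrs)
  # roundtrip spectrum -> (Rrs, Ers) -> spectrum
  z <- cpm_impedance(f, pr2)
  back <- nanolung:::rrs_ers_to_spectrum(rrs_ers(z))
  expect_equal(back$re_z, z$re_z)
  expect_equal(back$im_z, z$im_z)
})

test_that("surfactant deficit modifies R, G, H linearly and preserves alpha when k_G = k_H", {
  pr <- cpm_params(R = 0.5, I = 0.01, G = 4, H = 30, k_R = 0.2, k_G = 0.3, k_H = 0.1)
  expect_equal(coef_vec <- unlist(surfactant_modified_params(pr, 0)[c("R", "G", "H")]),
               c(R = 0.5, G = 4, H = 30))
  pr_h <- cpm_params(R = 1, I = 0.01, G = 4, H = 30, k_H = 0.1)
  expect_equal(surfactant_modified_params(pr_h, 0.5)$H, 30 * 1.05)
  pr_eq <- cpm_params(R = 1, I = 0.01, G = 4, H = 30, k_G = 0.4, k_H = 0.4)
  expect_equal(surfactant_modified_params(pr_eq, 0.7)$alpha, pr_eq$alpha)
  # positive coupling raises Rrs and Ers at every frequency
  f <- c(1, 3, 10, 20)
  pr_all <- cpm_params(R = 1, I = 0.01, G = 4, H = 30, k_R = .2, k_G = .2, k_H = .2)
  re0 <- rrs_ers(cpm_impedance(f, pr_all))
  re1 <- rrs_ers(cpm_impedance(f, surfactant_modified_params(pr_all, 0.5)))
  expect_true(all(re1$rrs > re0$rrs))
  expect_true(all(re1$ers > re0$ers))
})

test_that("CPM fitting recovers generating parameters from noiseless spectra", {
  f <- seq(0.5, 20, length.out = 15)
  for (seed in c(4, 8, 15)) {
    pr <- phys_params(seed)
    fit <- cpm_fit(cpm_impedance(f, pr))
    cf <- coef(fit)
    truth <- c(R = pr$R, I = pr$I, G = pr$G, H = pr$H)
    expect_equal(cf[names(truth)], truth, tolerance = 1e-3)
  }
  expect_error(cpm_fit(cpm_impedance(c(1, 2, 3), phys_params(1))), "underdetermined")
})

test_that("parameter recovery under 5% noise is unbiased to within 5% over 50 replicates", {
  f <- seq(0.5, 20, length.out = 15)
  pr <- cpm_params(R = 0.6, I = 0.01, G = 4, H = 35)
  truth <- c(R = pr$R, I = pr$I, G = pr$G, H = pr$H)
  sd_noise <- 0.05 * mean(abs(cpm_impedance(f, pr)$re_z))
  est <- t(vapply(1:50, function(i) {
    sp <- generate_synthetic_spectrum(pr, f, noise_sd = sd_noise, seed = 1000 + i)
    coef(cpm_fit(sp))[names(truth)]
  }, truth))
  bias <- abs(colMeans(est) - truth) / truth
  expect_lt(max(bias[c("R", "G", "H")]), 0.05)
  # recovery degrades gracefully with noise (seeded sweep on H)
  rmse_h <- vapply(c(0.01, 0.05, 0.15), function(frac) {
    sdn <- frac * mean(abs(cpm_impedance(f, pr)$re_z))
    hh <- vapply(1:20, function(i) {
      coef(cpm_fit(generate_synthetic_spectrum(pr, f, sdn, seed = 500 + i)))[["H"]]
    }, 0)
    sqrt(mean((hh - pr$H)^2))
  }, 0)
  expect_true(all(diff(rmse_h) > 0))
})

test_that("doubling R in the data shifts only the fitted R", {
  f <- seq(0.5, 20, length.out = 15)
  pr <- cpm_params(R = 0.6, I = 0.01, G = 4, H = 35)
  z2 <- cpm_impedance(f, cpm_params(R = 1.2, I = 0.01, G = 4, H = 35))
  cf <- coef(cpm_fit(z2))
  expect_equal(cf[["R"]], 1.2, tolerance = 1e-3)
  expect_equal(cf[["I"]], 0.01, tolerance = 1e-2)
  expect_equal(cf[["G"]], 4, tolerance = 1e-2)
  expect_equal(cf[["H"]], 35, tolerance = 1e-2)
})

test_that("coupling coefficients are recovered exactly from noiseless synthetic groups", {
  k_true <- c(k_R = 0.15, k_G = 0.6, k_H = 0.35)
  d_cs <- c(0.8, 0.4, 0.1)
  control <- data.frame(day = c(1, 3, 7), R = 0.6, G = 4, H = 35)
  treated <- control
  for (X in c("R", "G", "H")) {
    treated[[X]] <- control[[X]] * (1 + k_true[[paste0("k_", X)]] * d_cs)
  }
  expect_equal(fit_coupling_coefficients(control, treated, d_cs), k_true)
  # treated identical to control -> zero coefficients
  expect_equal(unname(fit_coupling_coefficients(control, control, d_cs)), c(0, 0, 0))
  expect_error(fit_coupling_coefficients(control, treated, c(0, 0, 0)), "all-zero")
})

test_that("synthetic spectra are deterministic in the seed with calibrated noise", {
  pr <- phys_params(3)
  f <- seq(1, 20, length.out = 10)
  expect_equal(generate_synthetic_spectrum(pr, f, 0, seed = 9),
               cpm_impedance(f, pr))
  s1 <- generate_synthetic_spectrum(pr, f, 0.1, seed = 7)
  s2 <- generate_synthetic_spectrum(pr, f, 0.1, seed = 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, generate_synthetic_spectrum(pr, f, 0.1, seed = 8)))

  f_many <- seq(1, 20, length.out = 500)   # 1000 noise draws across re and im
  s <- generate_synthetic_spectrum(pr, f_many, 0.2, seed = 11)
  z <- cpm_impedance(f_many, pr)
  emp <- stats::sd(c(s$re_z - z$re_z, s$im_z - z$im_z))
  expect_lt(abs(emp - 0.2) / 0.2, 0.1)
})

test_that("spectrum files round-trip through CSV with metadata", {
  pr <- phys_params(6)
  sp <- cpm_impedance(seq(1, 15, length.out = 8), pr)
  sp$peep_cmh2o <- 3; sp$day <- 3; sp$group <- "treated"
  tf <- tempfile(fileext = ".csv")
  write_spectrum(sp, tf)
  back <- read_spectrum(tf)
  expect_equal(back$re_z, sp$re_z)
  expect_equal(back$peep_cmh2o, rep(3, 8))
})
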