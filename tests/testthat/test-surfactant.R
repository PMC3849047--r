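# build a regulation-free, saturation-free (linear) model with random rates
random_linear_model <- function(seed) {
  set.seed(seed)
  p <- default_params()
  sp <- c("PL", "SA", "C")
  for (proc in c("K_Sec", "K_LB", "K_Re", "K_Ad", "K_Des", "K_Deg", "K_AW")) {
    v <- runif(3, 1e-5, 5e-3)
    p$rates[[proc]] <- as.list(setNames(v, sp))
  }
  p$rates$K_CSec <- list(PL = 0, SA = 0, C = runif(1, 0, 1e-4))
  surf_model(p, m_eq = setNames(rep(Inf, 3), sp), gen = setNames(numeric(3), sp),
             regulation_off = TRUE)
}

# 15 x 15 generator matrix of the linear (regulation-free, unsaturated) system
linear_matrix <- function(model) {
  A <- matrix(0, 15, 15)
  cm <- c("AT2", "LB", "AF", "Int", "Loss")
  idx <- function(s, c) (s - 1) * 5 + match(c, cm)
  K <- model$K
  for (s in 1:3) {
    A[idx(s, "AT2"), idx(s, "AT2")] <- -(K$K_Sec[s] + K$K_CSec[s])
    A[idx(s, "AT2"), idx(s, "AF")] <- K$K_Re[s]
    A[idx(s, "LB"), idx(s, "AT2")] <- K$K_Sec[s]
    A[idx(s, "LB"), idx(s, "LB")] <- -K$K_LB[s]
    A[idx(s, "AF"), idx(s, "LB")] <- K$K_LB[s]
    A[idx(s, "AF"), idx(s, "AT2")] <- K$K_CSec[s]
    A[idx(s, "AF"), idx(s, "AF")] <-
      -(K$K_Ad[s] + K$K_Re[s] + K$K_Deg[s] + K$K_AW[s])
    A[idx(s, "AF"), idx(s, "Int")] <- K$K_Des[s]
    A[idx(s, "Int"), idx(s, "AF")] <- K$K_Ad[s]
    A[idx(s, "Int"), idx(s, "Int")] <- -K$K_Des[s]
    A[idx(s, "Loss"), idx(s, "AF")] <- K$K_Deg[s] + K$K_AW[s]
  }
  A
}

test_that("regulation leaves rates unchanged without regulators and doubles them at unit forcing", {
  expect_identical(regulated_rate(0.01, "activation", c(0, 0), c(100, 200)), 0.01)
  expect_identical(regulated_rate(0.01, "inhibition", c(0, 0), c(100, 200)), 0.01)
  k <- 7.312e4
  expect_equal(regulated_rate(0.02, "activation", 1 / k, k), 0.04)
  # inhibition stays positive however strong the regulator
  expect_gt(regulated_rate(0.02, "inhibition", 1e3, 1e5), 0)
  expect_error(regulated_rate(0.02, "activation", -1, 10), "negative")
})

test_that("regulated adsorption of SA matches the closed form at reference concentrations", {
  p <- default_params()
  cf <- conc_factor(p)
  c_sa <- 0.0035 * cf
  c_c <- 0.0146 * cf
  oracle <- 0.0402 * (1 + 7.312e4 * c_sa + 2.185e5 * c_c)
  expect_equal(regulated_rate(0.0402, "activation", c(c_sa, c_c),
                              c(7.312e4, 2.185e5)), oracle)
  # model plumbing on the umol/ml scale reproduces the same value
  p$regulation$concentration_scale <- "umol_per_ml"
  m <- suppressWarnings(surf_model(p))
  star <- nanolung:::regulated_rates(m, m$ref["AF", ])
  expect_equal(unname(star$K_Ad[["SA"]]), oracle)
})

test_that("adsorption flux is linear in the free-film fraction and never negative", {
  expect_equal(adsorption_flux(0.08, 1.5, 1.5, 0.01), 0)        # saturated film
  expect_equal(adsorption_flux(0.08, 0, 1.5, 0.01), 0.01 * 0.08) # empty film
  expect_equal(adsorption_flux(0.08, 0.75, 1.5, 0.01),
               0.5 * adsorption_flux(0.08, 0, 1.5, 0.01))
  expect_equal(adsorption_flux(0.08, 3, 1.5, 0.01), 0)          # oversaturated
  expect_error(adsorption_flux(0.08, 1, 0, 0.01), "positive")
})

test_that("generation closure zeroes the AT2 balance and scales with the AT2 pool", {
  m <- default_model()
  gen <- generation_closure(m)
  expect_true(all(gen >= 0))
  d <- surfactant_rhs(surf_steady_state(m), m)
  expect_lt(max(abs(d[grepl("_AT2$", names(d))])), 1e-15)

  # no secretion, no recycle: nothing to generate
  m0 <- m
  m0$K$K_Sec[] <- 0; m0$K$K_CSec[] <- 0; m0$K$K_Re[] <- 0
  expect_equal(unname(generation_closure(m0)), c(0, 0, 0))

  # doubling the AT2 reference doubles the secretion contribution
  ref2 <- m$ref
  ref2["AT2", ] <- 2 * ref2["AT2", ]
  star <- nanolung:::regulated_rates(m, m$ref["AF", ])
  sec <- (star$K_Sec + m$K$K_CSec) * m$ref["AT2", ]
  expect_equal(generation_closure(m, ref2) - generation_closure(m),
               sec, tolerance = 1e-12)
})

test_that("the Loss balance and total-mass conservation hold for arbitrary states", {
  m <- default_model()
  set.seed(42)
  for (i in 1:20) {
    x <- setNames(runif(15, 0, 5), names(surf_steady_state(m)))
    d <- surfactant_rhs(x, m)
    af <- x[grepl("_AF$", names(x))]
    expect_equal(unname(d[grepl("_Loss$", names(d))]),
                 unname((m$K$K_Deg + m$K$K_AW) * af))
    expect_equal(sum(d), sum(m$Gen), tolerance = 1e-12)
  }
  expect_error(surfactant_rhs(runif(10), m), "15")
})

test_that("the model integrates exactly 15 coupled balances and is stationary at its steady state", {
  m <- default_model()
  ss <- surf_steady_state(m)
  expect_length(ss, 15)
  d <- surfactant_rhs(ss, m)
  expect_length(d, 15)
  expect_lt(max(abs(non_loss(d))), 1e-10 * max(ss))
})

test_that("a ten-day integration from steady state drifts less than 1% in every coordinate", {
  m <- default_model()
  ss <- surf_steady_state(m)
  out <- surf_simulate(m, seq(0, 14400, by = 720))
  fin <- out[nrow(out), -1]
  rel <- abs(non_loss(fin) - non_loss(ss)) / non_loss(ss)
  expect_lt(max(rel), 0.01)
})

test_that("the regulation-free unsaturated system obeys superposition", {
  m <- random_linear_model(7)
  x0 <- setNames(runif(15, 0, 2), names(surf_steady_state(m)))
  times <- c(0, 500, 2000)
  s1 <- surf_simulate(m, times, init = x0)
  s2 <- surf_simulate(m, times, init = 2 * x0)
  expect_equal(unname(s2[, -1]), unname(2 * s1[, -1]), tolerance = 1e-6)
})

test_that("the linear subsystem matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (seed in c(3, 19)) {
    m <- random_linear_model(seed)
    A <- linear_matrix(m)
    x0 <- setNames(runif(15, 0.1, 3), names(surf_steady_state(m)))
    t1 <- 800
    num <- surf_simulate(m, c(0, t1), init = x0)[2, -1]
    oracle <- as.numeric(Matrix::expm(A * t1) %*% x0)
    expect_equal(unname(num), oracle, tolerance = 1e-6)
  }
})

test_that("integration from non-negative states never goes negative", {
  m <- default_model()
  set.seed(5)
  for (i in 1:5) {
    x0 <- setNames(runif(15, 0, 3), names(surf_steady_state(m)))
    out <- surf_simulate(m, seq(0, 2000, by = 200), init = x0)
    expect_gt(min(out[, -1]), -1e-8)
  }
})
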