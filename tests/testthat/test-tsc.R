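test_that("salinity normalization scales to 35 psu and rejects degenerate salinity", {
  expect_equal(normalize_salinity(c(0.1, 0.2), 35), c(0.1, 0.2))   # identity at standard S
  expect_equal(normalize_salinity(0.2, 17.5), 0.4)
  expect_equal(normalize_salinity(0.3, 30), 0.35)
  expect_error(normalize_salinity(0.3, 0), "positive")
  expect_error(normalize_salinity(0.3, -2), "positive")
  # normalizing twice is the same as normalizing once
  A <- c(0.1, 0.5)
  expect_equal(normalize_salinity(normalize_salinity(A, 31), 35),
               normalize_salinity(A, 31))
})

# build a calibration table whose absorbance is an exact polynomial in the
# normalized coordinates the fit will construct, so planted coefficients are
# recoverable
planted_cal <- function(coef, wl = seq(208, 260, by = 1), temps = seq(4, 25, by = 3)) {
  W <- rep(wl, each = length(temps))
  Tv <- rep(temps, times = length(wl))
  Wn <- (W - mean(W)) / sd(W)
  Tn <- (Tv - mean(Tv)) / sd(Tv)
  dW <- nrow(coef) - 1; dT <- ncol(coef) - 1
  y <- numeric(length(W))
  for (j in 0:dT) for (i in 0:dW) y <- y + coef[i + 1, j + 1] * Wn^i * Tn^j
  A <- matrix(y, nrow = length(temps), ncol = length(wl))
  sample_table(sprintf("c%02d", seq_along(temps)), wl, A, temps,
               rep(35, length(temps)), rep(0, length(temps)))
}

test_that("the LNS surface fit recovers a planted polynomial exactly", {
  coef <- matrix(c(0.8, -0.3, 0.05, 0.01,
                   0.12, 0.02, -0.004, 0.001,
                   -0.01, 0.003, 0.0006, -2e-4), nrow = 4)
  cal <- planted_cal(coef)
  fit <- fit_lns_surface(cal, degrees = c(3, 2))
  expect_equal(fit$coef, coef, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(fit$sse, 1e-10)

  # constant absorbance: intercept only
  const <- planted_cal(matrix(c(0.5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), nrow = 4))
  fitc <- fit_lns_surface(const, degrees = c(3, 2))
  expect_equal(fitc$coef[1, 1], 0.5, tolerance = 1e-10)
  expect_equal(fitc$coef[-1], rep(0, 11), tolerance = 1e-10)
})

test_that("surface evaluation matches hand-evaluated polynomials", {
  m <- structure(list(w_mean = 230, w_sd = 10, t_mean = 15, t_sd = 5,
                      degrees = c(3L, 1L),
                      coef = matrix(c(1, 2, -0.5, 0.25, 0.1, 0, 0.3, -0.05), nrow = 4)),
                 class = "lns_model")
  wn <- (236 - 230) / 10; tn <- (18 - 15) / 5
  hand <- 1 + 2 * wn - 0.5 * wn^2 + 0.25 * wn^3 +
    tn * (0.1 + 0 * wn + 0.3 * wn^2 - 0.05 * wn^3)
  expect_equal(predict_lns(m, 236, 18), hand, tolerance = 1e-12)
  # intercept-only model is constant everywhere
  m0 <- m; m0$coef[] <- 0; m0$coef[1, 1] <- 0.7
  expect_equal(predict_lns(m0, c(210, 240, 260), c(4, 15, 25)), rep(0.7, 3))
  # an exact fit reproduces its calibration values at the calibration points
  coef <- matrix(c(0.6, -0.2, 0.03, 0.005, 0.1, 0.01, -0.002, 3e-4), nrow = 4)
  cal <- planted_cal(coef)
  fit <- fit_lns_surface(cal, degrees = c(3, 1))
  expect_equal(predict_lns(fit, rep(cal$wavelengths[5], 2), cal$temperature[c(1, 4)]),
               cal$absorbance[c(1, 4), 5], tolerance = 1e-8)
})

test_that("rank-deficient LNS designs are refused with advice", {
  cal <- planted_cal(matrix(c(0.5, 0.1, 0, 0), nrow = 2),
                     temps = c(10, 20))  # 2 temperatures only
  expect_error(fit_lns_surface(cal, degrees = c(3, 2)), "lower")
  expect_error(fit_lns_surface(planted_cal(matrix(c(0.5, 0.1, 0, 0), nrow = 2),
                                           temps = 10), degrees = c(1, 1)),
               "2 temperatures")
})

test_that("absorptivity rescaling and sea-salt subtraction follow the elementwise algebra", {
  expect_equal(molar_absorptivity(0.02, 0.4, 0.2), 0.04)
  expect_equal(molar_absorptivity(c(0.02, 0.03), c(0.2, 0.3), c(0.2, 0.3)),
               c(0.02, 0.03))  # measured == model leaves E_cal untouched
  set.seed(4)
  E <- matrix(runif(20, 0.01, 0.05), 4)
  Am <- matrix(runif(20, 0.5, 1), 4)
  Ao <- matrix(runif(20, 0.5, 1), 4)
  loop <- E
  for (i in 1:4) for (j in 1:5) loop[i, j] <- E[i, j] * Am[i, j] / Ao[i, j]
  expect_equal(molar_absorptivity(E, Am, Ao), loop, tolerance = 1e-12)
  expect_error(molar_absorptivity(0.02, 0.4, 1e-12), "tolerance")

  expect_equal(sea_salt_absorbance(0.01, 35), 0.35)
  expect_equal(sea_salt_absorbance(c(0.01, 0.02), 0), c(0, 0))
  loop2 <- E * 31.5
  expect_equal(sea_salt_absorbance(E, 31.5), loop2, tolerance = 1e-12)
  expect_error(sea_salt_absorbance(E, -1))

  expect_equal(remove_sea_salt(c(0.4, 0.5), c(0.4, 0.5)), c(0, 0))
  expect_error(remove_sea_salt(c(0.4, 0.5), 0.4), "mismatch")
  # negative residuals are preserved, not clipped
  expect_equal(remove_sea_salt(c(0.1, 0.2), c(0.3, 0.1)), c(-0.2, 0.1))
})

test_that("sea-salt removal recovers the pure nitrate spectrum by superposition", {
  lib <- seawater_library()
  grid <- seq(208, 260, by = 0.4)
  full <- forward_absorbance(lib, list(nitrate = 50e-6, humate = 0),
                             T = 12, S = 32, grid = grid)$values
  salt <- forward_absorbance(lib, list(nitrate = 0, humate = 0),
                             T = 12, S = 32, grid = grid)$values
  nitrate <- forward_absorbance(
    lib, list(nitrate = 50e-6, humate = 0, NaCl = 0, MgSO4 = 0, NaHCO3 = 0,
              NaBr = 0, NaNO2 = 0),
    T = 12, S = 32, grid = grid)$values
  expect_equal(remove_sea_salt(full, salt), nitrate, tolerance = 1e-10)
})

test_that("CDOM removal is exact for affine tails and recovers planted lines", {
  grid <- seq(208, 262, by = 0.4)
  line <- 0.05 - 1e-4 * grid
  out <- remove_cdom(uv_spectrum(grid, line))
  expect_equal(out$spectrum$values, rep(0, length(out$spectrum$wavelengths)),
               tolerance = 1e-12)
  expect_equal(unname(out$coefficients), c(0.05, -1e-4), tolerance = 1e-10)

  # nitrate-like band (zero at >= 240 nm) riding on a line is recovered
  band <- pmax(exp(-((grid - 212) / 8)^2) - exp(-((240 - 212) / 8)^2), 0) * (grid < 240)
  out2 <- remove_cdom(uv_spectrum(grid, band + line))
  keep <- grid >= 208 & grid <= 240
  expect_equal(out2$spectrum$values, band[keep], tolerance = 1e-10)
  expect_error(remove_cdom(uv_spectrum(grid, band), fit_window = c(300, 301)),
               "fewer than 2")
})

test_that("the full correction chain zeroes nitrate-free samples and is temperature-invariant for nitrate", {
  lib <- seawater_library()
  cal <- generate_lns_calibration(lib, 4:25, noise = FALSE)
  tsc <- fit_tsc(cal)
  # zero-nitrate, zero-CDOM samples at unseen temperatures vanish
  probe <- generate_lns_calibration(lib, seq(4.5, 24.5, by = 2.5), noise = FALSE)
  corr <- apply_tsc(tsc, probe)
  expect_lt(max(abs(corr$absorbance)), 1e-8)
  expect_equal(range(corr$wavelengths), c(208, 240))

  # nitrate + salt at fixed S: the corrected spectrum does not depend on T
  grid <- default_grid()
  Ts <- seq(4, 25, by = 3)
  A <- t(vapply(Ts, function(tt)
    forward_absorbance(lib, list(nitrate = 50e-6, humate = 0),
                       T = tt, S = 32, grid = grid)$values,
    numeric(length(grid))))
  tab <- sample_table(paste0("s", seq_along(Ts)), grid, A, Ts,
                      rep(32, length(Ts)), rep(50, length(Ts)))
  cc <- apply_tsc(tsc, tab)$absorbance
  expect_lt(max(abs(sweep(cc, 2, cc[1, ]))), 1e-8)
})

test_that("applying the correction to already-corrected salt-free spectra changes nothing", {
  lib <- seawater_library()
  tsc <- fit_tsc(generate_lns_calibration(lib, 4:25, noise = FALSE))
  grid <- default_grid()
  pure <- forward_absorbance(
    lib, list(nitrate = 40e-6, humate = 0, NaCl = 0, MgSO4 = 0, NaHCO3 = 0,
              NaBr = 0, NaNO2 = 0), T = 15, S = 0, grid = grid)$values
  tab <- sample_table("p", grid, matrix(pure, 1), 15, 0, 40)
  once <- apply_tsc(tsc, tab)
  keep <- grid >= 208 & grid <= 240
  expect_equal(once$absorbance[1, ], pure[keep], tolerance = 1e-10)
})
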