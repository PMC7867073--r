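test_that("absorbance follows the dark-corrected Beer-Lambert definition", {
  grid <- c(210, 220, 230)
  sp <- function(v) uv_spectrum(grid, rep(v, 3), kind = "intensity")
  # identical beams attenuate nothing
  expect_equal(compute_absorbance(sp(900), sp(900))$values, rep(0, 3))
  # one decade of attenuation
  expect_equal(compute_absorbance(sp(100), sp(1000))$values, rep(1, 3))
  # dark current subtracted from both beams
  expect_equal(compute_absorbance(sp(190), sp(1900), dark = 90)$values,
               rep(-log10(100 / 1810), 3))
  # per-wavelength dark spectrum accepted too
  dk <- uv_spectrum(grid, c(90, 80, 70), kind = "intensity")
  expect_equal(compute_absorbance(sp(190), sp(1900), dark = dk)$values[2],
               -log10(110 / 1820))
  out <- compute_absorbance(sp(100), sp(1000))
  expect_s3_class(out, "uv_spectrum")
  expect_identical(out$kind, "absorbance")
})

test_that("non-positive dark-corrected intensities raise an error naming the wavelength", {
  grid <- c(210, 220.5, 230)
  smp <- uv_spectrum(grid, c(500, 50, 500), kind = "intensity")
  ref <- uv_spectrum(grid, rep(1000, 3), kind = "intensity")
  expect_error(compute_absorbance(smp, ref, dark = 60), "220\\.5")
  expect_error(compute_absorbance(ref, smp, dark = 60), "220\\.5")
})

test_that("absorbance is monotone decreasing in sample intensity and zero for the reference itself", {
  grid <- seq(210, 214, by = 1)
  ref <- uv_spectrum(grid, rep(2000, 5), kind = "intensity")
  for (dark in c(0, 10, 150)) {
    expect_equal(compute_absorbance(ref, ref, dark)$values, rep(0, 5))
    a_prev <- Inf
    for (I in c(200, 500, 900, 1500)) {
      a <- compute_absorbance(uv_spectrum(grid, rep(I, 5), "intensity"), ref, dark)$values[1]
      expect_lt(a, a_prev)
      a_prev <- a
    }
  }
})

test_that("window selection keeps the closed interval and is idempotent", {
  grid <- default_grid()
  tab <- sample_table("a", grid, matrix(seq_along(grid), 1), 10, 33, 5)
  win <- select_window(tab, 208, 240)
  expect_length(win$wavelengths, 81)
  expect_equal(range(win$wavelengths), c(208, 240))
  expect_equal(select_window(win, 208, 240), win)
  # spanning the whole grid is the identity
  expect_equal(select_window(tab, 100, 400), tab)
  # a window with no grid points errors
  tab_int <- sample_table("a", 200:260, matrix(0, 1, 61), 10, 33, 5)
  expect_error(select_window(tab_int, 300.2, 300.9), "grid point")
  expect_error(select_window(tab, 240, 208))
})

test_that("nearest-wavelength alignment selects without interpolating, ties to the lower wavelength", {
  tab <- sample_table("a", c(210.0, 210.4), matrix(c(1, 2), 1), 10, 33, NA)
  expect_equal(align_nearest(tab, c(210.1, 210.4))$absorbance[1, 1], 1)   # nearest
  expect_equal(align_nearest(tab, c(210.2, 210.4))$absorbance[1, 1], 1)   # tie rule
  tab2 <- random_table()
  expect_equal(align_nearest(tab2, tab2$wavelengths), tab2)               # identity
  twice <- align_nearest(align_nearest(tab2, c(208.1, 209.3, 211.2)),
                         c(208.1, 209.3, 211.2))
  expect_equal(twice, align_nearest(tab2, c(208.1, 209.3, 211.2)))        # idempotent
  expect_error(align_nearest(tab2, c(100, 210)), "span")
})

test_that("spectra CSV round-trips within 1e-12 and rejects malformed files", {
  tab <- random_table(n = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(tab, path)
  back <- read_spectra_csv(path)
  expect_equal(back$absorbance, tab$absorbance, tolerance = 1e-12)
  expect_equal(back$temperature, tab$temperature, tolerance = 1e-12)
  expect_equal(back$salinity, tab$salinity, tolerance = 1e-12)
  expect_equal(back$reference_conc, tab$reference_conc, tolerance = 1e-12)
  expect_identical(back$ids, tab$ids)

  # missing required column
  df <- utils::read.csv(path, check.names = FALSE)
  df$temperature_C <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_spectra_csv(p2), "temperature_C")

  # non-numeric cell reported with row and column
  df <- utils::read.csv(path, check.names = FALSE)
  df$salinity_psu[3] <- "thirty"
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p3, row.names = FALSE, quote = FALSE)
  expect_error(read_spectra_csv(p3), "row 3.*salinity_psu")
})

test_that("model JSON round-trips reproduce predictions bit-identically", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  Xn <- matrix(rnorm(12), 3, 4)
  path <- withr::local_tempfile(fileext = ".json")

  m <- fit_kpls(X, y, kernel_spec("rbf"), n_components = 3)
  save_model(m, path)
  expect_identical(predict_kpls(load_model(path), Xn), predict_kpls(m, Xn))

  wa <- fit_wa_kpls(X, y, kernel_spec("linear"), n_components = 2, eta = 80, D = 3)
  save_model(wa, path)
  expect_identical(predict_wa_kpls(load_model(path), Xn), predict_wa_kpls(wa, Xn))

  lib <- seawater_library()
  cal <- generate_lns_calibration(lib, seq(4, 24, by = 4))
  tsc <- fit_tsc(cal)
  save_model(tsc, path)
  tab <- generate_samples(lib, 3, noise = FALSE, seed = 5)
  expect_identical(apply_tsc(load_model(path), tab)$absorbance,
                   apply_tsc(tsc, tab)$absorbance)
})
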