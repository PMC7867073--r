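# Scripted experiment workflows: the full three-method benchmark on seeded
# synthetic seawater, and the out-of-range extrapolation study.

#' Default benchmark configuration
#'
#' The default problem mirrors the reference study conditions: 600 training
#' and 200 test samples, nitrate 0-100 umol/L, temperature 4-25 degC,
#' salinity 30-35 psu, spectrometer noise at SNR 1000:1, an LNS calibration
#' series at 1-degC steps over 4-25 degC, modeling window 208-240 nm, CDOM
#' window 240-260 nm, degree-(3,2) LNS surface, RBF kernel with
#' median-heuristic gamma, component count chosen by the training-R^2 >=
#' 0.9995 rule, and a D = 20 / eta = 80% ensemble.
#'
#' @param seed Master seed; the calibration, training and test draws use
#'   `seed`, `seed + 1` and `seed + 2`.
#' @param ... Overrides for any configuration entry.
#' @return A named list.
#' @export
benchmark_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    n_train = 600, n_test = 200,
    conc_range = c(0, 100), T_range = c(4, 25), S_range = c(30, 35),
    noise = TRUE,
    cal_T = 4:25, cal_noise = TRUE,
    degrees = c(3, 2), model_window = c(208, 240), cdom_window = c(240, 260),
    kernel = "rbf", gamma = NULL,
    n_components = NULL, r2_threshold = 0.9995, a_max = 20,
    eta = 80, D = 20, weight_basis = "train",
    methods = c("wa-kpls", "mlr", "isus"),
    tolerances = c(2),
    isus_window = c(217, 240)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration entr%s: %s",
                 if (length(unknown) > 1) "ies" else "y",
                 paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Entries absent from the file keep their [benchmark_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(benchmark_config, c(list(seed = raw$seed %||% 1),
                              raw[setdiff(names(raw), "seed")]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# nitrate absorbance per umol/L on a grid, from the library's forward model
.nitrate_unit_spectrum <- function(lib, grid) {
  a1 <- forward_absorbance(lib, list(nitrate = 1e-6, humate = 0), T = 20, S = 0,
                           grid = grid)$values
  a0 <- forward_absorbance(lib, list(nitrate = 0, humate = 0), T = 20, S = 0,
                           grid = grid)$values
  a1 - a0
}

#' Run the full synthetic three-method benchmark
#'
#' Generates an LNS calibration series and labeled training/test sets from
#' the synthetic library, fits the TSC model, then fits and evaluates every
#' requested method: `"wa-kpls"` (TSC + weighted-average kernel PLS),
#' `"mlr"` (TSC + ordinary least squares) and `"isus"` (raw-absorbance
#' exponential-seawater retrieval with linear recalibration on the training
#' set). Identical configurations produce identical outputs.
#'
#' @param config A configuration list from [benchmark_config()] /
#'   [read_config()], or a path to a YAML file.
#' @param lib Optional `component_library`; defaults to [seawater_library()].
#' @return A `benchmark_result` list: `reports` (one `eval_report` per
#'   method, when the test set is labeled), `predictions` (one vector per
#'   method), `n_components`, `test`, `tsc`, `config`.
#' @export
run_benchmark <- function(config = benchmark_config(), lib = seawater_library()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(benchmark_config, config)
  cal <- generate_lns_calibration(lib, cfg$cal_T, seed = cfg$seed,
                                  noise = cfg$cal_noise)
  train <- generate_samples(lib, cfg$n_train, cfg$conc_range, cfg$T_range,
                            cfg$S_range, noise = cfg$noise, seed = cfg$seed + 1)
  test <- generate_samples(lib, cfg$n_test, cfg$conc_range, cfg$T_range,
                           cfg$S_range, noise = cfg$noise, seed = cfg$seed + 2)
  evaluate_methods(train, test, cal, cfg, lib)
}

#' Fit and evaluate the configured methods on given tables
#'
#' The workhorse behind [run_benchmark()]; usable directly with measured
#' data read via [read_spectra_csv()].
#'
#' @param train Labeled training `sample_table`.
#' @param test Test `sample_table` (metrics are skipped when unlabeled).
#' @param cal Zero-nitrate calibration `sample_table`.
#' @param cfg Configuration list.
#' @param lib `component_library` supplying the nitrate extinction for the
#'   ISUS comparator.
#' @return A `benchmark_result`.
#' @export
evaluate_methods <- function(train, test, cal, cfg = benchmark_config(),
                             lib = seawater_library()) {
  if (any(is.na(train$reference_conc)))
    stop("training table must be fully labeled")
  tsc <- fit_tsc(cal, degrees = cfg$degrees, model_window = cfg$model_window,
                 cdom_window = cfg$cdom_window)
  train_c <- apply_tsc(tsc, train)
  test_c <- apply_tsc(tsc, test)
  X_train <- train_c$absorbance
  X_test <- test_c$absorbance
  y_train <- train$reference_conc
  labeled <- !any(is.na(test$reference_conc))
  spec <- kernel_spec(cfg$kernel, gamma = cfg$gamma)
  spec <- resolve_gamma(spec, X_train)
  predictions <- list()
  reports <- list()
  A_used <- NA_integer_
  for (m in cfg$methods) {
    pred <- switch(m,
      "wa-kpls" = {
        A_used <- if (is.null(cfg$n_components)) {
          as.integer(select_components(X_train, y_train, spec,
                                       r2_threshold = cfg$r2_threshold,
                                       a_max = cfg$a_max))
        } else as.integer(cfg$n_components)
        wa <- fit_wa_kpls(X_train, y_train, spec, n_components = A_used,
                          eta = cfg$eta, D = cfg$D, seed = cfg$seed,
                          weight_basis = cfg$weight_basis)
        predict_wa_kpls(wa, X_test)
      },
      "mlr" = {
        mlr <- fit_mlr(X_train, y_train, wavelengths = train_c$wavelengths)
        predict_mlr(mlr, X_test)
      },
      "isus" = {
        eps <- .nitrate_unit_spectrum(lib, train$wavelengths)
        isus <- fit_isus(train, eps, window = cfg$isus_window)
        isus <- recalibrate_isus(isus, train)
        predict_isus(isus, test)
      },
      stop(sprintf("unknown method '%s'", m))
    )
    predictions[[m]] <- pred
    if (labeled)
      reports[[m]] <- residual_report(test$reference_conc, pred,
                                      T = test$temperature, S = test$salinity,
                                      tolerances = cfg$tolerances)
  }
  structure(list(reports = reports, predictions = predictions,
                 n_components = A_used, tsc = tsc, test = test, config = cfg),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> methods: %s; components = %s\n",
              paste(names(x$predictions), collapse = ", "),
              ifelse(is.na(x$n_components), "-", x$n_components)))
  for (m in names(x$reports)) {
    cat(sprintf("  %-8s ", m)); print(x$reports[[m]])
  }
  invisible(x)
}

#' Out-of-range extrapolation study
#'
#' For each training concentration band, trains the TSC-WA-KPLS pipeline on
#' in-band synthetic samples and predicts samples below the band and in the
#' 90-100 umol/L band, reporting the fraction of predictions within
#' +/- 2 umol/L of truth per band. The reference band design: training
#' 4-80 / 6-80 / 8-80 / 10-80 umol/L against low bands 0-3 / 0-5 / 0-7 /
#' 0-9 umol/L and the common high band 90-100 umol/L.
#'
#' @param bands A list of `list(train = c(lo, hi), low = c(lo, hi),
#'   high = c(lo, hi))` entries; the default is the four-band reference
#'   design. Test bands must not overlap their training band.
#' @param config Configuration list; `n_train` and `n_test` set the per-band
#'   sample counts (the study default is 300 training and 100 test samples
#'   per band).
#' @param lib Optional `component_library`.
#' @param tolerance Error band in umol/L, default 2.
#' @return A data frame with one row per band: the band bounds, the fraction
#'   within tolerance below and above the training range, and the in-band
#'   test RMSEP.
#' @export
run_extrapolation_study <- function(bands = NULL,
                                    config = benchmark_config(n_train = 300, n_test = 100),
                                    lib = seawater_library(),
                                    tolerance = 2) {
  if (is.character(config)) config <- read_config(config)
  cfg <- do.call(benchmark_config, config)
  if (is.null(bands)) {
    bands <- list(
      list(train = c(4, 80), low = c(0, 3), high = c(90, 100)),
      list(train = c(6, 80), low = c(0, 5), high = c(90, 100)),
      list(train = c(8, 80), low = c(0, 7), high = c(90, 100)),
      list(train = c(10, 80), low = c(0, 9), high = c(90, 100))
    )
  }
  cal <- generate_lns_calibration(lib, cfg$cal_T, seed = cfg$seed,
                                  noise = cfg$cal_noise)
  tsc <- fit_tsc(cal, degrees = cfg$degrees, model_window = cfg$model_window,
                 cdom_window = cfg$cdom_window)
  rows <- lapply(seq_along(bands), function(bi) {
    bd <- bands[[bi]]
    for (nm in c("low", "high")) {
      tb <- bd[[nm]]
      if (is.null(tb)) next
      if (tb[1] >= tb[2]) stop(sprintf("band %d: empty %s test band", bi, nm))
      if (tb[1] < bd$train[2] && tb[2] > bd$train[1])
        stop(sprintf("band %d: %s test band overlaps the training band", bi, nm))
    }
    seed_b <- cfg$seed + 10 * bi
    train <- generate_samples(lib, cfg$n_train, bd$train, cfg$T_range,
                              cfg$S_range, noise = cfg$noise, seed = seed_b)
    X_train <- apply_tsc(tsc, train)$absorbance
    spec <- resolve_gamma(kernel_spec(cfg$kernel, gamma = cfg$gamma), X_train)
    A_used <- if (is.null(cfg$n_components)) {
      as.integer(select_components(X_train, train$reference_conc, spec,
                                   r2_threshold = cfg$r2_threshold,
                                   a_max = cfg$a_max))
    } else as.integer(cfg$n_components)
    wa <- fit_wa_kpls(X_train, train$reference_conc, spec,
                      n_components = A_used, eta = cfg$eta, D = cfg$D,
                      seed = cfg$seed, weight_basis = cfg$weight_basis)
    frac_in_band <- function(band, seed_off) {
      tst <- generate_samples(lib, cfg$n_test, band, cfg$T_range, cfg$S_range,
                              noise = cfg$noise, seed = seed_b + seed_off)
      pred <- predict_wa_kpls(wa, apply_tsc(tsc, tst)$absorbance)
      c(mean(abs(pred - tst$reference_conc) <= tolerance),
        rmsep(tst$reference_conc, pred))
    }
    lo <- frac_in_band(bd$low, 1)
    hi <- frac_in_band(bd$high, 2)
    inb <- frac_in_band(bd$train, 3)
    data.frame(train_lo = bd$train[1], train_hi = bd$train[2],
               low_lo = bd$low[1], low_hi = bd$low[2],
               high_lo = bd$high[1], high_hi = bd$high[2],
               frac_within_low = lo[1], frac_within_high = hi[1],
               frac_within_inband = inb[1], rmsep_inband = inb[2],
               n_components = A_used)
  })
  do.call(rbind, rows)
}
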