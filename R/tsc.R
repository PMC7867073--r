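# Temperature and salinity correction (TSC).
#
# The sea-salt absorbance of seawater in the deep UV is dominated by bromide,
# whose charge-transfer-to-solvent band grows with temperature. The correction
# chain: (i) normalize calibration absorbances of low-nutrient seawater (LNS)
# to S = 35 psu; (ii) fit a bivariate polynomial surface A(W, T) on centered/
# scaled wavelength and temperature; (iii) convert the surface to a per-psu
# molar absorptivity, scale by each sample's salinity and subtract; (iv) fit a
# straight line to the 240-260 nm residual (where nitrate no longer absorbs)
# and subtract it over the modeling window to remove the CDOM baseline.

#' Normalize absorbance to the standard salinity
#'
#' Scales measured absorbance to S = 35 psu: `A * s_standard / Sm`.
#'
#' @param A Numeric absorbance vector (AU).
#' @param Sm Measured salinity in psu; must be > 0.
#' @param s_standard Standard salinity, 35 psu.
#' @return Scaled absorbance vector.
#' @export
normalize_salinity <- function(A, Sm, s_standard = 35) {
  if (!is.finite(Sm) || Sm <= 0)
    stop("salinity must be positive; freshwater or degenerate sample")
  A * s_standard / Sm
}

#' Fit the LNS absorbance surface in wavelength and temperature
#'
#' Least-squares fit of the bivariate polynomial
#' \deqn{A(W,T) = \sum_{i \le d_W} \sum_{j \le d_T} p_{ij} W^i T^j}
#' to a zero-nitrate (LNS) calibration table, with wavelength and temperature
#' centered and scaled by their mean and standard deviation before fitting so
#' the design stays well conditioned and the model is portable across grids.
#'
#' @param cal A salinity-normalized zero-nitrate `sample_table`.
#' @param degrees Integer pair `(dW, dT)`: polynomial degree in wavelength and
#'   temperature. Default `c(3, 2)`.
#' @return An `lns_model` with coefficients, normalization statistics and fit
#'   diagnostics (R^2, RMSE, SSE over the calibration points).
#' @export
fit_lns_surface <- function(cal, degrees = c(3, 2)) {
  stopifnot(inherits(cal, "sample_table"))
  dW <- as.integer(degrees[1]); dT <- as.integer(degrees[2])
  if (dW < 0 || dT < 0) stop("degrees must be non-negative")
  wl <- cal$wavelengths
  temps <- cal$temperature
  npar <- (dW + 1) * (dT + 1)
  if (length(wl) * length(temps) < npar)
    stop("not enough calibration points for the requested degrees")
  if (dT >= 1 && length(unique(temps)) < 2)
    stop("calibration must span at least 2 temperatures to fit a temperature term")
  # long format: one point per (sample, wavelength)
  W <- rep(wl, each = n_samples(cal))
  Tv <- rep(temps, times = length(wl))
  y <- as.vector(cal$absorbance)
  w_mean <- mean(W); w_sd <- stats::sd(W)
  t_mean <- mean(Tv); t_sd <- stats::sd(Tv)
  if (w_sd <= 0) stop("degenerate wavelength grid")
  if (t_sd <= 0) t_sd <- 1  # single temperature, dT = 0 fits are still allowed
  Wn <- (W - w_mean) / w_sd
  Tn <- (Tv - t_mean) / t_sd
  X <- matrix(0, length(y), npar)
  k <- 0
  for (j in 0:dT) for (i in 0:dW) {
    k <- k + 1
    X[, k] <- Wn^i * Tn^j
  }
  qrX <- qr(X)
  if (qrX$rank < npar)
    stop(sprintf("rank-deficient design (rank %d < %d parameters); lower the polynomial degrees",
                 qrX$rank, npar))
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    w_mean = w_mean, w_sd = w_sd, t_mean = t_mean, t_sd = t_sd,
    degrees = c(dW, dT),
    coef = matrix(beta, nrow = dW + 1, ncol = dT + 1),
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / length(y)), sse = sse,
    n_points = length(y)
  ), class = "lns_model")
}

#' @export
print.lns_model <- function(x, ...) {
  cat(sprintf("<lns_model> degrees (%d, %d), R2 = %.6f, RMSE = %.3g AU, SSE = %.4g\n",
              x$degrees[1], x$degrees[2], x$r2, x$rmse, x$sse))
  invisible(x)
}

#' Evaluate the LNS surface
#'
#' @param model An `lns_model`.
#' @param W Wavelength(s) in nm.
#' @param T Temperature(s) in degC. `W` and `T` are recycled to a common
#'   length and evaluated pairwise.
#' @return Predicted LNS absorbance (AU). Evaluation outside the fitted span
#'   extrapolates the polynomial and emits a warning.
#' @export
predict_lns <- function(model, W, T) {
  stopifnot(inherits(model, "lns_model"))
  nn <- max(length(W), length(T))
  W <- rep_len(as.numeric(W), nn); T <- rep_len(as.numeric(T), nn)
  Wn <- (W - model$w_mean) / model$w_sd
  Tn <- (T - model$t_mean) / model$t_sd
  if (any(abs(Tn) > 3.5) || any(abs(Wn) > 3.5))
    warning("evaluating the LNS surface outside its fitted span (extrapolation)")
  dW <- model$degrees[1]; dT <- model$degrees[2]
  out <- numeric(nn)
  for (j in 0:dT) for (i in 0:dW) {
    out <- out + model$coef[i + 1, j + 1] * Wn^i * Tn^j
  }
  out
}

#' Rescale calibration molar absorptivity to a measured water mass
#'
#' Elementwise `E_m = E_cal * A_meas_norm / A_model`: the calibration
#' absorptivity scaled by the ratio of observed (salinity-normalized,
#' nitrate-free) absorbance to the LNS-surface prediction.
#'
#' @param E_cal Calibration molar absorptivity (AU/psu), vector or matrix.
#' @param A_meas_norm Salinity-normalized measured absorbance, same shape.
#' @param A_model LNS-surface predicted absorbance, same shape; must exceed
#'   `tol` everywhere to avoid division blow-up.
#' @param tol Lower bound on `A_model`.
#' @return Rescaled molar absorptivity, same shape as `E_cal`.
#' @export
molar_absorptivity <- function(E_cal, A_meas_norm, A_model, tol = 1e-8) {
  if (length(E_cal) != length(A_meas_norm) || length(E_cal) != length(A_model))
    stop("E_cal, A_meas_norm and A_model must share the same shape")
  if (any(A_model <= tol))
    stop(sprintf("model absorbance at or below tolerance (%g); cannot rescale absorptivity", tol))
  E_cal * A_meas_norm / A_model
}

#' Sea-salt absorbance at a given salinity
#'
#' `A_ss = E_m * S`, elementwise.
#'
#' @param E_m Molar absorptivity of sea salt (AU/psu), vector or matrix.
#' @param S Salinity in psu, `>= 0`.
#' @return Sea-salt absorbance, same shape as `E_m`.
#' @export
sea_salt_absorbance <- function(E_m, S) {
  if (!is.finite(S) || S < 0) stop("salinity must be finite and >= 0")
  E_m * S
}

#' Subtract sea-salt absorbance from a measured spectrum
#'
#' `A' = A_meas - A_ss`. Negative results (noise) are preserved; clipping
#' would bias the downstream regression.
#'
#' @param A_meas Measured absorbance vector (AU).
#' @param A_ss Sea-salt absorbance vector on the same grid.
#' @return Residual absorbance vector.
#' @export
remove_sea_salt <- function(A_meas, A_ss) {
  if (length(A_meas) != length(A_ss))
    stop("grid mismatch: A_meas and A_ss differ in length")
  A_meas - A_ss
}

#' Remove the CDOM baseline by linear extrapolation
#'
#' Fits an ordinary least-squares line `e + f * lambda` (raw nm) to the
#' residual absorbance inside `fit_window` — where nitrate no longer absorbs —
#' and subtracts the extrapolated line over `apply_window`.
#'
#' @param spectrum A `uv_spectrum` of residual absorbance covering both
#'   windows.
#' @param fit_window Wavelength interval (nm) used to fit the line; default
#'   `c(240, 260)`.
#' @param apply_window Wavelength interval (nm) over which the corrected
#'   spectrum is returned; default `c(208, 240)`.
#' @return A list with `spectrum` (corrected `uv_spectrum` over
#'   `apply_window`) and `coefficients` `c(e, f)` of the fitted line.
#' @export
remove_cdom <- function(spectrum, fit_window = c(240, 260),
                        apply_window = c(208, 240)) {
  stopifnot(inherits(spectrum, "uv_spectrum"))
  wl <- spectrum$wavelengths
  infit <- wl >= fit_window[1] & wl <= fit_window[2]
  if (sum(infit) < 2)
    stop(sprintf("CDOM fit window [%g, %g] nm contains fewer than 2 grid points",
                 fit_window[1], fit_window[2]))
  ef <- .cdom_line(wl[infit], spectrum$values[infit])
  inapply <- wl >= apply_window[1] & wl <= apply_window[2]
  if (!any(inapply)) stop("apply window contains no grid points")
  corrected <- spectrum$values[inapply] - (ef[1] + ef[2] * wl[inapply])
  list(spectrum = uv_spectrum(wl[inapply], corrected, kind = "absorbance"),
       coefficients = c(e = unname(ef[1]), f = unname(ef[2])))
}

# closed-form OLS line fit
.cdom_line <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  f <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(ym - f * xm, f)
}

#' Fit the full temperature/salinity-correction model
#'
#' Normalizes the calibration table to standard salinity, restricts it to the
#' union of the modeling and CDOM windows, and fits the LNS polynomial
#' surface. The per-psu calibration absorptivity grid is the fitted surface
#' divided by `s_standard`.
#'
#' @param cal Zero-nitrate calibration `sample_table` (raw absorbances; the
#'   salinity normalization is applied here).
#' @param degrees Polynomial degrees `(dW, dT)` for [fit_lns_surface()].
#' @param model_window Modeling window in nm, default `c(208, 240)`.
#' @param cdom_window CDOM fit window in nm, default `c(240, 260)`.
#' @param s_standard Standard salinity in psu.
#' @return A `tsc_model`.
#' @export
fit_tsc <- function(cal, degrees = c(3, 2), model_window = c(208, 240),
                    cdom_window = c(240, 260), s_standard = 35) {
  stopifnot(inherits(cal, "sample_table"))
  if (model_window[1] >= model_window[2] || cdom_window[1] >= cdom_window[2])
    stop("windows must be non-empty intervals")
  norm_A <- cal$absorbance
  for (i in seq_len(n_samples(cal))) {
    norm_A[i, ] <- normalize_salinity(cal$absorbance[i, ], cal$salinity[i],
                                      s_standard)
  }
  cal_norm <- sample_table(cal$ids, cal$wavelengths, norm_A, cal$temperature,
                           rep(s_standard, n_samples(cal)), cal$reference_conc)
  cal_fit <- select_window(cal_norm, model_window[1], cdom_window[2])
  lns <- fit_lns_surface(cal_fit, degrees)
  structure(list(lns = lns, s_standard = s_standard,
                 model_window = as.numeric(model_window),
                 cdom_window = as.numeric(cdom_window)),
            class = "tsc_model")
}

#' @export
print.tsc_model <- function(x, ...) {
  cat(sprintf("<tsc_model> windows %g-%g / %g-%g nm, S_standard = %g psu\n",
              x$model_window[1], x$model_window[2],
              x$cdom_window[1], x$cdom_window[2], x$s_standard))
  print(x$lns)
  invisible(x)
}

#' Apply the temperature/salinity/CDOM correction to a sample table
#'
#' Per sample: evaluate the LNS surface at the sample's temperature, convert
#' to per-psu absorptivity, scale by the sample's salinity and subtract from
#' the measured spectrum; then fit and subtract the linear CDOM baseline from
#' the 240-260 nm residual; finally restrict to the modeling window. For
#' samples drawn from the calibrated water mass the LNS surface is the
#' nitrate-free absorbance estimate itself, so the Eq.-5-style measured/model
#' rescaling factor is unity (see the methods vignette; the general rescaling
#' is available via [molar_absorptivity()]).
#'
#' @param model A `tsc_model`.
#' @param table A `sample_table` whose grid covers both windows and which
#'   carries per-sample temperature and salinity.
#' @return A corrected `sample_table` over the modeling window, with the
#'   fitted CDOM line coefficients attached as attribute `"cdom_coef"`
#'   (one row `c(e, f)` per sample).
#' @export
apply_tsc <- function(model, table) {
  stopifnot(inherits(model, "tsc_model"), inherits(table, "sample_table"))
  mw <- model$model_window; cw <- model$cdom_window
  if (min(table$wavelengths) > mw[1] || max(table$wavelengths) < cw[2])
    stop("sample grid must cover both the modeling and CDOM windows")
  tab <- select_window(table, mw[1], cw[2])
  wl <- tab$wavelengths
  n <- n_samples(tab)
  inapply <- wl >= mw[1] & wl <= mw[2]
  infit <- wl >= cw[1] & wl <= cw[2]
  corrected <- matrix(0, n, sum(inapply))
  cdom_coef <- matrix(0, n, 2, dimnames = list(NULL, c("e", "f")))
  for (i in seq_len(n)) {
    A_model <- predict_lns(model$lns, wl, rep(tab$temperature[i], length(wl)))
    E_m <- A_model / model$s_standard                      # per-psu absorptivity
    A_ss <- sea_salt_absorbance(E_m, tab$salinity[i])
    A_prime <- remove_sea_salt(tab$absorbance[i, ], A_ss)
    ef <- .cdom_line(wl[infit], A_prime[infit])
    corrected[i, ] <- A_prime[inapply] - (ef[1] + ef[2] * wl[inapply])
    cdom_coef[i, ] <- ef
  }
  out <- sample_table(tab$ids, wl[inapply], corrected, tab$temperature,
                      tab$salinity, tab$reference_conc)
  attr(out, "cdom_coef") <- cdom_coef
  out
}
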