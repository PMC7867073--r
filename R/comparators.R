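# Baseline retrieval algorithms: TSC-MLR (ordinary least squares on the
# corrected modeling-window absorbance) and an ISUS-style decomposition of
# raw absorbance into an exponential seawater term, nitrate extinction and an
# affine baseline, followed by an optional linear recalibration.

#' Fit a multiple linear regression calibration
#'
#' Ordinary least squares of concentration on the corrected modeling-window
#' absorbance (plus an intercept). With fewer samples than wavelengths the
#' minimum-norm solution is returned with a warning.
#'
#' @param A_corrected Samples x wavelengths matrix of corrected absorbance.
#' @param y Reference concentrations, umol/L.
#' @param wavelengths Optional wavelength grid (stored for provenance).
#' @return An `mlr_model` with `coefficients` (intercept first).
#' @export
fit_mlr <- function(A_corrected, y, wavelengths = NULL) {
  A_corrected <- as.matrix(A_corrected)
  y <- as.numeric(y)
  stopifnot(nrow(A_corrected) == length(y))
  X <- cbind(1, A_corrected)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf("design rank %d < %d coefficients; returning the minimum-norm solution",
                    qrX$rank, ncol(X)))
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  structure(list(coefficients = unname(beta),
                 wavelengths = if (is.null(wavelengths)) numeric(0) else as.numeric(wavelengths)),
            class = "mlr_model")
}

#' Predict from an MLR calibration
#'
#' @param model An `mlr_model`.
#' @param A_corrected Samples x wavelengths matrix on the training grid.
#' @return Predicted concentrations, umol/L.
#' @export
predict_mlr <- function(model, A_corrected) {
  stopifnot(inherits(model, "mlr_model"))
  A_corrected <- as.matrix(A_corrected)
  if (ncol(A_corrected) != length(model$coefficients) - 1)
    stop("wavelength count differs from the fitted model")
  drop(cbind(1, A_corrected) %*% model$coefficients)
}

#' Published ISUS oligotrophic-seawater parameters
#'
#' The exponential seawater-absorbance fit parameters reported for the ISUS
#' retrieval: A = 1.1500276, B = 0.02840, C = -0.3101349, D = 0.001222, with
#' the wavelength origin at 210 nm.
#' @return Named numeric vector `c(A, B, C, D)`.
#' @export
isus_default_params <- function() {
  c(A = 1.1500276, B = 0.02840, C = -0.3101349, D = 0.001222)
}

#' ISUS-style seawater absorbance
#'
#' `A_OS(T, lambda) = (A + B T) exp((C + D T) (lambda - 210))`.
#'
#' @param T Temperature in degC.
#' @param lambda Wavelength in nm.
#' @param params Named vector `c(A, B, C, D)`.
#' @return Absorbance (AU); `T` and `lambda` recycle elementwise.
#' @export
isus_seawater_absorbance <- function(T, lambda, params = isus_default_params()) {
  W <- lambda - 210
  (params[["A"]] + params[["B"]] * T) * exp((params[["C"]] + params[["D"]] * T) * W)
}

#' Fit an ISUS-style retrieval model
#'
#' For each sample the measured absorbance over the retrieval window is
#' modeled as
#' `(S/35) A_OS(T, lambda) + C eps_NO3(lambda) + e + f lambda`
#' and the nitrate concentration C plus baseline `(e, f)` are solved by
#' linear least squares; the seawater term is fixed by the sample's
#' temperature and salinity.
#'
#' @param table A `sample_table` of raw (uncorrected) absorbance whose grid
#'   covers the retrieval window.
#' @param nitrate_extinction Nitrate absorbance per umol/L on the table's
#'   grid: a `uv_spectrum` or a numeric vector matching the full grid.
#' @param params Seawater parameters, default [isus_default_params()].
#' @param window Retrieval window in nm, default `c(217, 240)`.
#' @return An `isus_model` (with an empty recalibration slot; see
#'   [linear_recalibrate()]).
#' @export
fit_isus <- function(table, nitrate_extinction, params = isus_default_params(),
                     window = c(217, 240)) {
  stopifnot(inherits(table, "sample_table"))
  eps <- if (inherits(nitrate_extinction, "uv_spectrum")) {
    if (!isTRUE(all.equal(nitrate_extinction$wavelengths, table$wavelengths)))
      stop("nitrate extinction grid does not match the sample grid")
    nitrate_extinction$values
  } else as.numeric(nitrate_extinction)
  if (length(eps) != length(table$wavelengths))
    stop("nitrate extinction must be given on the sample wavelength grid")
  if (any(eps < 0)) stop("nitrate extinction must be >= 0")
  keep <- which(table$wavelengths >= window[1] & table$wavelengths <= window[2])
  if (length(keep) < 3)
    stop(sprintf("retrieval window [%g, %g] nm has %d grid points; need at least 3",
                 window[1], window[2], length(keep)))
  structure(list(params = params, window = as.numeric(window),
                 wavelengths = table$wavelengths[keep],
                 extinction = eps[keep],
                 recalibration = NULL),
            class = "isus_model")
}

#' Predict nitrate with an ISUS-style retrieval
#'
#' @param model An `isus_model`.
#' @param table A `sample_table` of raw absorbance on a grid covering the
#'   model's retrieval window (matched by nearest wavelength).
#' @return Predicted concentrations, umol/L; the stored linear recalibration,
#'   if any, is applied.
#' @export
predict_isus <- function(model, table) {
  stopifnot(inherits(model, "isus_model"), inherits(table, "sample_table"))
  tab <- align_nearest(table, model$wavelengths)
  wl <- model$wavelengths
  eps <- model$extinction
  n <- n_samples(tab)
  out <- numeric(n)
  base <- cbind(eps, 1, wl)
  qrB <- qr(base)
  if (qrB$rank < 3) stop("singular retrieval design (constant extinction?)")
  for (i in seq_len(n)) {
    aos <- isus_seawater_absorbance(tab$temperature[i], wl, model$params)
    r <- tab$absorbance[i, ] - (tab$salinity[i] / 35) * aos
    out[i] <- qr.coef(qrB, r)[1]
  }
  if (!is.null(model$recalibration))
    out <- model$recalibration[["a"]] * out + model$recalibration[["b"]]
  out
}

#' Linear recalibration of predictions against reference concentrations
#'
#' Least-squares fit `ref ~ a * pred + b`; the corrected predictions are
#' `a * pred + b`.
#'
#' @param pred Predicted concentrations, umol/L.
#' @param ref Reference concentrations, umol/L (at least 2 distinct values).
#' @return A list with `a`, `b` and `corrected`.
#' @export
linear_recalibrate <- function(pred, ref) {
  pred <- as.numeric(pred); ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(unique(ref)) < 2) stop("need at least 2 distinct reference values")
  if (stats::sd(pred) == 0) stop("constant predictions cannot be recalibrated")
  a <- stats::cov(pred, ref) / stats::var(pred)
  b <- mean(ref) - a * mean(pred)
  list(a = a, b = b, corrected = a * pred + b)
}

#' Attach a linear recalibration to an ISUS model
#'
#' Convenience wrapper: predicts the calibration table, fits
#' [linear_recalibrate()] against its reference concentrations and stores
#' `(a, b)` in the model so later predictions are corrected automatically.
#'
#' @param model An `isus_model`.
#' @param table A labeled `sample_table`.
#' @return The updated `isus_model`.
#' @export
recalibrate_isus <- function(model, table) {
  stopifnot(inherits(model, "isus_model"))
  ref <- table$reference_conc
  if (any(is.na(ref))) stop("recalibration table must be fully labeled")
  model$recalibration <- NULL  # refit from raw retrievals, never compose
  pred <- predict_isus(model, table)
  rc <- linear_recalibrate(pred, ref)
  model$recalibration <- c(a = rc$a, b = rc$b)
  model
}
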