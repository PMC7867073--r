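#' Construct a single UV spectrum
#'
#' A spectrum is a wavelength-indexed trace of either raw detector counts
#' (`kind = "intensity"`) or absorbance in AU (`kind = "absorbance"`).
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param values Numeric vector of the same length; detector counts or AU.
#' @param kind Either `"absorbance"` or `"intensity"`.
#' @return An object of class `uv_spectrum`.
#' @examples
#' s <- uv_spectrum(c(210, 211, 212), c(0.1, 0.2, 0.3))
#' @export
uv_spectrum <- function(wavelengths, values, kind = c("absorbance", "intensity")) {
  kind <- match.arg(kind)
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("`wavelengths` and `values` must have the same length")
  if (length(wavelengths) == 0) stop("empty spectrum")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be finite and strictly increasing")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  structure(list(wavelengths = wavelengths, values = values, kind = kind),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %s, %d points, %.3f-%.3f nm\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Construct a sample table of absorbance spectra with metadata
#'
#' The central data container: one row per sample, one column per wavelength,
#' plus per-sample temperature (degC), salinity (psu) and, where known, the
#' reference nitrate concentration (umol/L).
#'
#' @param ids Character vector of sample identifiers.
#' @param wavelengths Numeric wavelength grid in nm, strictly increasing.
#' @param absorbance Numeric matrix, `length(ids)` x `length(wavelengths)`, AU.
#' @param temperature Numeric vector of sample temperatures in degC.
#' @param salinity Numeric vector of sample salinities in psu.
#' @param reference_conc Optional numeric vector of reference nitrate
#'   concentrations in umol/L; `NA` marks unlabeled samples.
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(ids, wavelengths, absorbance, temperature, salinity,
                         reference_conc = NULL) {
  ids <- as.character(ids)
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.matrix(absorbance)
  n <- length(ids)
  if (any(!is.finite(wavelengths)) || (length(wavelengths) > 1 && any(diff(wavelengths) <= 0)))
    stop("`wavelengths` must be finite and strictly increasing")
  if (nrow(absorbance) != n)
    stop(sprintf("absorbance matrix has %d rows but %d sample ids", nrow(absorbance), n))
  if (ncol(absorbance) != length(wavelengths))
    stop(sprintf("absorbance matrix has %d columns but %d wavelengths",
                 ncol(absorbance), length(wavelengths)))
  if (length(temperature) != n || length(salinity) != n)
    stop("temperature and salinity must have one value per sample")
  if (any(!is.finite(temperature))) stop("temperature must be finite")
  if (any(!is.finite(salinity))) stop("salinity must be finite")
  if (is.null(reference_conc)) reference_conc <- rep(NA_real_, n)
  reference_conc <- as.numeric(reference_conc)
  if (length(reference_conc) != n)
    stop("reference_conc must have one value per sample")
  if (any(reference_conc < 0, na.rm = TRUE))
    stop("reference_conc must be >= 0 where present")
  dimnames(absorbance) <- NULL
  structure(list(ids = ids, wavelengths = wavelengths, absorbance = absorbance,
                 temperature = as.numeric(temperature),
                 salinity = as.numeric(salinity),
                 reference_conc = reference_conc),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d samples x %d wavelengths (%.3f-%.3f nm)\n",
              length(x$ids), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf("  T %.1f-%.1f degC, S %.1f-%.1f psu, %d labeled\n",
              min(x$temperature), max(x$temperature),
              min(x$salinity), max(x$salinity),
              sum(!is.na(x$reference_conc))))
  invisible(x)
}

#' Number of samples in a sample table
#' @param table A `sample_table`.
#' @export
n_samples <- function(table) length(table$ids)

#' Compute absorbance from raw intensity spectra
#'
#' Applies the Beer-Lambert absorbance definition
#' \deqn{A_\lambda = -\log_{10}\!\big((I_\lambda - I_D)/(I_{\lambda,0} - I_D)\big)}
#' where \eqn{I_\lambda} is the sample beam, \eqn{I_{\lambda,0}} the reference
#' (deionized-water) beam and \eqn{I_D} the detector dark current.
#'
#' @param sample_intensity `uv_spectrum` of kind `"intensity"`.
#' @param reference_intensity `uv_spectrum` of kind `"intensity"` on the same grid.
#' @param dark Dark current: a scalar (counts) or a `uv_spectrum`/vector on the
#'   same grid. The detector dark level is usually a single per-device constant.
#' @return A `uv_spectrum` of kind `"absorbance"`.
#' @export
compute_absorbance <- function(sample_intensity, reference_intensity, dark = 0) {
  stopifnot(inherits(sample_intensity, "uv_spectrum"),
            inherits(reference_intensity, "uv_spectrum"))
  wl <- sample_intensity$wavelengths
  if (!isTRUE(all.equal(wl, reference_intensity$wavelengths, tolerance = 0)))
    stop("sample and reference spectra must share an identical wavelength grid")
  dk <- if (inherits(dark, "uv_spectrum")) {
    if (!isTRUE(all.equal(wl, dark$wavelengths, tolerance = 0)))
      stop("dark spectrum must share the sample wavelength grid")
    dark$values
  } else {
    if (!(length(dark) %in% c(1L, length(wl)))) stop("dark must be scalar or per-wavelength")
    rep_len(as.numeric(dark), length(wl))
  }
  num <- sample_intensity$values - dk
  den <- reference_intensity$values - dk
  bad <- which(num <= 0 | den <= 0)
  if (length(bad))
    stop(sprintf(
      "non-positive dark-corrected intensity at %.3f nm (sample-dark = %.6g, reference-dark = %.6g)",
      wl[bad[1]], num[bad[1]], den[bad[1]]))
  uv_spectrum(wl, -log10(num / den), kind = "absorbance")
}

#' Restrict a sample table to a wavelength window
#'
#' Keeps the columns whose wavelength lies in the closed interval `[lo, hi]`.
#' The deep-UV modeling window of the method is 208-240 nm, where nitrate and
#' bromide absorb but chloride no longer swamps the signal.
#'
#' @param table A `sample_table`.
#' @param lo,hi Window bounds in nm, `lo < hi`.
#' @return A `sample_table` with restricted columns; metadata unchanged.
#' @export
select_window <- function(table, lo, hi) {
  stopifnot(inherits(table, "sample_table"))
  if (!(is.finite(lo) && is.finite(hi) && lo < hi)) stop("need finite lo < hi")
  keep <- which(table$wavelengths >= lo & table$wavelengths <= hi)
  if (length(keep) < 2)
    stop(sprintf("window [%g, %g] nm contains %d grid point(s); need at least 2",
                 lo, hi, length(keep)))
  sample_table(table$ids, table$wavelengths[keep],
               table$absorbance[, keep, drop = FALSE],
               table$temperature, table$salinity, table$reference_conc)
}

#' Align a sample table onto a target wavelength grid by nearest neighbour
#'
#' Maps every target wavelength to the single nearest source column; no
#' interpolation of absorbance values is performed. Ties (a target exactly
#' midway between two source wavelengths) resolve to the lower wavelength.
#'
#' @param table A `sample_table`.
#' @param target_grid Numeric vector of target wavelengths (nm), strictly
#'   increasing, within the span of the source grid.
#' @return A `sample_table` on the target grid (carrying the source
#'   wavelengths actually selected).
#' @export
align_nearest <- function(table, target_grid) {
  stopifnot(inherits(table, "sample_table"))
  target_grid <- as.numeric(target_grid)
  src <- table$wavelengths
  if (any(target_grid < min(src)) || any(target_grid > max(src)))
    stop("target grid extends outside the source wavelength span")
  idx <- vapply(target_grid, function(w) {
    d <- abs(src - w)
    # which.min returns the first (lowest-wavelength) index on ties
    which.min(d)
  }, integer(1))
  if (any(diff(idx) <= 0))
    stop("target grid maps to non-increasing source columns; coarsen the target grid")
  sample_table(table$ids, src[idx], table$absorbance[, idx, drop = FALSE],
               table$temperature, table$salinity, table$reference_conc)
}
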