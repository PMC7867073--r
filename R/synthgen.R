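# Synthetic seawater absorbance generator.
#
# Forward model: Beer-Lambert additivity over the dissolved species of an
# artificial-seawater recipe,
#   A(lambda) = b * sum_j eps_j(lambda) * (1 + tc_j (T - 20)) * C_j * s_j(S),
# with s_j(S) = S/35 for sea-salt species and 1 otherwise. The extinction
# shapes are fixed, versioned constants of the library: they reproduce the
# qualitative deep-UV picture (chloride dominant below 208 nm, a bromide decay
# over 200-266 nm carrying the temperature dependence, a nitrate band that
# vanishes above 240 nm, a broadband CDOM tail) while keeping the total
# sea-salt extinction exactly cubic in wavelength on 208-260 nm, so the
# polynomial LNS calibration surface is an exact description of the sea-salt
# matrix it is meant to remove.

#' Construct a synthetic seawater component
#'
#' @param name Component name.
#' @param extinction A function of wavelength (nm) returning molar
#'   absorptivity in AU L mol^-1 mm^-1; must be >= 0.
#' @param concentration Concentration in mol/L.
#' @param temp_coeff Fractional absorbance change per degC about 20 degC
#'   (0 for temperature-independent species).
#' @param sea_salt Logical; sea-salt species scale with salinity as S/35.
#' @return A `seawater_component`.
#' @export
seawater_component <- function(name, extinction, concentration,
                               temp_coeff = 0, sea_salt = FALSE) {
  stopifnot(is.function(extinction), is.finite(temp_coeff), concentration >= 0)
  structure(list(name = name, extinction = extinction,
                 concentration = concentration, temp_coeff = temp_coeff,
                 sea_salt = sea_salt),
            class = "seawater_component")
}

# shape helpers: each returns a dimensionless shape in [0, 1]-ish scale
.cubic_decay <- function(lambda, zero_at, width) {
  pmax((zero_at - lambda) / width, 0)^3
}

#' Default synthetic seawater component library
#'
#' Species and concentrations follow the standard artificial-seawater recipe:
#' NaCl 0.55 mol/L, MgSO4 28 mmol/L, NaHCO3 2.3 mmol/L, NaBr 0.8 mmol/L,
#' sodium humate 5 umol/L, NaH2PO4 2.26 umol/L, NaNO2 0.22 umol/L, and
#' sodium nitrate at a nominal 30 umol/L (overridden during generation).
#' Optical path length 10 mm; spectrometer noise from a 1000:1 signal-to-noise
#' ratio and 2.5 counts RMS dark noise.
#'
#' Extinction shapes (documented constants of this library, not literature
#' values): chloride, sulfate and bicarbonate are steep cubics vanishing at or
#' below 208 nm; bromide is a decaying cubic `((266-lambda)/66)^3` (zero above
#' 266 nm) with temperature coefficient +0.01/degC; nitrate is a Gaussian band
#' centred at 205 nm (sigma 10 nm) truncated to zero at and above 240 nm;
#' nitrite follows the bromide shape at trace amplitude; humate (the CDOM
#' carrier) is `exp(-s (lambda - 240))` with slope `s = cdom_slope`; phosphate
#' does not absorb above 200 nm.
#'
#' @param path_length_mm Optical path length b in mm.
#' @param snr Intensity signal-to-noise ratio (single acquisition).
#' @param dark_noise_counts Detector dark noise, counts RMS.
#' @param ref_counts Nominal reference-beam level in counts, used to express
#'   dark noise relative to the signal.
#' @param cdom_shape `"exponential"` (default) or `"linear"` CDOM tail.
#' @param cdom_slope CDOM spectral slope s in nm^-1.
#' @return A `component_library`.
#' @export
seawater_library <- function(path_length_mm = 10, snr = 1000,
                             dark_noise_counts = 2.5, ref_counts = 60000,
                             cdom_shape = c("exponential", "linear"),
                             cdom_slope = 0.014) {
  cdom_shape <- match.arg(cdom_shape)
  stopifnot(path_length_mm > 0, snr > 0, dark_noise_counts >= 0)
  force(cdom_slope)
  cdom_fun <- if (cdom_shape == "exponential") {
    function(lambda) 400 * exp(-cdom_slope * (lambda - 240))
  } else {
    function(lambda) 400 * pmax(1 - cdom_slope * (lambda - 240), 0)
  }
  # nitrate pi->pi* band: peak near 205 nm with a steep red-edge decay
  # (peak molar absorptivity ~6.5e3 L mol^-1 cm^-1), truncated to exactly
  # zero at and above 240 nm
  nitrate_fun <- function(lambda) {
    g <- exp(-((lambda - 205) / 10)^2)
    650 * pmax(g - exp(-((240 - 205) / 10)^2), 0) * (lambda < 240)
  }
  comps <- list(
    seawater_component("NaCl", function(l) 1.2 * .cubic_decay(l, 208, 8),
                       0.55, temp_coeff = 0, sea_salt = TRUE),
    seawater_component("MgSO4", function(l) 0.5 * .cubic_decay(l, 206, 6),
                       0.028, temp_coeff = 0, sea_salt = TRUE),
    seawater_component("NaHCO3", function(l) 5 * .cubic_decay(l, 208, 8),
                       0.0023, temp_coeff = 0, sea_salt = TRUE),
    # amplitude anchored to published deep-UV seawater absorbance:
    # ~1.6 AU at 210 nm, 20 degC, S = 35, 10 mm path
    seawater_component("NaBr", function(l) 327 * .cubic_decay(l, 266, 66),
                       8e-4, temp_coeff = 0.01, sea_salt = TRUE),
    seawater_component("nitrate", nitrate_fun, 30e-6,
                       temp_coeff = 0, sea_salt = FALSE),
    seawater_component("humate", cdom_fun, 5e-6,
                       temp_coeff = 0, sea_salt = FALSE),
    seawater_component("NaH2PO4", function(l) rep(0, length(l)), 2.26e-6,
                       temp_coeff = 0, sea_salt = FALSE),
    seawater_component("NaNO2", function(l) 450 * .cubic_decay(l, 266, 66),
                       0.22e-6, temp_coeff = 0, sea_salt = FALSE)
  )
  names(comps) <- vapply(comps, `[[`, "", "name")
  structure(list(components = comps, path_length_mm = path_length_mm,
                 snr = snr, dark_noise_counts = dark_noise_counts,
                 ref_counts = ref_counts, cdom_shape = cdom_shape,
                 cdom_slope = cdom_slope),
            class = "component_library")
}

#' Default instrument wavelength grid
#'
#' 200-385 nm at 0.4 nm optical resolution.
#' @return Numeric vector of wavelengths in nm.
#' @export
default_grid <- function() seq(200, 385, by = 0.4)

#' Noiseless forward absorbance of a component mixture
#'
#' Evaluates the additive Beer-Lambert model at temperature `T` and salinity
#' `S` on the given grid. Exact and noise-free; linear in every concentration.
#'
#' @param lib A `component_library`.
#' @param conc_overrides Named list/vector of concentration overrides in mol/L
#'   (e.g. `list(nitrate = 50e-6)`); names must match library components.
#' @param T Temperature in degC.
#' @param S Salinity in psu.
#' @param grid Wavelength grid in nm.
#' @return A `uv_spectrum` of kind `"absorbance"`.
#' @export
forward_absorbance <- function(lib, conc_overrides = list(), T = 20, S = 35,
                               grid = default_grid()) {
  stopifnot(inherits(lib, "component_library"), is.finite(T), is.finite(S))
  conc_overrides <- as.list(conc_overrides)
  unknown <- setdiff(names(conc_overrides), names(lib$components))
  if (length(unknown))
    stop(sprintf("unknown component(s) in overrides: %s", paste(unknown, collapse = ", ")))
  A <- numeric(length(grid))
  for (cmp in lib$components) {
    conc <- if (cmp$name %in% names(conc_overrides))
      as.numeric(conc_overrides[[cmp$name]]) else cmp$concentration
    if (conc == 0) next
    sal <- if (cmp$sea_salt) S / 35 else 1
    A <- A + lib$path_length_mm * cmp$extinction(grid) *
      (1 + cmp$temp_coeff * (T - 20)) * conc * sal
  }
  uv_spectrum(grid, A, kind = "absorbance")
}

# absorbance-domain noise sd from intensity-domain SNR + dark noise:
# first-order propagation of A = -log10((I - ID)/(I0 - ID)) with per-beam
# counts noise sigma_b = sqrt((ref/snr)^2 + dark^2); the sample beam sits at
# ref * 10^-A, so its relative noise grows as 10^A.
.absorbance_noise_sd <- function(lib, A) {
  sigma_b <- sqrt((lib$ref_counts / lib$snr)^2 + lib$dark_noise_counts^2)
  sigma_b * sqrt(1 + 10^(2 * pmin(A, 3))) / (lib$ref_counts * log(10))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

#' Generate a labeled synthetic seawater dataset
#'
#' Nitrate concentration, temperature and salinity are drawn uniformly from
#' their ranges; absorbance is the noiseless forward model plus (optionally)
#' zero-mean Gaussian noise whose standard deviation is the absorbance
#' equivalent of the instrument's 1000:1 intensity signal-to-noise ratio and
#' dark noise. The drawn nitrate concentration is recorded as ground truth.
#'
#' @param lib A `component_library`.
#' @param n Number of samples.
#' @param conc_range Nitrate range in umol/L, e.g. `c(0, 100)`.
#' @param T_range Temperature range in degC, e.g. `c(4, 25)`.
#' @param S_range Salinity range in psu, e.g. `c(30, 35)`.
#' @param noise Logical; add spectrometer noise.
#' @param seed RNG seed; identical seeds give identical tables.
#' @param grid Wavelength grid in nm.
#' @return A `sample_table` with `reference_conc` filled in.
#' @export
generate_samples <- function(lib, n, conc_range = c(0, 100),
                             T_range = c(4, 25), S_range = c(30, 35),
                             noise = TRUE, seed = 1, grid = default_grid()) {
  stopifnot(inherits(lib, "component_library"), n >= 1)
  chk <- function(r, what) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2])
      stop(sprintf("invalid %s range", what))
  }
  chk(conc_range, "concentration"); chk(T_range, "temperature"); chk(S_range, "salinity")
  with_seed(seed, {
    conc <- stats::runif(n, conc_range[1], conc_range[2])
    temp <- stats::runif(n, T_range[1], T_range[2])
    sal <- stats::runif(n, S_range[1], S_range[2])
    A <- matrix(0, n, length(grid))
    for (i in seq_len(n)) {
      A[i, ] <- forward_absorbance(lib, list(nitrate = conc[i] * 1e-6),
                                   T = temp[i], S = sal[i], grid = grid)$values
    }
    if (noise) {
      sd_mat <- .absorbance_noise_sd(lib, A)
      A <- A + matrix(stats::rnorm(length(A)), n) * sd_mat
    }
    sample_table(sprintf("syn%04d", seq_len(n)), grid, A, temp, sal, conc)
  })
}

#' Generate a zero-nitrate calibration series for the LNS surface
#'
#' Emulates the low-nutrient-seawater (LNS) calibration run: one zero-nitrate,
#' zero-CDOM sample per requested temperature at fixed salinity, measured on
#' the instrument grid. This is the input for fitting the sea-salt absorbance
#' surface.
#'
#' @param lib A `component_library`.
#' @param T_list Temperatures in degC (the reference design is 4-25 degC at
#'   1 degC intervals).
#' @param seed RNG seed (used only when `noise = TRUE`).
#' @param noise Logical; add spectrometer noise.
#' @param salinity Salinity of the calibration water in psu.
#' @param grid Wavelength grid in nm.
#' @return A `sample_table` with `reference_conc = 0` throughout.
#' @export
generate_lns_calibration <- function(lib, T_list = 4:25, seed = 1,
                                     noise = FALSE, salinity = 35,
                                     grid = default_grid()) {
  stopifnot(inherits(lib, "component_library"), length(T_list) >= 1)
  n <- length(T_list)
  A <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    A[i, ] <- forward_absorbance(lib, list(nitrate = 0, humate = 0),
                                 T = T_list[i], S = salinity, grid = grid)$values
  }
  if (noise) {
    A <- with_seed(seed, A + matrix(stats::rnorm(length(A)), n) *
                     .absorbance_noise_sd(lib, A))
  }
  sample_table(sprintf("lns_T%05.1f", as.numeric(T_list)), grid, A,
               as.numeric(T_list), rep(salinity, n), rep(0, n))
}
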