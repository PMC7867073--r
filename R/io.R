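#' Read a wide-format spectra CSV into a sample table
#'
#' Expected header: `sample_id,temperature_C,salinity_psu,nitrate_umol_L,`
#' followed by one `A_<wavelength>` column per grid point, wavelengths printed
#' to three decimals (e.g. `A_208.000`). `nitrate_umol_L` may be empty for
#' unlabeled samples.
#'
#' @param path Path to a CSV file.
#' @return A `sample_table`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("sample_id", "temperature_C", "salinity_psu", "nitrate_umol_L")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("spectra CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  acol <- grep("^A_", names(df), value = TRUE)
  if (length(acol) < 2) stop("spectra CSV must contain at least two A_<wavelength> columns")
  wl <- suppressWarnings(as.numeric(sub("^A_", "", acol)))
  if (any(is.na(wl))) stop("malformed wavelength column name(s) in spectra CSV")
  o <- order(wl)
  wl <- wl[o]; acol <- acol[o]
  for (cn in c("temperature_C", "salinity_psu", acol)) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(trimws(as.character(v))))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'", bad[1], cn, v[bad[1]]))
      df[[cn]] <- vn
    }
  }
  ref <- suppressWarnings(as.numeric(df$nitrate_umol_L))
  A <- as.matrix(df[acol])
  if (any(is.na(A)))
    stop("missing or non-numeric absorbance cell in spectra CSV")
  sample_table(df$sample_id, wl, A, df$temperature_C, df$salinity_psu, ref)
}

#' Write a sample table to the wide spectra CSV dialect
#'
#' @param table A `sample_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "sample_table"))
  A <- table$absorbance
  df <- data.frame(sample_id = table$ids,
                   temperature_C = table$temperature,
                   salinity_psu = table$salinity,
                   nitrate_umol_L = table$reference_conc,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(A) <- sprintf("A_%.3f", table$wavelengths)
  out <- cbind(df, as.data.frame(A, check.names = FALSE))
  # write.table renders doubles via as.character (15 significant digits),
  # which keeps read-write round trips within 1e-12 relative
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# --- model JSON serialization ------------------------------------------------
# Every fitted model is a single self-describing JSON file:
# {schema, schema_version, class, payload}. Matrices are encoded explicitly
# as {dim, data} (column-major) so round-trips are shape-exact; doubles are
# written at full precision so reloaded models predict bit-identically.

MODEL_SCHEMA <- "nitrauv/model"
MODEL_SCHEMA_VERSION <- 1L

enc_payload <- function(x) {
  if (is.matrix(x)) {
    list(`_matrix` = TRUE, dim = dim(x), data = as.vector(x))
  } else if (is.list(x)) {
    lapply(x, enc_payload)
  } else x
}

dec_payload <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$`_matrix`))
      return(matrix(as.numeric(unlist(x$data)), nrow = x$dim[[1]], ncol = x$dim[[2]]))
    return(lapply(x, dec_payload))
  }
  x
}

#' Save a fitted model to a JSON file
#'
#' @param model A fitted model object (`lns_model`, `tsc_model`, `kpls_model`,
#'   `wa_kpls_model`, `mlr_model` or `isus_model`).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  cls <- class(model)[1]
  known <- c("lns_model", "tsc_model", "kpls_model", "wa_kpls_model",
             "mlr_model", "isus_model")
  if (!cls %in% known)
    stop(sprintf("cannot serialize object of class '%s'", cls))
  obj <- list(schema = MODEL_SCHEMA,
              schema_version = MODEL_SCHEMA_VERSION,
              class = cls,
              payload = enc_payload(strip_classes(model)))
  # I(17) = 17 significant digits: doubles survive the round trip exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_classes)
  } else x
}

#' Load a fitted model from a JSON file
#'
#' @param path Path to a model JSON written by [save_model()].
#' @return The fitted model object, with derived quantities (e.g. the training
#'   kernel matrix) rebuilt from the stored inputs.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, MODEL_SCHEMA))
    stop("not a nitrauv model JSON file")
  payload <- dec_payload(obj$payload)
  restore_model(payload, obj$class)
}

restore_model <- function(p, cls) {
  num <- function(v) if (is.null(v)) NULL else as.numeric(unlist(v))
  switch(cls,
    lns_model = {
      p$coef <- as.matrix(p$coef)
      p$degrees <- as.integer(num(p$degrees))
      structure(p, class = "lns_model")
    },
    tsc_model = {
      p$lns <- restore_model(p$lns, "lns_model")
      p$model_window <- num(p$model_window)
      p$cdom_window <- num(p$cdom_window)
      structure(p, class = "tsc_model")
    },
    kpls_model = rebuild_kpls(p),
    wa_kpls_model = {
      p$models <- lapply(p$models, rebuild_kpls)
      p$weights <- num(p$weights)
      structure(p, class = "wa_kpls_model")
    },
    mlr_model = {
      p$coefficients <- num(p$coefficients)
      p$wavelengths <- num(p$wavelengths)
      structure(p, class = "mlr_model")
    },
    isus_model = {
      p$params <- num(p$params)
      names(p$params) <- c("A", "B", "C", "D")
      p$window <- num(p$window)
      p$extinction <- num(p$extinction)
      p$wavelengths <- num(p$wavelengths)
      if (!is.null(p$recalibration)) p$recalibration <- num(p$recalibration)
      structure(p, class = "isus_model")
    },
    stop(sprintf("unknown model class '%s' in JSON", cls))
  )
}

rebuild_kpls <- function(p) {
  p$X <- as.matrix(p$X)
  p$scores_t <- as.matrix(p$scores_t)
  p$scores_u <- as.matrix(p$scores_u)
  p$alpha <- as.matrix(p$alpha)
  p$y_mean <- as.numeric(unlist(p$y_mean))
  p$kernel <- kernel_spec(p$kernel$kind, gamma = p$kernel$gamma)
  # the raw training kernel is derived data; rebuild rather than store
  p$K <- kernel_matrix(p$X, p$X, p$kernel)
  structure(p, class = "kpls_model")
}
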