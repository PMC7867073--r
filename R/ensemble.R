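# Weighted-average KPLS (WA-KPLS).
#
# D KPLS sub-models are fitted on random eta% subsets of the training set;
# each sub-model j gets a weight proportional to 1/RMSEP_j, and the ensemble
# prediction is the weighted average of the sub-model predictions. Averaging
# learners fitted on perturbed training sets damps the over-fitting a single
# fully-extracted KPLS model is prone to.

#' Seeded random subsets of the training indices
#'
#' @param n Training-set size.
#' @param eta Subsample percentage, `0 < eta <= 100`.
#' @param D Number of subsets.
#' @param seed RNG seed.
#' @return A list of `D` integer vectors, each of `round(n * eta / 100)`
#'   distinct indices sampled without replacement, sorted ascending.
#' @export
subsample_indices <- function(n, eta, D, seed = 1) {
  stopifnot(n >= 1, D >= 1)
  if (!(eta > 0 && eta <= 100)) stop("eta must be in (0, 100]")
  size <- round(n * eta / 100)
  if (size < 2)
    stop(sprintf("eta = %g%% of n = %d gives subsets of size %d; need at least 2", eta, n, size))
  with_seed(seed, lapply(seq_len(D), function(j) sort(sample.int(n, size))))
}

#' Inverse-RMSEP sub-model weights
#'
#' `w_j = (1/RMSEP_j) / sum_k (1/RMSEP_k)`, with RMSEP values floored at
#' `epsilon` so an exactly-zero error does not divide by zero.
#'
#' @param rmseps Non-negative RMSEP values, one per sub-model.
#' @param epsilon Floor for zero RMSEP, default 1e-12.
#' @return Weights summing to 1, all positive.
#' @export
submodel_weights <- function(rmseps, epsilon = 1e-12) {
  if (length(rmseps) == 0) stop("empty RMSEP vector")
  if (any(!is.finite(rmseps)) || any(rmseps < 0))
    stop("RMSEP values must be finite and >= 0")
  inv <- 1 / pmax(rmseps, epsilon)
  inv / sum(inv)
}

#' Fit a weighted-average KPLS ensemble
#'
#' @param X Training inputs, `n x p`.
#' @param Y Training responses (vector or one-column matrix).
#' @param spec A `kernel_spec`; an unset RBF gamma is resolved once on the
#'   full training set and shared by every sub-model.
#' @param n_components Components per sub-model.
#' @param eta Subsample percentage (default 80).
#' @param D Number of sub-models (default 20).
#' @param seed RNG seed for the subsampling.
#' @param weight_basis `"train"`: RMSEP of each sub-model evaluated on the
#'   full training set (the literal reading of the weighting rule);
#'   `"oob"`: evaluated on the sub-model's held-out samples, which counters
#'   over-fitting more aggressively.
#' @param ... Passed to [fit_kpls()].
#' @return A `wa_kpls_model`.
#' @export
fit_wa_kpls <- function(X, Y, spec = kernel_spec("rbf"), n_components,
                        eta = 80, D = 20, seed = 1,
                        weight_basis = c("train", "oob"), ...) {
  weight_basis <- match.arg(weight_basis)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  spec <- resolve_gamma(spec, X)
  idx_sets <- subsample_indices(n, eta, D, seed)
  models <- vector("list", D)
  rmseps <- numeric(D)
  for (j in seq_len(D)) {
    idx <- idx_sets[[j]]
    models[[j]] <- tryCatch(
      fit_kpls(X[idx, , drop = FALSE], Y[idx, , drop = FALSE], spec,
               n_components = n_components, ...),
      error = function(e) stop(sprintf("sub-model %d failed: %s", j, conditionMessage(e))))
    if (weight_basis == "train") {
      pred <- predict_kpls(models[[j]], X)
      rmseps[j] <- rmsep(drop(Y), drop(pred))
    } else {
      hold <- setdiff(seq_len(n), idx)
      if (length(hold) == 0) {
        warning(sprintf("sub-model %d has no held-out samples (eta = 100); using training RMSEP", j))
        hold <- seq_len(n)
      }
      pred <- predict_kpls(models[[j]], X[hold, , drop = FALSE])
      rmseps[j] <- rmsep(drop(Y)[hold], drop(pred))
    }
  }
  structure(list(models = models, weights = submodel_weights(rmseps),
                 rmseps = rmseps, eta = eta, D = D, seed = seed,
                 weight_basis = weight_basis, kernel = spec,
                 n_components = as.integer(n_components)),
            class = "wa_kpls_model")
}

#' @export
print.wa_kpls_model <- function(x, ...) {
  cat(sprintf("<wa_kpls_model> D = %d sub-models, eta = %g%%, %d components, %s kernel\n",
              x$D, x$eta, x$n_components, x$kernel$kind))
  invisible(x)
}

#' Predict from a WA-KPLS ensemble
#'
#' Weighted sum of the sub-model predictions.
#'
#' @param model A `wa_kpls_model`.
#' @param X_new New inputs.
#' @return Prediction vector.
#' @export
predict_wa_kpls <- function(model, X_new) {
  stopifnot(inherits(model, "wa_kpls_model"))
  preds <- vapply(seq_along(model$models),
                  function(j) drop(predict_kpls(model$models[[j]], X_new)),
                  numeric(nrow(as.matrix(X_new))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% model$weights)
}
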