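# Kernel partial least squares (KPLS).
#
# PLS performed in the implicit feature space of a kernel function
# K(x_i, x_j) = <phi(x_i), phi(x_j)>. Components are extracted by a
# NIPALS-style iteration on the centered kernel with deflation
#   K <- (I - t t') K (I - t t'),  Y <- Y - t t' Y,
# and the regression operates through the dual coefficients
#   alpha = U (T' K U)^-1 T' Y
# (K the original centered training kernel), so that fitted values are
# K alpha and test predictions are Kt alpha with Kt the centered test kernel.

#' Kernel specification
#'
#' @param kind `"linear"` (`<z, x>`) or `"rbf"` (`exp(-gamma ||z - x||^2)`).
#' @param gamma RBF width parameter (1/units^2 of the inputs); must be > 0
#'   when given. `NULL` requests the median heuristic: at fit time the kernel
#'   width sigma is set to the median pairwise Euclidean distance between
#'   training rows and `gamma = 1 / (2 sigma^2)`.
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), gamma = NULL) {
  kind <- match.arg(kind)
  if (!is.null(gamma)) {
    gamma <- as.numeric(gamma)
    if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0")
  }
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

#' Kernel matrix between two input sets
#'
#' @param X Training-side inputs, `n x p` matrix.
#' @param Z Evaluation-side inputs, `m x p` matrix.
#' @param spec A `kernel_spec`; for `"rbf"` the gamma must be resolved.
#' @return The `m x n` matrix with entries `K(z_i, x_j)`.
#' @export
kernel_matrix <- function(X, Z, spec) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  stopifnot(inherits(spec, "kernel_spec"))
  if (ncol(X) != ncol(Z))
    stop(sprintf("input dimension mismatch: %d vs %d columns", ncol(Z), ncol(X)))
  if (spec$kind == "linear") return(Z %*% t(X))
  if (is.null(spec$gamma))
    stop("rbf kernel needs a resolved gamma; fit a model or supply one")
  d2 <- outer(rowSums(Z^2), rowSums(X^2), `+`) - 2 * Z %*% t(X)
  exp(-spec$gamma * pmax(d2, 0))
}

#' Resolve an unset RBF gamma by the median heuristic
#'
#' Sets the kernel width to the median pairwise Euclidean distance sigma
#' between training rows, i.e. `gamma = 1 / (2 sigma^2)` in the Gaussian
#' kernel `exp(-||x - z||^2 / (2 sigma^2))`.
#'
#' @param spec A `kernel_spec`.
#' @param X Training inputs. For large n a deterministic subset of at most
#'   256 evenly spaced rows is used.
#' @return A `kernel_spec` with gamma filled in.
#' @export
resolve_gamma <- function(spec, X) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$kind != "rbf" || !is.null(spec$gamma)) return(spec)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n > 256) X <- X[round(seq(1, n, length.out = 256)), , drop = FALSE]
  sigma <- stats::median(stats::dist(X))
  if (!is.finite(sigma) || sigma <= 0)
    stop("median pairwise distance is zero; supply gamma explicitly")
  kernel_spec("rbf", gamma = 1 / (2 * sigma^2))
}

#' Center a training kernel matrix
#'
#' Feature-space centering: `(I - 1/n 11') K (I - 1/n 11')`.
#'
#' @param K The `n x n` training kernel.
#' @return The centered kernel.
#' @export
center_train_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("training kernel must be square")
  rm_ <- rowMeans(K)
  cm_ <- colMeans(K)
  K - outer(rm_, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm_) + mean(K)
}

#' Center a test kernel against its training kernel
#'
#' `(Kt - 1/n 1_m 1_n' K)(I - 1/n 1_n 1_n')` with `K` the uncentered
#' training kernel and `Kt` the uncentered test-vs-train kernel.
#'
#' @param Kt The `m x n` test kernel.
#' @param K The `n x n` uncentered training kernel.
#' @return The centered test kernel.
#' @export
center_test_kernel <- function(Kt, K) {
  Kt <- as.matrix(Kt); K <- as.matrix(K)
  if (ncol(Kt) != nrow(K) || nrow(K) != ncol(K))
    stop("size mismatch between test and training kernels")
  n <- nrow(K)
  Ktc <- sweep(Kt, 2, colMeans(K))        # Kt - 1_m (colMeans K)'
  Ktc <- Ktc - (rowMeans(Kt) - mean(K))   # right-multiply by (I - 1/n 11')
  Ktc
}

#' Fit a kernel partial least squares model
#'
#' Extracts `n_components` score pairs by the NIPALS iteration
#' `t = K u; t <- t/||t||; c = Y' t; u = Y c; u <- u/||u||` on the centered
#' kernel and column-centered response, deflating both after each component.
#' With a single response column the iteration converges in one pass.
#'
#' @param X Training inputs, `n x p` matrix (stored for test-kernel
#'   evaluation).
#' @param Y Responses: length-n vector or `n x m` matrix. Centered
#'   internally; the mean is restored at prediction.
#' @param spec A `kernel_spec`; an unset RBF gamma is resolved by the median
#'   heuristic and stored.
#' @param n_components Number of components A, `1 <= A <= n - 1`.
#' @param tol Convergence tolerance on the score update, default 1e-10.
#' @param max_iter Inner-iteration cap, default 500 (warns on
#'   non-convergence and keeps the current score).
#' @param u_init `"y1"` (deterministic, first column of the current response)
#'   or `"random"` (seeded random start, for fidelity with the randomized
#'   initialization described for the algorithm).
#' @param seed Seed for `u_init = "random"`.
#' @return A `kpls_model`.
#' @export
fit_kpls <- function(X, Y, spec = kernel_spec("rbf"), n_components,
                     tol = 1e-10, max_iter = 500,
                     u_init = c("y1", "random"), seed = 1) {
  u_init <- match.arg(u_init)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training samples")
  if (nrow(Y) != n) stop("X and Y row counts differ")
  A <- as.integer(n_components)
  if (A < 1 || A > n - 1)
    stop(sprintf("n_components must be between 1 and n - 1 = %d", n - 1))
  spec <- resolve_gamma(spec, X)
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2, y_mean)
  K <- kernel_matrix(X, X, spec)
  Kc <- center_train_kernel(K)
  Kd <- Kc
  Yd <- Yc
  Tm <- matrix(0, n, A)
  Um <- matrix(0, n, A)
  if (u_init == "random") {
    rand_u <- with_seed(seed, matrix(stats::rnorm(n * A), n, A))
  }
  for (a in seq_len(A)) {
    u <- if (u_init == "y1") Yd[, 1] else rand_u[, a]
    if (sqrt(sum(u^2)) < .Machine$double.eps^0.5)
      u <- rep(1, n)  # degenerate deflated response; fall back to a flat start
    t_old <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t_new <- drop(Kd %*% u)
      nt <- sqrt(sum(t_new^2))
      if (nt < 1e-12)
        stop(sprintf("zero-norm score while extracting component %d; reduce n_components", a))
      t_new <- t_new / nt
      cc <- crossprod(Yd, t_new)
      u <- drop(Yd %*% cc)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-12)
        stop(sprintf("zero-norm response weight while extracting component %d; reduce n_components", a))
      u <- u / nu
      if (sqrt(sum((t_new - t_old)^2)) < tol) { converged <- TRUE; t_old <- t_new; break }
      t_old <- t_new
    }
    if (!converged && max_iter > 1)
      warning(sprintf("component %d: inner iteration did not converge in %d iterations", a, max_iter))
    t_cur <- t_old
    Tm[, a] <- t_cur
    Um[, a] <- u
    # deflate: K <- (I - tt')K(I - tt'), Y <- Y - tt'Y
    Kt_ <- drop(crossprod(t_cur, Kd))          # t'K
    Ktt <- drop(Kt_ %*% t_cur)                 # t'Kt
    Kd <- Kd - outer(t_cur, Kt_) - outer(drop(Kd %*% t_cur), t_cur) +
      Ktt * outer(t_cur, t_cur)
    Kd <- (Kd + t(Kd)) / 2                     # keep symmetric against round-off
    Yd <- Yd - outer(t_cur, drop(crossprod(t_cur, Yd)))
  }
  M <- crossprod(Tm, Kc %*% Um)                # T'KU, A x A
  alpha <- tryCatch(Um %*% solve(M, crossprod(Tm, Yc)),
                    error = function(e) stop("singular (T'KU); reduce n_components"))
  structure(list(X = X, kernel = spec, n_components = A,
                 scores_t = Tm, scores_u = Um, K = K,
                 alpha = alpha, y_mean = y_mean,
                 Yc = Yc),
            class = "kpls_model")
}

#' @export
print.kpls_model <- function(x, ...) {
  cat(sprintf("<kpls_model> %d components, %s kernel%s, n = %d, p = %d\n",
              x$n_components, x$kernel$kind,
              if (x$kernel$kind == "rbf") sprintf(" (gamma = %.4g)", x$kernel$gamma) else "",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' Predict from a fitted KPLS model
#'
#' Builds the test kernel against the stored training inputs, centers it, and
#' applies the dual regression coefficients; the training response mean is
#' added back.
#'
#' @param model A `kpls_model`.
#' @param X_new New inputs, `m x p` matrix (p as in training).
#' @return Predictions: a vector for single-response models, else a matrix.
#' @export
predict_kpls <- function(model, X_new) {
  stopifnot(inherits(model, "kpls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != ncol(model$X))
    stop(sprintf("X_new has %d columns; training had %d", ncol(X_new), ncol(model$X)))
  Kt <- kernel_matrix(model$X, X_new, model$kernel)
  Ktc <- center_test_kernel(Kt, model$K)
  pred <- sweep(Ktc %*% model$alpha, 2, model$y_mean, `+`)
  if (ncol(pred) == 1) drop(pred) else pred
}

#' Fitted training values of a KPLS model
#'
#' @param model A `kpls_model`.
#' @param n_components Optionally evaluate with only the leading components.
#' @return Fitted values on the training set.
#' @export
fitted_kpls <- function(model, n_components = model$n_components) {
  A <- as.integer(n_components)
  stopifnot(A >= 1, A <= model$n_components)
  Kc <- center_train_kernel(model$K)
  Tm <- model$scores_t[, seq_len(A), drop = FALSE]
  Um <- model$scores_u[, seq_len(A), drop = FALSE]
  M <- crossprod(Tm, Kc %*% Um)
  alpha <- Um %*% solve(M, crossprod(Tm, model$Yc))
  pred <- sweep(Kc %*% alpha, 2, model$y_mean, `+`)
  if (ncol(pred) == 1) drop(pred) else pred
}

#' Select the number of KPLS components by a training-R^2 threshold
#'
#' Fits up to `a_max` components once (the NIPALS components are nested) and
#' returns the smallest count whose training R^2 meets the threshold; if the
#' threshold is never reached, returns `a_max` with a warning.
#'
#' @param X,Y,spec As in [fit_kpls()].
#' @param r2_threshold Training R^2 requirement; the reference criterion is
#'   0.9995.
#' @param a_max Largest component count to consider (`<= n - 1`).
#' @param ... Passed to [fit_kpls()].
#' @return Integer component count, with the fitted `a_max`-component model
#'   attached as attribute `"model"` and the R^2 path as attribute `"r2"`.
#' @export
select_components <- function(X, Y, spec = kernel_spec("rbf"),
                              r2_threshold = 0.9995, a_max, ...) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (missing(a_max)) a_max <- min(nrow(X) - 1L, 30L)
  a_max <- as.integer(min(a_max, nrow(X) - 1L))
  model <- NULL
  for (A_try in rev(seq_len(a_max))) {
    model <- tryCatch(fit_kpls(X, Y, spec, n_components = A_try, ...),
                      error = function(e) NULL)
    if (!is.null(model)) { a_max <- A_try; break }
  }
  if (is.null(model)) stop("could not extract even one component")
  r2_path <- vapply(seq_len(a_max), function(A) {
    f <- as.matrix(fitted_kpls(model, A))
    1 - sum((Y - f)^2) / sum(sweep(Y, 2, colMeans(Y))^2)
  }, numeric(1))
  hit <- which(r2_path >= r2_threshold)
  A_sel <- if (length(hit)) min(hit) else {
    warning(sprintf("training R^2 never reached %g; returning a_max = %d",
                    r2_threshold, a_max))
    a_max
  }
  structure(as.integer(A_sel), model = model, r2 = r2_path)
}
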