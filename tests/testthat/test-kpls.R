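test_that("kernel matrices match hand calculations and are symmetric", {
  X <- rbind(c(1, 0), c(0, 2))
  expect_equal(kernel_matrix(X, X, kernel_spec("linear")),
               rbind(c(1, 0), c(0, 4)))
  set.seed(1)
  Z <- matrix(rnorm(21), 7, 3)
  for (g in c(0.1, 1, 5)) {
    K <- kernel_matrix(Z, Z, kernel_spec("rbf", gamma = g))
    expect_equal(diag(K), rep(1, 7))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_true(all(K > 0 & K <= 1))
  }
  expect_error(kernel_matrix(X, matrix(0, 2, 3), kernel_spec("linear")), "dimension")
  expect_error(kernel_matrix(X, X, kernel_spec("rbf")), "gamma")
  expect_error(kernel_spec("rbf", gamma = -1), "gamma")
})

test_that("kernel centering matches the explicit feature-space construction", {
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  Z <- matrix(rnorm(12), 4, 3)
  K <- kernel_matrix(X, X, kernel_spec("linear"))
  Kc <- center_train_kernel(K)
  expect_lt(max(abs(rowSums(Kc))), 1e-10)
  expect_lt(max(abs(colSums(Kc))), 1e-10)
  expect_equal(center_train_kernel(Kc), Kc, tolerance = 1e-10)
  # centering the linear kernel == kernel of the column-centered inputs
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(Kc, Xc %*% t(Xc), tolerance = 1e-10)
  # test-kernel centering likewise: (Z - mean_X) (X - mean_X)'
  Kt <- kernel_matrix(X, Z, kernel_spec("linear"))
  expect_equal(center_test_kernel(Kt, K),
               sweep(Z, 2, colMeans(X)) %*% t(Xc), tolerance = 1e-10)
  expect_error(center_test_kernel(Kt, K[1:9, 1:9]), "mismatch")
})

test_that("an exactly linear response is fitted to machine precision at full rank", {
  set.seed(3)
  X <- matrix(rnorm(60), 15, 4)
  y <- drop(X %*% c(2, -1, 0.5, 3)) + 4
  m <- fit_kpls(X, y, kernel_spec("linear"), n_components = 4)
  expect_lt(rmsep(y, fitted_kpls(m)), 1e-8)
  expect_equal(predict_kpls(m, X), fitted_kpls(m), tolerance = 1e-10)
  # a duplicated training row used as test input reproduces its fitted value
  expect_equal(predict_kpls(m, X[c(3, 3), ])[1], fitted_kpls(m)[3],
               tolerance = 1e-10)
})

test_that("single-response extraction converges in one inner pass", {
  set.seed(4)
  X <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  # with u proportional to the (deflated) response, two iterations suffice;
  # a capped run must agree with the fully iterated one and not warn
  m2 <- suppressWarnings(fit_kpls(X, y, kernel_spec("rbf"), 3, max_iter = 2))
  m500 <- fit_kpls(X, y, kernel_spec("rbf"), 3, max_iter = 500)
  expect_equal(m2$scores_t, m500$scores_t, tolerance = 1e-12)
  expect_no_warning(fit_kpls(X, y, kernel_spec("rbf"), 3))
})

test_that("a two-sample problem matches the hand-solved single component", {
  # n = 2: centered y = (d, -d)/..; centered K = s [[1,-1],[-1,1]];
  # the single score is (1,-1)/sqrt(2) up to sign and the fit is exact
  X <- rbind(c(0, 0), c(1, 1))
  y <- c(1, 3)
  m <- fit_kpls(X, y, kernel_spec("linear"), n_components = 1)
  expect_equal(abs(m$scores_t[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(fitted_kpls(m), y, tolerance = 1e-10)
  expect_equal(predict_kpls(m, rbind(c(0.5, 0.5))), 2, tolerance = 1e-10)
})

test_that("linear-kernel KPLS agrees with an independent classical PLS implementation", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(8:20, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    Xn <- matrix(rnorm(4 * p), 4, p)
    for (A in seq_len(p)) {
      m <- fit_kpls(X, y, kernel_spec("linear"), n_components = A)
      expect_equal(predict_kpls(m, Xn), pls1_oracle(X, y, A, Xn), tolerance = 1e-6)
    }
  }
})

test_that("scores are orthonormal and training R^2 never decreases with components", {
  set.seed(6)
  X <- matrix(rnorm(25 * 5), 25, 5)
  y <- drop(X %*% rnorm(5)) + 0.3 * rnorm(25)
  m <- fit_kpls(X, y, kernel_spec("rbf"), n_components = 8)
  G <- crossprod(m$scores_t)
  expect_equal(G, diag(8), tolerance = 1e-8)
  r2 <- vapply(1:8, function(A) r_squared(y, fitted_kpls(m, A)), numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("component selection follows the training-R^2 threshold rule", {
  set.seed(7)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- drop(X %*% c(1, 2, -1))
  A <- select_components(X, y, kernel_spec("linear"), r2_threshold = 0.9995, a_max = 6)
  expect_equal(as.integer(A), 3)                      # rank of the signal
  expect_equal(attr(A, "r2")[3], 1, tolerance = 1e-8)
  # a threshold of zero is met by the first component
  expect_equal(as.integer(select_components(X, y, kernel_spec("linear"),
                                            r2_threshold = 0, a_max = 6)), 1)
  # pure noise never reaches the threshold: a_max with a warning
  y2 <- rnorm(20)
  expect_warning(
    A2 <- select_components(X, y2, kernel_spec("linear"), r2_threshold = 0.9995,
                            a_max = 3),
    "never reached")
  expect_equal(as.integer(A2), 3)
})

test_that("degenerate extractions are refused with informative errors", {
  X <- matrix(rnorm(20), 10, 2)
  y <- rnorm(10)
  expect_error(fit_kpls(X, y, kernel_spec("linear"), n_components = 12), "n_components")
  # rank-1 inputs cannot supply a third linear component
  X1 <- cbind(1:10, 2 * (1:10))
  expect_error(fit_kpls(X1, y, kernel_spec("linear"), n_components = 5),
               "zero-norm|singular")
})
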