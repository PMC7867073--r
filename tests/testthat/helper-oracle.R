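# Independent classical PLS1 oracle (X-space NIPALS with loading deflation),
# used to cross-check the kernel implementation through a different algebraic
# route. Verified once against scikit-learn's PLSRegression during
# development; kept free of any code path it checks.
pls1_oracle <- function(X, y, ncomp, Xnew = X) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  Xd <- sweep(X, 2, xm); yd <- y - ym
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd)); w <- w / sqrt(sum(w^2))
    t_ <- drop(Xd %*% w)
    pp <- drop(crossprod(Xd, t_)) / sum(t_^2)
    q <- sum(yd * t_) / sum(t_^2)
    Xd <- Xd - outer(t_, pp); yd <- yd - t_ * q
    W[, a] <- w; P[, a] <- pp; Q[a] <- q
  }
  B <- W %*% solve(crossprod(P, W), Q)
  drop(sweep(as.matrix(Xnew), 2, xm) %*% B) + ym
}

# small random labeled table for I/O round-trip tests
random_table <- function(n = 5, grid = seq(208, 212, by = 0.4), seed = 99) {
  set.seed(seed)
  sample_table(sprintf("s%02d", 1:n), grid,
               matrix(runif(n * length(grid)), n),
               temperature = runif(n, 4, 25),
               salinity = runif(n, 30, 35),
               reference_conc = c(NA, runif(n - 1, 0, 100)))
}
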