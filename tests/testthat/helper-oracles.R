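# Shared fixtures and independent oracles for the test suite.

# Unpenalized PLS2 by classical NIPALS with regression-mode deflation of
# both blocks. Written independently of the package internals: component
# weights come from the alternating y-score/x-weight NIPALS recursion, not
# from the package's cross-product sparsification path.
nipals_pls2 <- function(X, Y, ncomp, scale = TRUE, tol = 1e-12,
                        max_iter = 1000) {
  Xc <- base::scale(X, center = TRUE, scale = scale)
  Yc <- base::scale(Y, center = TRUE, scale = FALSE)
  U <- matrix(0, ncol(X), ncomp)
  V <- matrix(0, ncol(Y), ncomp)
  S <- matrix(0, nrow(X), ncomp)
  C <- matrix(0, ncol(X), ncomp)
  D <- matrix(0, ncol(Y), ncomp)
  for (h in seq_len(ncomp)) {
    u <- svd(crossprod(Xc, Yc))$u[, 1]
    for (it in seq_len(max_iter)) {
      xi <- Xc %*% u
      v <- crossprod(Yc, xi); v <- v / sqrt(sum(v^2))
      omega <- Yc %*% v
      u_new <- crossprod(Xc, omega); u_new <- u_new / sqrt(sum(u_new^2))
      if (max(abs(u_new - u)) < tol) { u <- u_new; break }
      u <- u_new
    }
    xi <- drop(Xc %*% u)
    cc <- drop(crossprod(Xc, xi)) / sum(xi^2)
    dd <- drop(crossprod(Yc, xi)) / sum(xi^2)
    Xc <- Xc - tcrossprod(xi, cc)
    Yc <- Yc - tcrossprod(xi, dd)
    U[, h] <- u; V[, h] <- v; S[, h] <- xi; C[, h] <- cc; D[, h] <- dd
  }
  list(U = U, V = V, scores = S, C = C, D = D)
}

# flip the sign of oracle vectors to match a reference (sign is arbitrary)
align_sign <- function(x, ref) if (sum(x * ref) < 0) -x else x

# small random multiclass dataset with named dims
random_dataset <- function(n = 20, p = 30, K = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(paste0("s", seq_len(n)),
                                paste0("g", seq_len(p))))
    y <- stats::setNames(rep(paste0("c", seq_len(K)), length.out = n),
                         rownames(X))
    list(X = X, y = y)
  })
}
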