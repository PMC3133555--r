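test_that("soft-thresholding matches its closed form and contracts", {
  expect_equal(soft_threshold(c(0.5, -0.3, 0.1), 0.2), c(0.3, -0.1, 0))
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_identical(soft_threshold(x, 0), x)
  expect_equal(soft_threshold(0.1, 0.5), 0)
  expect_error(soft_threshold(x, -1), "nonnegative")

  # componentwise contraction toward zero for random inputs and lambdas
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(50); lam <- runif(1, 0, 2)
      out <- soft_threshold(x, lam)
      expect_true(all(abs(out) <= abs(x) + 1e-15))
      expect_true(all(out * x >= 0))  # sign preserved or zeroed
    }
  })
})

test_that("keepX maps to the (keepX+1)-th largest threshold", {
  expect_equal(sparsify_to_keepx(c(0.5, -0.3, 0.1), 2), c(0.4, -0.2, 0))
  x <- rnorm(10)
  expect_identical(sparsify_to_keepx(x, 10), x)
  expect_warning(out <- sparsify_to_keepx(c(0.5, 0.5, 0.5), 2),
                 "hard selection")
  expect_equal(out, c(0.5, 0.5, 0))  # ties broken by lowest index, unshrunk
  expect_error(sparsify_to_keepx(x, 0), "keepX")
  expect_error(sparsify_to_keepx(x, 11), "keepX")

  # generic input: exactly keepX nonzeros
  withr::with_seed(12, {
    for (k in c(1, 3, 7)) {
      expect_equal(sum(sparsify_to_keepx(rnorm(20), k) != 0), k)
    }
  })
})

test_that("unpenalized component recovers the dominant singular pair", {
  d <- random_dataset(n = 6, p = 4, K = 2, seed = 3)
  Xc <- scale(d$X[, 1:4], scale = FALSE)
  Y <- scale(encode_dummy(d$y), scale = FALSE)
  comp <- fit_component(Xc, Y, keepX = 4)
  sv <- svd(crossprod(Xc, Y))
  u_ref <- align_sign(sv$u[, 1], comp$u)
  v_ref <- align_sign(sv$v[, 1], comp$v)
  expect_lt(max(abs(comp$u - u_ref)), 1e-8)
  expect_lt(max(abs(comp$v - v_ref)), 1e-8)
  expect_true(comp$converged)
})

test_that("rank-one cross-product converges immediately to its factors", {
  a <- c(3, -1, 2, 0.5); b <- c(1, -2)
  # build X, Y with crossprod(X, Y) = a b'
  X <- diag(4); Y <- tcrossprod(diag(4) %*% a, b) / 1  # X'Y = a b'
  comp <- fit_component(X, Y, keepX = 4)
  expect_lt(max(abs(comp$u - align_sign(a / sqrt(sum(a^2)), comp$u))), 1e-10)
  expect_lt(max(abs(comp$v - align_sign(b / sqrt(sum(b^2)), comp$v))), 1e-10)
})

test_that("keepX = 1 finds the single best feature by exhaustive search", {
  d <- random_dataset(n = 15, p = 8, K = 3, seed = 9)
  Xc <- scale(d$X)
  Y <- scale(encode_dummy(d$y), scale = FALSE)
  comp <- fit_component(Xc, Y, keepX = 1)
  sel <- which(comp$u != 0)
  expect_length(sel, 1)
  # brute force: for each single feature j, the best achievable covariance
  # cov(X e_j, Y v) over unit v is ||Y' X_j||
  scores <- apply(Xc, 2, function(xj) sqrt(sum(crossprod(Y, xj)^2)))
  expect_equal(sel, which.max(scores), ignore_attr = TRUE)
})

test_that("deflation residual is orthogonal to the score", {
  d <- random_dataset(n = 10, p = 8, K = 2, seed = 5)
  Xc <- scale(d$X)
  Y <- scale(encode_dummy(d$y), scale = FALSE)
  comp <- fit_component(Xc, Y, keepX = 8)
  defl <- deflate(Xc, Y, comp)
  expect_lt(max(abs(crossprod(comp$xi, defl$X))), 1e-8)
  # rank-1 X deflated by its own component vanishes
  X1 <- tcrossprod(rnorm(6), rnorm(4))
  Y1 <- matrix(X1 %*% rnorm(4), 6, 1)
  c1 <- fit_component(X1, Y1, keepX = 4)
  d1 <- deflate(X1, Y1, c1)
  expect_lt(max(abs(d1$X)), 1e-10)
  expect_error(deflate(Xc[, 1:3], Y, comp), "mismatch")
})

test_that("full-keepX multi-component fit matches the NIPALS PLS2 oracle", {
  d <- random_dataset(n = 20, p = 30, K = 3, seed = 42)
  Y <- encode_dummy(d$y)
  fit <- fit_spls(d$X, Y, ncomp = 2, scale = TRUE)
  or <- nipals_pls2(d$X, Y, ncomp = 2, scale = TRUE)
  for (h in 1:2) {
    expect_lt(max(abs(fit$components[[h]]$u -
                        align_sign(or$U[, h], fit$components[[h]]$u))), 1e-8)
    expect_lt(max(abs(fit$scores[, h] -
                        align_sign(or$scores[, h], fit$scores[, h]))), 1e-8)
  }
})

test_that("scores are mutually orthogonal across dimensions and keepX", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(10:25, 1); p <- sample(8:40, 1)
      d <- random_dataset(n = n, p = p, K = 3, seed = i + 100)
      keepX <- sample(seq(2, p), 3, replace = TRUE)
      fit <- fit_spls(d$X, encode_dummy(d$y), ncomp = 3, keepX = keepX)
      S <- fit$scores
      for (h in 1:(fit$H - 1)) for (l in (h + 1):fit$H) {
        expect_lt(abs(sum(S[, h] * S[, l])),
                  1e-8 * sqrt(sum(S[, h]^2) * sum(S[, l]^2)))
      }
    }
  })
})

test_that("sequential and closed-form predictions agree", {
  withr::with_seed(5, {
    for (i in 1:5) {
      d <- random_dataset(n = 12, p = 6, K = 2, seed = i)
      fit <- fit_spls(d$X, encode_dummy(d$y), ncomp = 3,
                      keepX = c(6, 4, 2))
      Xnew <- matrix(rnorm(5 * 6), 5, 6,
                     dimnames = list(NULL, colnames(d$X)))
      p_seq <- predict_response(fit, Xnew, ncomp = 3)
      p_cf <- predict_response(fit, Xnew, ncomp = 3,
                               method = "closed_form")
      expect_lt(max(abs(p_seq$Y_hat - p_cf$Y_hat)), 1e-10)
    }
  })
})

test_that("training prediction reproduces scores-times-loadings exactly", {
  d <- random_dataset(n = 14, p = 10, K = 3, seed = 8)
  Y <- encode_dummy(d$y)
  fit <- fit_spls(d$X, Y, ncomp = 2, keepX = 5)
  pred <- predict_response(fit, d$X, ncomp = 2)
  D <- vapply(fit$components, `[[`, numeric(3), "d")
  manual <- sweep(fit$scores %*% t(D), 2, fit$y_means, "+")
  expect_lt(max(abs(pred$Y_hat - manual)), 1e-12)
  expect_lt(max(abs(pred$scores - fit$scores)), 1e-12)
})

test_that("fit is invariant to feature permutation", {
  d <- random_dataset(n = 16, p = 12, K = 2, seed = 21)
  perm <- withr::with_seed(22, sample(12))
  f1 <- fit_spls(d$X, encode_dummy(d$y), ncomp = 2, keepX = 4)
  f2 <- fit_spls(d$X[, perm], encode_dummy(d$y), ncomp = 2, keepX = 4)
  for (h in 1:2) {
    expect_equal(f2$components[[h]]$u[order(perm)],
                 f1$components[[h]]$u, tolerance = 1e-10)
    expect_equal(f2$scores[, h], f1$scores[, h], tolerance = 1e-10)
  }
})

test_that("model JSON serialization round-trips floats exactly", {
  d <- random_dataset(n = 12, p = 9, K = 3, seed = 30)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = c(4, 3))
  tf <- withr::local_tempfile(fileext = ".json")
  write_model(fit, tf)
  back <- read_model(tf)
  expect_identical(back$classes, fit$classes)
  expect_identical(back$core$keepX, fit$core$keepX)
  for (h in 1:2) {
    expect_identical(back$core$components[[h]]$u, fit$core$components[[h]]$u)
    expect_identical(back$core$components[[h]]$d, fit$core$components[[h]]$d)
  }
  # predictions from the reloaded model are identical
  p1 <- predict_classes(fit, d$X)
  p2 <- predict_classes(back, d$X)
  expect_identical(unname(p1$predicted_labels), unname(p2$predicted_labels))
  expect_equal(p1$decision_values, p2$decision_values, tolerance = 0)
})

test_that("degenerate inputs raise the documented errors", {
  d <- random_dataset(n = 10, p = 6, K = 2, seed = 40)
  Y <- encode_dummy(d$y)
  expect_error(fit_component(matrix(0, 10, 6), Y - rep(colMeans(Y),
               each = 10), keepX = 3), "no covariance")
  # ncomp beyond rank stops early with a warning
  Xr1 <- tcrossprod(rnorm(10), rnorm(6))
  colnames(Xr1) <- paste0("g", 1:6); rownames(Xr1) <- paste0("s", 1:10)
  expect_warning(fit <- fit_spls(Xr1, Y, ncomp = 3, scale = FALSE),
                 "stopping early")
  expect_lt(fit$H, 3)
})
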