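test_that("separable two-class data is perfectly fit with one dimension", {
  sim <- simulate_expression(synthetic_spec(K = 2, n_per_class = 20, p = 50,
                                            q = 5, delta = 3, rho = 0,
                                            seed = 1))
  fit <- splsda(sim$X, sim$labels, ncomp = 1, keepX = 5)
  pred <- predict_classes(fit, sim$X, distance = "max")
  expect_equal(error_rate(pred$predicted_labels, sim$labels), 0)
  # and the selected 5 features are informative ones
  expect_true(all(selected_variables(fit, 1)$feature_id %in%
                    sim$true_support))
})

test_that("keepX = p reduces to classical PLS-DA", {
  d <- random_dataset(n = 18, p = 12, K = 3, seed = 2)
  fit_sparse <- splsda(d$X, d$y, ncomp = 2, keepX = 12)
  fit_plain <- splsda(d$X, d$y, ncomp = 2)  # default keepX = p
  for (h in 1:2)
    expect_identical(fit_sparse$core$components[[h]]$u,
                     fit_plain$core$components[[h]]$u)
  # all features carry nonzero weight somewhere
  expect_equal(nrow(selected_variables(fit_plain, "all")), 12)
})

test_that("decision rules argmax correctly and break ties low", {
  d <- random_dataset(n = 15, p = 10, K = 3, seed = 4)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = 5)
  pred <- predict_classes(fit, d$X)
  expect_identical(
    unname(pred$predicted_labels),
    fit$classes[apply(pred$decision_values, 1, which.max)])
  # explicit tie-break check on the documented contract
  expect_equal(which.max(c(0.5, 0.5)), 1L)
  expect_identical(colnames(pred$decision_values), fit$classes)
})

test_that("max-distance decision rows sum to one on training data", {
  d <- random_dataset(n = 21, p = 15, K = 3, seed = 6)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = 7)
  pred <- predict_classes(fit, d$X, distance = "max")
  # least squares onto centered dummy + re-added class means preserves the
  # row-sum of the simplex coding
  expect_true(all(abs(rowSums(pred$decision_values) - 1) < 1e-6))
})

test_that("max and centroid rules agree on well-separated classes", {
  sim <- simulate_expression(synthetic_spec(K = 2, n_per_class = 15, p = 40,
                                            q = 6, delta = 3, rho = 0,
                                            seed = 11))
  fit <- splsda(sim$X, sim$labels, ncomp = 1, keepX = 6)
  test <- simulate_expression(synthetic_spec(K = 2, n_per_class = 10, p = 40,
                                             q = 6, delta = 3, rho = 0,
                                             seed = 12))
  p_max <- predict_classes(fit, test$X, distance = "max")
  p_cen <- predict_classes(fit, test$X, distance = "centroid")
  p_mah <- predict_classes(fit, test$X, distance = "mahalanobis")
  expect_identical(p_max$predicted_labels, p_cen$predicted_labels)
  expect_identical(p_cen$predicted_labels, p_mah$predicted_labels)
  # centroid decisions are negative distances: the chosen class maximizes
  expect_true(all(p_cen$decision_values <= 0))
})

test_that("prediction is invariant to class relabeling order", {
  d <- random_dataset(n = 24, p = 10, K = 3, seed = 14)
  fit1 <- splsda(d$X, d$y, ncomp = 2)
  # present the same samples with a different first-appearance order
  ord <- order(match(d$y, c("c3", "c1", "c2")))
  fit2 <- splsda(d$X[ord, ], d$y[ord], ncomp = 2)
  Xnew <- random_dataset(n = 10, p = 10, K = 2, seed = 15)$X
  p1 <- predict_classes(fit1, Xnew)$predicted_labels
  p2 <- predict_classes(fit2, Xnew)$predicted_labels
  expect_identical(unname(p1), unname(p2))
})

test_that("selected_variables reports supports and exact weights", {
  d <- random_dataset(n = 20, p = 30, K = 3, seed = 16)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = 10)
  for (h in 1:2) {
    sel <- selected_variables(fit, h)
    expect_equal(nrow(sel), 10)
    u <- fit$core$components[[h]]$u
    names(u) <- fit$core$feature_ids
    expect_equal(sel$weight, unname(u[sel$feature_id]))
    expect_false(is.unsorted(rev(sel$abs_weight)))
  }
  union <- selected_variables(fit, "all")
  expect_lte(nrow(union), 20)
  expect_error(selected_variables(fit, 3), "range")
})

test_that("labels are matched to samples by name, not position", {
  d <- random_dataset(n = 12, p = 8, K = 2, seed = 18)
  shuffled <- withr::with_seed(19, sample(d$y))
  fit1 <- splsda(d$X, d$y, ncomp = 1)
  fit2 <- splsda(d$X, shuffled, ncomp = 1)  # named: realigned to rownames
  expect_identical(fit1$core$components[[1]]$u,
                   fit2$core$components[[1]]$u)
})

test_that("loadings and supports match the mixOmics reference", {
  skip_if_not_installed("mixOmics")
  d <- random_dataset(n = 30, p = 40, K = 3, seed = 7)
  fit <- splsda(d$X, d$y, ncomp = 2, keepX = 8, scale = TRUE)
  ref <- mixOmics::splsda(d$X, factor(d$y, levels = unique(d$y)),
                          ncomp = 2, keepX = c(8, 8), scale = TRUE)
  for (h in 1:2) {
    u <- fit$core$components[[h]]$u
    u_ref <- ref$loadings$X[, h]
    expect_identical(sort(fit$core$feature_ids[u != 0]),
                     sort(names(u_ref)[u_ref != 0]))
    expect_gt(abs(stats::cor(fit$core$scores[, h], ref$variates$X[, h])),
              0.999)
  }
})
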