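#' Sparse PLS discriminant analysis
#'
#' Fits sparse PLS of X against the dummy-coded class membership matrix,
#' penalizing the X-side weight vector only (the dummy response block is
#' left unpenalized), so each dimension selects keepX discriminative
#' features. Class centroids in latent-score space and the pooled
#' within-class score covariance are stored for centroid / Mahalanobis
#' prediction.
#'
#' @param X Samples x features numeric matrix (expression values or 0/1/2
#'   genotypes).
#' @param labels Class label vector aligned with the rows of X (named
#'   vectors are matched to rownames).
#' @param ncomp Number of latent dimensions H; a practical default for a
#'   K-class problem is K - 1 (see \code{\link{choose_ncomp}}).
#' @param keepX Features kept per dimension (scalar broadcast, or a length-H
#'   vector); default ncol(X), i.e. classical PLS-DA with no selection.
#' @param scale Scale X columns to unit variance (default TRUE).
#' @param tol,max_iter Convergence controls for each component fit.
#' @return An object of class \code{"splsda_model"} with the fitted core
#'   \code{spls_model}, \code{classes} (first-appearance order),
#'   \code{labels}, \code{train_scores}, \code{class_centroids} (K x H) and
#'   \code{pooled_score_cov} (H x H).
#' @examples
#' sim <- simulate_expression(synthetic_spec(K = 2, n_per_class = 10,
#'   p = 30, q = 5, delta = 3, seed = 1))
#' fit <- splsda(sim$X, sim$labels, ncomp = 1, keepX = 5)
#' selected_variables(fit, 1)
#' @export
splsda <- function(X, labels, ncomp, keepX = NULL, scale = TRUE,
                   tol = 1e-6, max_iter = 500L) {
  X <- validate_feature_matrix(as.matrix(X))
  labels <- align_labels(labels, X)
  classes <- unique(as.character(labels))
  Y <- encode_dummy(labels, classes)
  core <- fit_spls(X, Y, ncomp = ncomp, keepX = keepX, scale = scale,
                   tol = tol, max_iter = max_iter)
  build_splsda_model(core, classes, labels)
}

align_labels <- function(labels, X) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (length(labels) != nrow(X))
    stop("labels length does not match number of samples", call. = FALSE)
  if (!is.null(names(labels)) && !is.null(rownames(X))) {
    if (!all(rownames(X) %in% names(labels)))
      stop("label names do not cover all sample ids", call. = FALSE)
    labels <- labels[rownames(X)]
  } else {
    names(labels) <- rownames(X)
  }
  labels
}

build_splsda_model <- function(core, classes, labels) {
  scores <- core$scores
  centroids <- matrix(NA_real_, length(classes), core$H,
                      dimnames = list(classes, colnames(scores)))
  for (k in classes)
    centroids[k, ] <- colMeans(scores[labels == k, , drop = FALSE])
  # pooled within-class covariance of the latent scores
  n <- nrow(scores)
  K <- length(classes)
  pooled <- matrix(0, core$H, core$H)
  for (k in classes) {
    Sk <- scores[labels == k, , drop = FALSE]
    if (nrow(Sk) > 1)
      pooled <- pooled + crossprod(sweep(Sk, 2, colMeans(Sk), "-"))
  }
  pooled <- pooled / max(n - K, 1)
  structure(list(core = core, classes = classes, labels = labels,
                 train_scores = scores, class_centroids = centroids,
                 pooled_score_cov = pooled),
            class = "splsda_model")
}

#' Predict class membership for new samples
#'
#' Three decision rules are supported. \code{"max"} (default): predict the
#' dummy response block and call the class with the largest predicted value
#' per row. \code{"centroid"}: project new samples into latent-score space
#' and assign the nearest training class centroid in the Euclidean metric.
#' \code{"mahalanobis"}: the same with the pooled within-class score
#' covariance as metric. Argmax ties are broken by lowest class index.
#'
#' @param model An \code{splsda_model}.
#' @param X_new Matrix of new samples over the model's features.
#' @param ncomp Number of dimensions to use (default: all).
#' @param distance One of \code{"max"}, \code{"centroid"},
#'   \code{"mahalanobis"}.
#' @return List of class \code{"splsda_prediction"} with
#'   \code{predicted_labels}, \code{decision_values} (n_new x K: predicted
#'   dummy scores, or negative distances for the centroid rules),
#'   \code{scores}, \code{distance_used} and \code{ncomp_used}.
#' @export
predict_classes <- function(model, X_new, ncomp = model$core$H,
                            distance = c("max", "centroid", "mahalanobis")) {
  stopifnot(inherits(model, "splsda_model"))
  distance <- match.arg(distance)
  pred <- predict_response(model$core, X_new, ncomp = ncomp)
  K <- length(model$classes)
  if (distance == "max") {
    decision <- pred$Y_hat
  } else {
    cent <- model$class_centroids[, seq_len(ncomp), drop = FALSE]
    S <- pred$scores
    if (distance == "mahalanobis") {
      V <- model$pooled_score_cov[seq_len(ncomp), seq_len(ncomp),
                                  drop = FALSE]
      Vi <- tryCatch(solve(V), error = function(e)
        stop("pooled score covariance is singular; ",
             "use distance = \"centroid\"", call. = FALSE))
    } else {
      Vi <- diag(ncomp)
    }
    decision <- matrix(NA_real_, nrow(S), K,
                       dimnames = list(rownames(S), model$classes))
    for (k in seq_len(K)) {
      delta <- sweep(S, 2, cent[k, ], "-")
      decision[, k] <- -sqrt(rowSums((delta %*% Vi) * delta))
    }
  }
  idx <- apply(decision, 1, which.max)  # which.max: first max, lowest index
  structure(list(predicted_labels = stats::setNames(model$classes[idx],
                                                    rownames(decision)),
                 decision_values = decision,
                 scores = pred$scores,
                 distance_used = distance,
                 ncomp_used = ncomp),
            class = "splsda_prediction")
}

#' @export
predict.splsda_model <- function(object, newdata, ncomp = object$core$H,
                                 distance = "max", ...) {
  predict_classes(object, newdata, ncomp = ncomp, distance = distance)
}

#' Selected features and their loading weights
#'
#' @param model An \code{splsda_model} or \code{spls_model}.
#' @param dim A dimension index, or \code{"all"} for the union across
#'   dimensions.
#' @return For a single dimension: a data.frame (feature_id, weight,
#'   abs_weight) of nonzero-weight features sorted by |weight| descending.
#'   For \code{"all"}: a data.frame over the union of supports with one
#'   weight column per dimension.
#' @export
selected_variables <- function(model, dim = "all") {
  core <- if (inherits(model, "splsda_model")) model$core else model
  stopifnot(inherits(core, "spls_model"))
  U <- vapply(core$components, `[[`,
              numeric(length(core$feature_ids)), "u")
  rownames(U) <- core$feature_ids
  if (identical(dim, "all")) {
    keep <- rowSums(U != 0) > 0
    out <- data.frame(feature_id = core$feature_ids[keep],
                      U[keep, , drop = FALSE],
                      check.names = FALSE, row.names = NULL)
    colnames(out)[-1] <- paste0("weight_comp", seq_len(core$H))
    ord <- order(apply(abs(U[keep, , drop = FALSE]), 1, max),
                 decreasing = TRUE)
    out[ord, , drop = FALSE]
  } else {
    if (dim < 1 || dim > core$H)
      stop("dim out of range for this model", call. = FALSE)
    u <- U[, dim]
    keep <- u != 0
    out <- data.frame(feature_id = core$feature_ids[keep],
                      weight = u[keep], abs_weight = abs(u[keep]),
                      row.names = NULL)
    out[order(out$abs_weight, decreasing = TRUE), , drop = FALSE]
  }
}

#' @export
print.splsda_model <- function(x, ...) {
  cat(sprintf("sPLS-DA model: %d classes (%s), %d dimension(s)\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              x$core$H))
  cat(sprintf("  n = %d samples, p = %d features\n",
              nrow(x$train_scores), length(x$core$feature_ids)))
  cat(sprintf("  keepX = %s; scaled = %s\n",
              paste(x$core$keepX, collapse = ", "),
              x$core$standardizer_X$scale_enabled))
  sel <- selected_variables(x, "all")
  cat(sprintf("  %d feature(s) selected across dimensions\n", nrow(sel)))
  invisible(x)
}

#' @export
print.splsda_prediction <- function(x, ...) {
  cat(sprintf("sPLS-DA prediction (%s distance, %d dimension(s)):\n",
              x$distance_used, x$ncomp_used))
  print(table(x$predicted_labels))
  invisible(x)
}
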