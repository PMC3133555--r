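#' Misclassification rate
#' @param predicted,truth Label vectors of equal length.
#' @return Fraction of mismatches in [0, 1].
#' @export
error_rate <- function(predicted, truth) {
  if (length(predicted) == 0 || length(truth) == 0)
    stop("empty label vectors", call. = FALSE)
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ", call. = FALSE)
  mean(as.character(predicted) != as.character(truth))
}

#' Stratified k-fold partition
#'
#' Spreads every class's samples across the k folds as evenly as possible
#' (per-class fold counts differ by at most 1). Deterministic given
#' \code{seed}.
#'
#' @param labels Class label vector (length n).
#' @param k Number of folds (>= 2).
#' @param seed RNG seed for the within-class shuffles.
#' @return Integer vector of fold assignments in 1..k, aligned with
#'   \code{labels}.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold per class so small classes don't pile into
      # fold 1
      start <- sample.int(k, 1)
      folds[idx] <- ((start - 1 + seq_along(idx) - 1) %% k) + 1
    }
  })
  folds
}

#' Repeated stratified cross-validation of sPLS-DA
#'
#' For every keepX setting in \code{keepX_grid} and every dimension
#' h = 1..ncomp, estimates the held-out misclassification rate by k-fold
#' cross-validation repeated \code{repeats} times (the conventional design
#' is 10-fold averaged 10 times). Standardization and the full model are
#' refit inside every training split, so no information leaks from held-out
#' samples. Per-sample errors are aggregated within each fold, then
#' averaged over the k x repeats folds; the sd is taken across those fold
#' errors. A repeat whose folds miss a class entirely is redrawn with a
#' derived sub-seed.
#'
#' @param X Samples x features matrix.
#' @param labels Class labels aligned with X.
#' @param ncomp Maximum number of dimensions to evaluate.
#' @param keepX_grid Vector (or list of per-dimension vectors) of selection
#'   sizes; each scalar entry is broadcast over dimensions.
#' @param k Folds (default 10). @param repeats Repeats (default 10).
#' @param distance Decision rule passed to \code{\link{predict_classes}}.
#' @param scale Scale X within each training fold (default TRUE).
#' @param seed Seed controlling all fold draws.
#' @return An object of class \code{"cv_result"}: a data.frame \code{table}
#'   with columns keepX, dimension, mean_error, sd_error, plus fields
#'   \code{n_folds}, \code{n_repeats}, \code{seed}.
#' @export
cv_error <- function(X, labels, ncomp, keepX_grid = ncol(X), k = 10,
                     repeats = 10, distance = "max", scale = TRUE,
                     seed = 1) {
  X <- validate_feature_matrix(as.matrix(X))
  labels <- align_labels(labels, X)
  if (!is.list(keepX_grid)) keepX_grid <- as.list(keepX_grid)
  classes <- unique(labels)

  # fold errors: [setting, dimension, fold-instance]
  res <- vector("list", length(keepX_grid))
  for (g in seq_along(keepX_grid)) {
    res[[g]] <- matrix(NA_real_, ncomp, k * repeats)
  }
  for (r in seq_len(repeats)) {
    folds <- draw_valid_folds(labels, k, seed = seed * 1000L + r,
                              classes = classes)
    for (fold in seq_len(k)) {
      test_idx <- which(folds == fold)
      train_idx <- which(folds != fold)
      Xtr <- X[train_idx, , drop = FALSE]
      ytr <- labels[train_idx]
      Xte <- X[test_idx, , drop = FALSE]
      yte <- labels[test_idx]
      for (g in seq_along(keepX_grid)) {
        fit <- splsda(Xtr, ytr, ncomp = ncomp, keepX = keepX_grid[[g]],
                      scale = scale)
        for (h in seq_len(fit$core$H)) {
          pred <- predict_classes(fit, Xte, ncomp = h, distance = distance)
          res[[g]][h, (r - 1) * k + fold] <-
            error_rate(pred$predicted_labels, yte)
        }
      }
    }
  }
  rows <- do.call(rbind, lapply(seq_along(keepX_grid), function(g) {
    kx <- keepX_grid[[g]]
    data.frame(keepX = if (length(kx) == 1) kx else paste(kx, collapse = ","),
               dimension = seq_len(ncomp),
               mean_error = rowMeans(res[[g]], na.rm = TRUE),
               sd_error = apply(res[[g]], 1, stats::sd, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(table = rows, n_folds = k, n_repeats = repeats,
                 seed = seed, ncomp = ncomp, classes = classes),
            class = "cv_result")
}

# draw a stratified partition in which every training split keeps all
# classes; redraw with a sub-seed when a class is so small it vanishes
draw_valid_folds <- function(labels, k, seed, classes,
                             max_redraws = 50L) {
  for (attempt in seq_len(max_redraws)) {
    folds <- stratified_folds(labels, k, seed = seed + (attempt - 1L))
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[folds != f])) == length(classes), logical(1)))
    if (ok) {
      if (attempt > 1)
        message(sprintf("fold draw redrawn %d time(s) to keep all classes",
                        attempt - 1L))
      return(folds)
    }
  }
  stop("could not draw folds keeping every class in every training split",
       call. = FALSE)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d-fold x %d repeat(s), seed %d\n",
              x$n_folds, x$n_repeats, x$seed))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Choose the number of sPLS-DA dimensions
#'
#' Without a cross-validation result, returns the K - 1 default: for a
#' K-class problem the cross-validated error typically stabilizes after the
#' first K - 1 dimensions. With a \code{cv_result}, applies a one-sd elbow
#' rule: the smallest dimension whose mean error is within one sd of the
#' minimum over dimensions, capped at K - 1 unless the curve strictly
#' improves beyond it (which covers data where fewer dimensions suffice,
#' e.g. near-duplicate classes).
#'
#' @param labels Class labels (used for K).
#' @param cv Optional \code{cv_result}; when it spans several keepX
#'   settings the error curve is averaged over settings per dimension.
#' @return Integer number of dimensions.
#' @export
choose_ncomp <- function(labels, cv = NULL) {
  K <- length(unique(as.character(labels)))
  default <- max(K - 1L, 1L)
  if (is.null(cv)) return(default)
  stopifnot(inherits(cv, "cv_result"))
  agg <- stats::aggregate(cbind(mean_error, sd_error) ~ dimension,
                          data = cv$table, FUN = mean)
  agg <- agg[order(agg$dimension), ]
  best <- which.min(agg$mean_error)
  cutoff <- agg$mean_error[best] + agg$sd_error[best]
  elbow <- min(which(agg$mean_error <= cutoff))
  h <- min(elbow, default)
  # data-driven override: go beyond K-1 only on strict improvement
  if (best > default &&
      agg$mean_error[best] < agg$mean_error[default] - agg$sd_error[best])
    h <- best
  as.integer(h)
}
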