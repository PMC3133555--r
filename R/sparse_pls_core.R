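#' Soft-thresholding operator
#'
#' The proximal map of the L1 penalty, applied componentwise:
#' \code{sign(x) * pmax(abs(x) - lam, 0)}. Entries smaller than \code{lam}
#' in magnitude are zeroed, the rest shrink toward zero.
#'
#' @param x Numeric vector.
#' @param lam Nonnegative threshold.
#' @return Thresholded vector of the same length.
#' @examples
#' soft_threshold(c(0.5, -0.3, 0.1), 0.2)
#' @export
soft_threshold <- function(x, lam) {
  if (length(lam) != 1 || is.na(lam) || lam < 0)
    stop("lam must be a single nonnegative number", call. = FALSE)
  sign(x) * pmax(abs(x) - lam, 0)
}

#' Sparsify a weight vector to a target number of nonzeros
#'
#' Maps the user-facing sparsity parameter keepX to a soft threshold: lambda
#' is set to the (keepX + 1)-th largest absolute entry (zero when
#' keepX = length(x)), so that on tie-free input exactly keepX entries
#' survive, shrunk by lambda. If mass ties at the boundary zero the whole
#' vector, the keepX largest-magnitude entries are kept unshrunk instead
#' (ties broken by lowest index) with a warning.
#'
#' @param x Numeric vector.
#' @param keepX Integer in [1, length(x)].
#' @return Vector with at most keepX nonzeros (exactly keepX generically).
#' @examples
#' sparsify_to_keepx(c(0.5, -0.3, 0.1), 2)  # lambda = 0.1 -> (0.4, -0.2, 0)
#' @export
sparsify_to_keepx <- function(x, keepX) {
  p <- length(x)
  if (length(keepX) != 1 || keepX < 1 || keepX > p)
    stop(sprintf("keepX must lie in [1, %d]", p), call. = FALSE)
  keepX <- as.integer(keepX)
  if (keepX == p) return(x)
  a <- abs(x)
  lam <- sort(a, decreasing = TRUE)[keepX + 1]
  out <- soft_threshold(x, lam)
  if (all(out == 0)) {
    warning("soft-thresholding zeroed all entries (ties at the boundary); ",
            "falling back to hard selection of the keepX largest entries",
            call. = FALSE)
    keep_idx <- order(a, decreasing = TRUE)[seq_len(keepX)]
    out <- numeric(p)
    out[keep_idx] <- x[keep_idx]
  }
  out
}

#' Fit one sparse PLS component on (deflated) data blocks
#'
#' Solves the penalized rank-one approximation of the cross-product matrix
#' M = t(X_h) %*% Y_h by alternating updates: starting from the dominant
#' right singular vector v of M, repeat u <- sparsify_to_keepx(M v) scaled
#' to unit norm, then v <- t(M) u scaled to unit norm, until the maximum
#' absolute change in u falls below \code{tol}. Only the X-side weight u is
#' penalized. The latent score, X-loading and Y-loading needed for deflation
#' and prediction are computed at the fixed point.
#'
#' @param Xh,Yh Column-centered matrices for the current deflation step.
#' @param keepX Number of X features to keep on this dimension.
#' @param tol Convergence tolerance on max |delta u| (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return A list of class \code{"pls_component"} with elements \code{u}
#'   (sparse unit X-weight), \code{v} (unit Y-weight), \code{xi} (latent
#'   score X_h u), \code{c} (X-loading: regression of X_h on xi), \code{d}
#'   (Y-loading), \code{n_iter}, \code{converged}. Sign convention: the
#'   largest-magnitude entry of u is positive.
#' @export
fit_component <- function(Xh, Yh, keepX, tol = 1e-6, max_iter = 500L) {
  M <- crossprod(Xh, Yh)
  if (all(abs(M) < .Machine$double.eps * 100))
    stop("cross-product matrix is zero: no covariance left to model",
         call. = FALSE)
  sv <- svd(M, nu = 0, nv = 1)
  v <- sv$v[, 1]
  u <- numeric(nrow(M))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    u_new <- sparsify_to_keepx(drop(M %*% v), keepX)
    u_new <- u_new / sqrt(sum(u_new^2))
    v <- drop(crossprod(M, u_new))
    v <- v / sqrt(sum(v^2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning(sprintf("component did not converge in %d iterations", max_iter),
            call. = FALSE)
  # deterministic sign: largest-|u| entry positive
  s <- sign(u[which.max(abs(u))])
  if (s < 0) { u <- -u; v <- -v }
  xi <- drop(Xh %*% u)
  ss <- sum(xi^2)
  comp <- list(u = u, v = v, xi = xi,
               c = drop(crossprod(Xh, xi)) / ss,
               d = drop(crossprod(Yh, xi)) / ss,
               n_iter = iter, converged = converged)
  class(comp) <- "pls_component"
  comp
}

#' Regression-mode deflation of both blocks
#'
#' Subtracts from X_h and Y_h the part explained by the current latent
#' score: X_{h+1} = X_h - xi c', Y_{h+1} = Y_h - xi d'. Deflating both
#' blocks on the same score guarantees mutually orthogonal scores across
#' dimensions and supports the regression prediction formula.
#'
#' @param Xh,Yh Current data blocks.
#' @param comp A \code{pls_component} fitted on (Xh, Yh).
#' @return List with deflated \code{X} and \code{Y}.
#' @export
deflate <- function(Xh, Yh, comp) {
  stopifnot(inherits(comp, "pls_component"))
  if (nrow(Xh) != length(comp$xi) || ncol(Xh) != length(comp$c) ||
      ncol(Yh) != length(comp$d))
    stop("dimension mismatch between blocks and component", call. = FALSE)
  list(X = Xh - tcrossprod(comp$xi, comp$c),
       Y = Yh - tcrossprod(comp$xi, comp$d))
}

#' Fit a multi-dimension sparse PLS model (regression mode)
#'
#' Iterates \code{\link{fit_component}} and \code{\link{deflate}} H times.
#' X is standardized (centered, optionally scaled) and Y is column-centered
#' internally; the standardization parameters and Y means are stored on the
#' model so prediction applies the training transformation.
#'
#' @param X Samples x features predictor matrix.
#' @param Y Samples x responses matrix (e.g. a dummy class matrix).
#' @param ncomp Number of dimensions H.
#' @param keepX Integer vector of per-dimension selection sizes; a scalar is
#'   broadcast to all dimensions. Defaults to ncol(X) (no selection).
#' @param scale Scale X columns to unit variance (default TRUE).
#' @param tol,max_iter Convergence controls passed to fit_component.
#' @return Object of class \code{"spls_model"}: \code{components} (list of
#'   pls_component), \code{keepX}, \code{standardizer_X}, \code{y_means},
#'   \code{H}, \code{feature_ids}, \code{response_ids}, \code{scores}
#'   (n x H matrix of latent variables).
#' @export
fit_spls <- function(X, Y, ncomp, keepX = NULL, scale = TRUE,
                     tol = 1e-6, max_iter = 500L) {
  X <- validate_feature_matrix(as.matrix(X))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("X and Y row counts differ", call. = FALSE)
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  p <- ncol(X)
  if (is.null(keepX)) keepX <- p
  if (length(keepX) == 1) keepX <- rep(keepX, ncomp)
  if (length(keepX) != ncomp)
    stop("keepX must have length 1 or ncomp", call. = FALSE)
  std <- fit_standardizer(X, scale = scale)
  Xh <- apply_standardizer(std, X)
  y_means <- colMeans(Y)
  Yh <- sweep(Y, 2, y_means, "-")

  comps <- vector("list", ncomp)
  for (h in seq_len(ncomp)) {
    M_norm <- max(abs(crossprod(Xh, Yh)))
    if (M_norm < 1e-12) {
      warning(sprintf(
        "no covariance left after %d dimension(s); stopping early", h - 1L),
        call. = FALSE)
      comps <- comps[seq_len(h - 1L)]
      ncomp <- h - 1L
      keepX <- keepX[seq_len(ncomp)]
      break
    }
    comp <- fit_component(Xh, Yh, keepX[h], tol = tol, max_iter = max_iter)
    comps[[h]] <- comp
    defl <- deflate(Xh, Yh, comp)
    Xh <- defl$X
    Yh <- defl$Y
  }
  if (ncomp == 0) stop("no component could be fitted", call. = FALSE)
  scores <- vapply(comps, `[[`, numeric(nrow(X)), "xi")
  dimnames(scores) <- list(rownames(X), paste0("comp", seq_len(ncomp)))
  # column sums of squares of the standardized X: lets feature-score
  # correlations be recovered from the model alone (X_std' xi_h = c_h
  # ||xi_h||^2 under orthogonal-score deflation)
  Xs <- apply_standardizer(std, X)
  x_ss <- stats::setNames(colSums(Xs^2), colnames(X))
  structure(list(components = comps, keepX = as.integer(keepX),
                 standardizer_X = std, y_means = y_means, H = ncomp,
                 feature_ids = colnames(X),
                 response_ids = colnames(Y),
                 scores = scores, x_ss = x_ss),
            class = "spls_model")
}

#' Predict responses from a sparse PLS model
#'
#' Normative path (\code{method = "sequential"}): standardize X_new with the
#' training standardizer, then for h = 1..ncomp project onto u_h and deflate
#' with the training X-loading c_h; the prediction accumulates
#' y_means + sum_h xi_h d_h'. The closed form applies
#' beta = U (C'U)^{-1} D' to the standardized X_new; the two agree to
#' numerical precision and the equivalence is exercised in the test suite.
#'
#' @param model An \code{spls_model}.
#' @param X_new Matrix with the model's p features (columns matched by name
#'   when named).
#' @param ncomp Number of dimensions to use (default: all H).
#' @param method \code{"sequential"} (default) or \code{"closed_form"}.
#' @return List with \code{Y_hat} (n_new x q predicted responses) and
#'   \code{scores} (n_new x ncomp projected latent variables).
#' @export
predict_response <- function(model, X_new, ncomp = model$H,
                             method = c("sequential", "closed_form")) {
  stopifnot(inherits(model, "spls_model"))
  method <- match.arg(method)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$feature_ids))
    stop("X_new feature count does not match model", call. = FALSE)
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(X_new)))
      stop("X_new lacks model features", call. = FALSE)
    X_new <- X_new[, model$feature_ids, drop = FALSE]
  }
  if (ncomp < 1 || ncomp > model$H)
    stop("ncomp out of range for this model", call. = FALSE)
  Xc <- apply_standardizer(model$standardizer_X, X_new)
  q <- length(model$y_means)
  n_new <- nrow(Xc)
  scores <- matrix(0, n_new, ncomp,
                   dimnames = list(rownames(X_new),
                                   paste0("comp", seq_len(ncomp))))
  if (method == "sequential") {
    Yhat <- matrix(rep(model$y_means, each = n_new), n_new, q)
    for (h in seq_len(ncomp)) {
      comp <- model$components[[h]]
      xi <- drop(Xc %*% comp$u)
      scores[, h] <- xi
      Yhat <- Yhat + tcrossprod(xi, comp$d)
      Xc <- Xc - tcrossprod(xi, comp$c)
    }
  } else {
    U <- vapply(model$components[seq_len(ncomp)], `[[`,
                numeric(length(model$feature_ids)), "u")
    C <- vapply(model$components[seq_len(ncomp)], `[[`,
                numeric(length(model$feature_ids)), "c")
    D <- vapply(model$components[seq_len(ncomp)], `[[`, numeric(q), "d")
    CtU <- crossprod(C, U)
    Wstar <- tryCatch(U %*% solve(CtU), error = function(e) {
      warning("closed-form coefficients unavailable (singular C'U); ",
              "use the sequential path", call. = FALSE)
      NULL
    })
    if (is.null(Wstar)) {
      return(predict_response(model, X_new, ncomp, method = "sequential"))
    }
    beta <- Wstar %*% t(D)
    Yhat <- sweep(Xc %*% beta, 2, model$y_means, "+")
    scores <- Xc %*% Wstar
    dimnames(scores) <- list(rownames(X_new), paste0("comp", seq_len(ncomp)))
  }
  colnames(Yhat) <- model$response_ids
  rownames(Yhat) <- rownames(X_new)
  list(Y_hat = Yhat, scores = scores)
}

#' Serialize a sparse PLS(-DA) model to JSON
#'
#' Writes every component's u, v, c, d, the keepX vector, standardization
#' parameters and class/response names as structured text; floats survive a
#' round trip exactly (digits = NA, i.e. full precision).
#'
#' @param model An \code{spls_model} or \code{splsda_model}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  is_da <- inherits(model, "splsda_model")
  core <- if (is_da) model$core else model
  ser <- list(
    type = if (is_da) "splsda" else "spls",
    H = core$H,
    keepX = core$keepX,
    feature_ids = core$feature_ids,
    response_ids = core$response_ids,
    y_means = unname(core$y_means),
    standardizer = list(means = unname(core$standardizer_X$means),
                        scales = unname(core$standardizer_X$scales),
                        scale_enabled = core$standardizer_X$scale_enabled),
    components = lapply(core$components, function(cp)
      list(u = unname(cp$u), v = unname(cp$v), xi = unname(cp$xi),
           c = unname(cp$c), d = unname(cp$d),
           n_iter = cp$n_iter, converged = cp$converged)),
    sample_ids = rownames(core$scores),
    x_ss = unname(core$x_ss)
  )
  if (is_da) {
    ser$classes <- model$classes
    ser$labels <- unname(model$labels)
  }
  # digits = I(17): 17 significant digits, enough for an exact double
  # round trip
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a model written by \code{\link{write_model}}
#' @param path Path to the JSON model file.
#' @return The reconstructed \code{spls_model} or \code{splsda_model}.
#' @export
read_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(ser$feature_ids)
  comps <- lapply(seq_len(ser$H), function(h) {
    cp <- if (is.data.frame(ser$components)) {
      as.list(ser$components[h, ])
    } else ser$components[[h]]
    structure(list(
      u = stats::setNames(unlist(cp$u), ser$feature_ids),
      v = stats::setNames(unlist(cp$v), ser$response_ids),
      xi = stats::setNames(unlist(cp$xi), ser$sample_ids),
      c = stats::setNames(unlist(cp$c), ser$feature_ids),
      d = stats::setNames(unlist(cp$d), ser$response_ids),
      n_iter = cp$n_iter, converged = cp$converged),
      class = "pls_component")
  })
  std <- structure(list(
    means = stats::setNames(ser$standardizer$means, ser$feature_ids),
    scales = stats::setNames(ser$standardizer$scales, ser$feature_ids),
    scale_enabled = ser$standardizer$scale_enabled),
    class = "column_standardizer")
  scores <- vapply(comps, `[[`, numeric(length(comps[[1]]$xi)), "xi")
  dimnames(scores) <- list(ser$sample_ids, paste0("comp", seq_len(ser$H)))
  core <- structure(list(
    components = comps, keepX = as.integer(ser$keepX),
    standardizer_X = std,
    y_means = stats::setNames(ser$y_means, ser$response_ids),
    H = ser$H, feature_ids = ser$feature_ids,
    response_ids = ser$response_ids, scores = scores,
    x_ss = stats::setNames(ser$x_ss, ser$feature_ids)),
    class = "spls_model")
  if (identical(ser$type, "splsda")) {
    labels <- stats::setNames(ser$labels, ser$sample_ids)
    build_splsda_model(core, ser$classes, labels)
  } else {
    core
  }
}
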