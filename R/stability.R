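#' Bolasso-style selection-frequency analysis for one dimension
#'
#' Perturbs the training set B times — bootstrap samples of size n, or
#' half-samples of size floor(n/2) drawn without replacement — refits the
#' sPLS-DA model on each resample with the keepX sizes of the earlier
#' dimensions held fixed at \code{prior_keepX}, and records which features
#' carry nonzero weight on dimension \code{dimension}. The relative
#' selection frequency of feature j is the fraction of resamples selecting
#' it. The analysis is meant to be run sequentially: settle keepX for
#' dimension 1 from its frequency profile, then condition on it while
#' analysing dimension 2, and so on.
#'
#' @param X Samples x features matrix.
#' @param labels Class labels aligned with X.
#' @param dimension Dimension h under analysis (>= 1).
#' @param keepX_h Selection size tried on dimension h.
#' @param prior_keepX Integer vector of keepX for dimensions 1..h-1
#'   (empty for h = 1).
#' @param B Number of resamples (>= 2; default 100).
#' @param mode \code{"bootstrap"} (size-n, with replacement; default) or
#'   \code{"half"} (size floor(n/2), without replacement).
#' @param scale Scale X within each refit (default TRUE).
#' @param seed Seed controlling all resample draws.
#' @return Object of class \code{"stability_result"}: \code{frequencies}
#'   (named p-vector in [0, 1]), \code{dimension}, \code{n_resamples},
#'   \code{mode}, \code{keepX_used}, \code{prior_keepX}, \code{seed}.
#' @export
stability_frequencies <- function(X, labels, dimension = 1, keepX_h,
                                  prior_keepX = integer(0), B = 100,
                                  mode = c("bootstrap", "half"),
                                  scale = TRUE, seed = 1) {
  mode <- match.arg(mode)
  X <- validate_feature_matrix(as.matrix(X))
  labels <- align_labels(labels, X)
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (length(prior_keepX) != dimension - 1)
    stop("prior_keepX must have length dimension - 1", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  classes <- unique(labels)
  keepX <- c(as.integer(prior_keepX), as.integer(keepX_h))
  counts <- stats::setNames(numeric(p), colnames(X))
  for (b in seq_len(B)) {
    idx <- draw_valid_resample(labels, classes, mode,
                               seed = seed * 10000L + b)
    Xb <- X[idx, , drop = FALSE]
    rownames(Xb) <- paste0("r", seq_along(idx))  # bootstrap duplicates
    yb <- stats::setNames(labels[idx], rownames(Xb))
    fit <- splsda(Xb, yb, ncomp = dimension, keepX = keepX, scale = scale)
    support <- fit$core$components[[dimension]]$u != 0
    counts <- counts + support
  }
  structure(list(frequencies = counts / B, dimension = as.integer(dimension),
                 n_resamples = as.integer(B), mode = mode,
                 keepX_used = as.integer(keepX_h),
                 prior_keepX = as.integer(prior_keepX), seed = seed),
            class = "stability_result")
}

# resample indices keeping every class present and non-constant columns
# unlikely; redraw with a sub-seed when a class is missing
draw_valid_resample <- function(labels, classes, mode, seed,
                                max_redraws = 50L) {
  n <- length(labels)
  size <- if (mode == "bootstrap") n else n %/% 2L
  for (attempt in seq_len(max_redraws)) {
    idx <- with_seed(seed + (attempt - 1L) * 1000000L, {
      sample.int(n, size, replace = (mode == "bootstrap"))
    })
    # every class must appear at least twice for a meaningful refit
    tab <- table(factor(labels[idx], levels = classes))
    if (all(tab >= 2)) {
      if (attempt > 1)
        message(sprintf("resample redrawn %d time(s) to keep all classes",
                        attempt - 1L))
      return(idx)
    }
  }
  stop("could not draw a resample containing every class", call. = FALSE)
}

#' Keep the most stable features from a frequency profile
#'
#' @param result A \code{stability_result}.
#' @param rule \code{"top_m"} or \code{"threshold"}.
#' @param m Number of features to keep under \code{"top_m"} (ties broken by
#'   lowest feature index).
#' @param t Frequency cutoff in [0, 1] under \code{"threshold"}; features
#'   with frequency >= t are kept (t = 1 is the strict
#'   intersection-across-resamples rule).
#' @return Character vector of feature ids.
#' @export
stable_selection <- function(result, rule = c("top_m", "threshold"),
                             m = result$keepX_used, t = 0.5) {
  stopifnot(inherits(result, "stability_result"))
  rule <- match.arg(rule)
  freq <- result$frequencies
  if (rule == "top_m") {
    if (m < 1 || m > length(freq)) stop("m out of range", call. = FALSE)
    # order() is stable: ties resolve to the lowest index
    names(freq)[order(freq, decreasing = TRUE)[seq_len(m)]]
  } else {
    if (t < 0 || t > 1) stop("t must lie in [0, 1]", call. = FALSE)
    names(freq)[freq >= t]
  }
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Stability analysis: dimension %d, keepX = %d, %d %s resamples\n",
    x$dimension, x$keepX_used, x$n_resamples, x$mode))
  top <- sort(x$frequencies, decreasing = TRUE)[seq_len(min(
    10, length(x$frequencies)))]
  cat("Top frequencies:\n")
  print(round(top, 3))
  invisible(x)
}
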