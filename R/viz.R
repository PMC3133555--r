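#' Sample score plot data
#'
#' Coordinates of the training samples (and optionally new samples) on two
#' latent dimensions, the standard projection view for judging how well the
#' classes separate.
#'
#' @param model An \code{splsda_model}.
#' @param dims Pair of dimension indices (default c(1, 2)).
#' @param X_new Optional matrix of new samples to project alongside the
#'   training set (labelled class "unknown").
#' @return A data.frame with columns sample_id, score_d1, score_d2, class;
#'   attribute \code{"dims"} records the dimensions used.
#' @export
sample_plot_data <- function(model, dims = c(1, 2), X_new = NULL) {
  stopifnot(inherits(model, "splsda_model"))
  H <- model$core$H
  if (length(dims) != 2 || any(dims < 1) || any(dims > H))
    stop(sprintf("dims must be two indices in 1..%d", H), call. = FALSE)
  S <- model$train_scores
  out <- data.frame(sample_id = rownames(S),
                    score_d1 = S[, dims[1]],
                    score_d2 = S[, dims[2]],
                    class = unname(model$labels[rownames(S)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(X_new)) {
    pr <- predict_response(model$core, X_new, ncomp = max(dims))
    out <- rbind(out, data.frame(
      sample_id = rownames(pr$scores),
      score_d1 = pr$scores[, dims[1]],
      score_d2 = pr$scores[, dims[2]],
      class = "unknown", row.names = NULL, stringsAsFactors = FALSE))
  }
  attr(out, "dims") <- dims
  attr(out, "kind") <- "samples"
  out
}

#' Correlation circle data
#'
#' For every feature selected on at least one dimension, the Pearson
#' correlations between that feature (standardized training values) and the
#' two latent score vectors. Because scores are orthogonal across
#' dimensions, each point lies within the unit disk; features near the
#' circle load strongly on the displayed dimensions, and angles between
#' points approximate between-feature correlations.
#'
#' @param model An \code{splsda_model}.
#' @param dims Pair of dimension indices (default c(1, 2)).
#' @return A data.frame with columns feature_id, cor_d1, cor_d2;
#'   zero-variance features are excluded with a warning.
#' @export
correlation_circle_data <- function(model, dims = c(1, 2)) {
  stopifnot(inherits(model, "splsda_model"))
  H <- model$core$H
  if (length(dims) != 2 || any(dims < 1) || any(dims > H))
    stop(sprintf("dims must be two indices in 1..%d", H), call. = FALSE)
  sel <- selected_variables(model, "all")$feature_id
  core <- model$core
  # exact feature-score correlations from model quantities alone: both the
  # standardized X columns and the scores are mean-zero, and under
  # orthogonal-score deflation X_std' xi_h = c_h ||xi_h||^2, so
  # cor(X_j, xi_h) = c_{h,j} ||xi_h|| / sqrt(sum(X_j^2))
  ss <- core$x_ss[sel]
  zero <- ss <= .Machine$double.eps * 100
  if (any(zero)) {
    warning(sprintf("excluding %d zero-variance feature(s)", sum(zero)),
            call. = FALSE)
    sel <- sel[!zero]
    ss <- ss[!zero]
  }
  cors <- vapply(dims, function(h) {
    comp <- core$components[[h]]
    comp$c[match(sel, core$feature_ids)] *
      sqrt(sum(comp$xi^2)) / sqrt(ss)
  }, numeric(length(sel)))
  out <- data.frame(feature_id = sel,
                    cor_d1 = cors[, 1], cor_d2 = cors[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dims") <- dims
  attr(out, "kind") <- "correlation_circle"
  out
}

#' Loading-weight plot data
#'
#' Absolute weights of the features selected on one dimension, sorted
#' descending — the bar-plot view of which features drive a dimension.
#'
#' @param model An \code{splsda_model}.
#' @param dim Dimension index.
#' @return A data.frame with columns feature_id, abs_weight, sign.
#' @export
loading_plot_data <- function(model, dim = 1) {
  sel <- selected_variables(model, dim)
  out <- data.frame(feature_id = sel$feature_id,
                    abs_weight = sel$abs_weight,
                    sign = ifelse(sel$weight >= 0, "+", "-"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dims") <- c(dim, dim)
  attr(out, "kind") <- "loadings"
  out
}

#' Write a plot table as TSV
#' @param table A data.frame from one of the \code{*_plot_data} functions.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_plot_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Render a plot table to PNG
#'
#' Draws the figure corresponding to a plot table (sample scores,
#' correlation circle, or loading weights) using base graphics. The figure
#' is always generated from the emitted table, never from model internals,
#' so a table written to disk and re-read renders identically.
#'
#' @param table A plot-table data.frame (attribute \code{"kind"} set by the
#'   \code{*_plot_data} functions, or inferred from columns).
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return \code{path}, invisibly.
#' @export
render_plot <- function(table, path, width = 800, height = 800) {
  kind <- attr(table, "kind")
  if (is.null(kind)) {
    kind <- if ("cor_d1" %in% colnames(table)) "correlation_circle"
    else if ("abs_weight" %in% colnames(table)) "loadings"
    else "samples"
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  if (kind == "samples") {
    cls <- factor(table$class)
    plot(table$score_d1, table$score_d2, col = as.integer(cls),
         pch = as.integer(cls), xlab = "latent variable 1",
         ylab = "latent variable 2", main = "Sample scores")
    graphics::legend("topright", legend = levels(cls),
                     col = seq_along(levels(cls)),
                     pch = seq_along(levels(cls)))
  } else if (kind == "correlation_circle") {
    theta <- seq(0, 2 * pi, length.out = 200)
    plot(cos(theta), sin(theta), type = "l", asp = 1, col = "grey",
         xlab = "correlation with dim 1", ylab = "correlation with dim 2",
         main = "Correlation circle")
    graphics::abline(h = 0, v = 0, col = "grey", lty = 2)
    graphics::points(table$cor_d1, table$cor_d2, pch = 20)
    graphics::text(table$cor_d1, table$cor_d2, table$feature_id,
                   pos = 3, cex = 0.7)
  } else {
    ord <- order(table$abs_weight)
    graphics::barplot(table$abs_weight[ord],
                      names.arg = table$feature_id[ord],
                      horiz = TRUE, las = 1, cex.names = 0.6,
                      xlab = "|loading weight|",
                      main = "Loading weights")
  }
  invisible(path)
}
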