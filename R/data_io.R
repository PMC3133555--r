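#' Read a samples x features matrix from delimited text
#'
#' Reads a TSV/CSV matrix with one header row of identifiers and one leading
#' identifier column. The file may store samples in rows (default) or in
#' columns; the returned matrix is always oriented samples x features.
#'
#' @param path Path to a delimited text file.
#' @param orientation Either \code{"samples_in_rows"} (default) or
#'   \code{"features_in_rows"}; the file is transposed as needed so that the
#'   result has one row per sample.
#' @param sep Field separator; \code{"\t"} by default, use \code{","} for CSV.
#' @return A numeric matrix with \code{rownames} = sample identifiers and
#'   \code{colnames} = feature identifiers.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_feature_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))), tf)
#' X <- read_feature_matrix(tf)
#' @export
read_feature_matrix <- function(path,
                                orientation = c("samples_in_rows",
                                                "features_in_rows"),
                                sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, colClasses = NA,
                          stringsAsFactors = FALSE, comment.char = "")
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad) > 0) {
    for (j in bad) {
      nonnum <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))
      stop(sprintf(
        "non-numeric value in column '%s', row '%s'",
        colnames(df)[j],
        rownames(df)[if (length(nonnum)) nonnum[1] else 1]), call. = FALSE)
    }
  }
  X <- as.matrix(df)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row '%s', column '%s'",
                 rownames(X)[idx[1]], colnames(X)[idx[2]]), call. = FALSE)
  }
  if (orientation == "features_in_rows") X <- t(X)
  # minimum sizes for modeling (n >= 3, p >= 2) are enforced at fit time
  validate_feature_matrix(X, min_n = 1, min_p = 1)
  X
}

#' Write a feature matrix as delimited text
#'
#' @param X Numeric matrix with sample rownames and feature colnames.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(X, path, sep = "\t") {
  validate_feature_matrix(X, min_n = 1, min_p = 1)
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_feature_matrix <- function(X, min_n = 3, min_p = 2) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("X must be a numeric matrix", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values", call. = FALSE)
  if (nrow(X) < min_n)
    stop(sprintf("need at least %d samples, got %d", min_n, nrow(X)),
         call. = FALSE)
  if (ncol(X) < min_p)
    stop(sprintf("need at least %d features, got %d", min_p, ncol(X)),
         call. = FALSE)
  if (is.null(rownames(X))) rownames(X) <- paste0("sample", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("feature", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature identifiers", call. = FALSE)
  invisible(X)
}

#' Read per-sample class labels
#'
#' Reads a label file with columns \code{sample_id} and \code{label}
#' (header required), or a single unnamed column aligned with a matrix.
#'
#' @param path Path to the label file.
#' @param sep Field separator.
#' @return A character vector of labels, named by sample identifier when the
#'   file provides one.
#' @export
read_labels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) >= 2) {
    labels <- as.character(df[[2]])
    names(labels) <- as.character(df[[1]])
  } else {
    labels <- as.character(df[[1]])
  }
  labels
}

#' Dummy (indicator) coding of class labels
#'
#' Recodes a K-class label vector as an n x K block of 0/1 indicators: row i
#' carries a single 1 in the column of its class. This is the response block
#' that turns PLS regression into a discriminant analysis.
#'
#' @param labels Character or factor vector of class labels (length n).
#' @param classes Optional ordered vector of class names; defaults to
#'   first-appearance order of \code{labels}.
#' @return An n x K numeric 0/1 matrix with \code{colnames} = classes and row
#'   names taken from \code{labels} names if present.
#' @examples
#' encode_dummy(c("A", "B", "A"))
#' @export
encode_dummy <- function(labels, classes = NULL) {
  labels <- as.character(labels)
  if (is.null(classes)) classes <- unique(labels)
  classes <- as.character(classes)
  if (length(classes) < 2)
    stop("need at least 2 classes to discriminate", call. = FALSE)
  if (!all(labels %in% classes))
    stop("labels contain values not listed in classes", call. = FALSE)
  if (!all(classes %in% labels))
    stop(sprintf("class '%s' has no samples",
                 setdiff(classes, labels)[1]), call. = FALSE)
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(names(labels), classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Recover labels from a dummy matrix (row-wise argmax)
#' @param Y An n x K dummy (or predicted-score) matrix with class colnames.
#' @return Character vector of class names, ties broken by lowest column index.
#' @export
decode_dummy <- function(Y) {
  colnames(Y)[apply(Y, 1, which.max)]
}

#' Fit a column standardizer on training data
#'
#' Captures per-column means (and, when \code{scale = TRUE}, standard
#' deviations with denominator n - 1) so that the identical transformation
#' can be applied to held-out samples. Centering is always performed; unit
#' variance scaling is on by default, matching common PLS practice for data
#' whose features are on heterogeneous scales.
#'
#' @param X Training matrix (samples x features).
#' @param scale Logical; divide by the column standard deviation.
#' @return An object of class \code{"column_standardizer"} with fields
#'   \code{means}, \code{scales}, \code{scale_enabled}.
#' @export
fit_standardizer <- function(X, scale = TRUE) {
  means <- colMeans(X)
  if (scale) {
    scales <- apply(X, 2, stats::sd)
    zero <- which(scales <= .Machine$double.eps * 100)
    if (length(zero) > 0)
      stop(sprintf("constant column(s) with scaling enabled: %s",
                   paste(colnames(X)[zero], collapse = ", ")), call. = FALSE)
  } else {
    scales <- rep(1, ncol(X))
  }
  names(scales) <- colnames(X)
  structure(list(means = means, scales = scales, scale_enabled = scale),
            class = "column_standardizer")
}

#' Apply (or invert) a fitted standardizer
#' @param s A \code{column_standardizer}.
#' @param X Matrix with the same p columns the standardizer was fit on.
#' @param invert Logical; undo the transformation instead of applying it.
#' @return Transformed matrix with dimnames preserved.
#' @export
apply_standardizer <- function(s, X, invert = FALSE) {
  stopifnot(inherits(s, "column_standardizer"))
  if (ncol(X) != length(s$means))
    stop("column count does not match standardizer", call. = FALSE)
  if (invert) {
    sweep(sweep(X, 2, s$scales, "*"), 2, s$means, "+")
  } else {
    sweep(sweep(X, 2, s$means, "-"), 2, s$scales, "/")
  }
}

#' Minor allele frequency filter for 0/1/2 genotype matrices
#'
#' For a biallelic SNP coded as the count of mutant alleles (0, 1 or 2 per
#' individual), the allele frequency is f = sum(genotypes) / (2n) and the
#' minor allele frequency is MAF = min(f, 1 - f). Features are retained iff
#' MAF strictly exceeds \code{threshold}.
#'
#' @param X Genotype matrix (samples x SNPs) with all entries in {0, 1, 2}.
#' @param threshold MAF cutoff in [0, 0.5); default 0.05.
#' @return A list with \code{X} (the filtered matrix), \code{kept}
#'   (character vector of retained SNP ids) and \code{maf} (named MAF vector
#'   over all input SNPs).
#' @examples
#' G <- matrix(c(0, 0, 1, 0, 0, 0), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("snp1", "snp2")))
#' maf_filter(G)$kept  # snp1 kept (MAF 1/6), snp2 dropped (MAF 0)
#' @export
maf_filter <- function(X, threshold = 0.05) {
  validate_feature_matrix(X, min_n = 1, min_p = 1)
  if (!all(X %in% c(0, 1, 2)))
    stop("genotype entries must all be 0, 1 or 2", call. = FALSE)
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)", call. = FALSE)
  f <- colSums(X) / (2 * nrow(X))
  maf <- pmin(f, 1 - f)
  keep <- maf > threshold
  list(X = X[, keep, drop = FALSE],
       kept = colnames(X)[keep],
       maf = stats::setNames(maf, colnames(X)))
}
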