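#' Specification for a synthetic multiclass dataset
#'
#' Describes a K-class dataset with q informative features among p. In
#' expression mode the informative block is equicorrelated Gaussian with
#' class-dependent means; the informative features are partitioned into K
#' groups and class k's mean is \code{delta} (in noise-sd units) on its own
#' group and 0 elsewhere, so the class mean patterns are orthogonal and
#' discriminating all K classes genuinely requires about K - 1 latent
#' dimensions. In snp mode genotypes are Binomial(2, f) counts of the
#' mutant allele with f = base_maf everywhere except that class k's
#' informative group has f = base_maf + maf_shift (clipped to [0.01, 0.99]).
#'
#' @param K Number of classes (default 3).
#' @param n_per_class Samples per class; scalar or length-K (default 20).
#' @param p Total features (default 500).
#' @param q Informative features (default 15).
#' @param delta Between-class mean shift in noise-sd units (default 1.5).
#' @param rho Equicorrelation of the informative block, in [0, 1)
#'   (default 0.5).
#' @param noise_sd Noise standard deviation (default 1).
#' @param mode \code{"expression"} or \code{"snp"}.
#' @param base_maf Baseline allele frequency, snp mode (default 0.2).
#' @param maf_shift Class-dependent allele-frequency shift on informative
#'   SNPs, snp mode (default 0.15).
#' @param seed RNG seed; same seed gives bitwise-identical data.
#' @return A list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(K = 3, n_per_class = 20, p = 500, q = 15,
                           delta = 1.5, rho = 0.5, noise_sd = 1,
                           mode = c("expression", "snp"),
                           base_maf = 0.2, maf_shift = 0.15, seed = 1) {
  mode <- match.arg(mode)
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, K)
  if (length(n_per_class) != K)
    stop("n_per_class must be a scalar or length K", call. = FALSE)
  if (q > p) stop("q must not exceed p", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (delta < 0) stop("delta must be nonnegative", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (mode == "snp" && (base_maf <= 0 || base_maf >= 0.5))
    stop("base_maf must lie in (0, 0.5)", call. = FALSE)
  structure(list(K = K, n_per_class = as.integer(n_per_class), p = p, q = q,
                 delta = delta, rho = rho, noise_sd = noise_sd, mode = mode,
                 base_maf = base_maf, maf_shift = maf_shift, seed = seed),
            class = "synthetic_spec")
}

# informative features partitioned into K contiguous blocks, sizes differ <= 1
informative_blocks <- function(q, K) {
  sizes <- rep(q %/% K, K) + c(rep(1, q %% K), rep(0, K - q %% K))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  mapply(function(s, e) if (e >= s) seq(s, e) else integer(0),
         starts, ends, SIMPLIFY = FALSE)
}

#' Simulate expression-like multiclass data with planted features
#'
#' @param spec A \code{\link{synthetic_spec}} with mode "expression".
#' @return List with \code{X} (n x p matrix), \code{labels} (named character
#'   vector), \code{true_support} (ids of the q informative features) and
#'   \code{spec}.
#' @examples
#' sim <- simulate_expression(synthetic_spec(K = 3, n_per_class = 5,
#'   p = 50, q = 6, seed = 7))
#' dim(sim$X)
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mode != "expression")
    stop("spec mode must be \"expression\"", call. = FALSE)
  n <- sum(spec$n_per_class)
  cls <- rep(paste0("class", seq_len(spec$K)), times = spec$n_per_class)
  blocks <- informative_blocks(spec$q, spec$K)
  mu <- matrix(0, spec$K, spec$q)
  for (k in seq_len(spec$K)) mu[k, blocks[[k]]] <- spec$delta
  X <- with_seed(spec$seed, {
    # equicorrelated informative block via a per-sample shared factor
    z_common <- stats::rnorm(n)
    Z <- matrix(stats::rnorm(n * spec$q), n, spec$q)
    inf <- (sqrt(spec$rho) * z_common +
              sqrt(1 - spec$rho) * Z) * spec$noise_sd
    inf <- inf + mu[match(cls, paste0("class", seq_len(spec$K))), ,
                    drop = FALSE] * spec$noise_sd
    noise <- matrix(stats::rnorm(n * (spec$p - spec$q), sd = spec$noise_sd),
                    n, spec$p - spec$q)
    cbind(inf, noise)
  })
  dimnames(X) <- list(paste0("sample", seq_len(n)),
                      paste0("feature", seq_len(spec$p)))
  labels <- stats::setNames(cls, rownames(X))
  list(X = X, labels = labels,
       true_support = colnames(X)[seq_len(spec$q)], spec = spec)
}

#' Simulate SNP-like 0/1/2 genotype data with class-dependent frequencies
#'
#' @param spec A \code{\link{synthetic_spec}} with mode "snp".
#' @return List with \code{X} (n x p genotype matrix, entries in {0,1,2}),
#'   \code{labels}, \code{true_support} and \code{spec}.
#' @export
simulate_snp <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$mode != "snp")
    stop("spec mode must be \"snp\"", call. = FALSE)
  n <- sum(spec$n_per_class)
  cls <- rep(paste0("class", seq_len(spec$K)), times = spec$n_per_class)
  blocks <- informative_blocks(spec$q, spec$K)
  f <- matrix(spec$base_maf, spec$K, spec$p)
  for (k in seq_len(spec$K)) f[k, blocks[[k]]] <- spec$base_maf +
      spec$maf_shift
  if (any(f <= 0 | f >= 1))
    warning("allele frequencies outside (0, 1) were clipped to [0.01, 0.99]",
            call. = FALSE)
  f <- pmin(pmax(f, 0.01), 0.99)
  ki <- match(cls, paste0("class", seq_len(spec$K)))
  X <- with_seed(spec$seed, {
    probs <- f[ki, , drop = FALSE]
    matrix(stats::rbinom(n * spec$p, size = 2, prob = probs), n, spec$p)
  })
  dimnames(X) <- list(paste0("sample", seq_len(n)),
                      paste0("snp", seq_len(spec$p)))
  labels <- stats::setNames(cls, rownames(X))
  list(X = X, labels = labels,
       true_support = if (spec$maf_shift != 0)
         colnames(X)[seq_len(spec$q)] else character(0),
       spec = spec)
}

# run code with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
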