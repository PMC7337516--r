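## Sparse Bayesian NMF of accessibility counts: C ~ N(AP, Sigma) with a
## spike-and-slab (zero / gamma) prior on every element of A and P, fit by
## element-wise Gibbs sampling (see src/gibbs_nmf.cpp). Point estimates are
## posterior means over the sampling phase; pattern order is canonicalized
## by descending row sum of P.

#' Configuration for the Bayesian NMF
#'
#' @param n_patterns number of latent patterns n to learn (the model rank).
#' @param n_iterations Gibbs sweeps per phase; the sampler runs
#'   \code{n_iterations} of burn-in followed by \code{n_iterations} of
#'   sampling. Default 10000.
#' @param seed integer RNG seed; identical seed + config + input gives
#'   bit-identical output.
#' @param uncertainty_floor minimum per-element standard deviation of the
#'   noise model (must be > 0).
#' @param uncertainty_fraction multiplicative noise fraction: the standard
#'   deviation of entry (i,j) is \code{max(fraction * C[i,j], floor)}.
#' @param sparsity_scale scale of the gamma slab of the sparsity prior on
#'   elements of A and P.
#' @param zero_prob prior mass on exact zero for each element of A and P
#'   (the spike weight of the sparsity prior), in [0, 1).
#' @param n_feature_subsets number of random feature subsets for the
#'   genome-wide (distributed) mode; 1 means a single chain.
#' @return A \code{FactorizationConfig} list.
#' @export
factorization_config <- function(n_patterns, n_iterations = 10000L, seed = 42L,
                                 uncertainty_floor = 0.1,
                                 uncertainty_fraction = 0.1,
                                 sparsity_scale = 1, zero_prob = 0.25,
                                 n_feature_subsets = 1L) {
  if (length(n_patterns) != 1 || n_patterns < 1 || n_patterns != round(n_patterns))
    stop("n_patterns must be a positive integer")
  if (n_iterations < 1) stop("n_iterations must be positive")
  if (uncertainty_floor <= 0) stop("uncertainty_floor must be > 0")
  if (!(uncertainty_fraction > 0 && uncertainty_fraction <= 1))
    stop("uncertainty_fraction must be in (0, 1]")
  if (sparsity_scale <= 0) stop("sparsity_scale must be > 0")
  if (zero_prob < 0 || zero_prob >= 1) stop("zero_prob must be in [0, 1)")
  if (n_feature_subsets < 1) stop("n_feature_subsets must be >= 1")
  structure(list(n_patterns = as.integer(n_patterns),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 uncertainty_floor = uncertainty_floor,
                 uncertainty_fraction = uncertainty_fraction,
                 sparsity_scale = sparsity_scale,
                 zero_prob = zero_prob,
                 n_feature_subsets = as.integer(n_feature_subsets)),
            class = "FactorizationConfig")
}

#' Per-element uncertainty (noise standard deviation) of a count matrix
#'
#' Builds the standard-deviation matrix of the Gaussian noise model as
#' \code{max(fraction * C, floor)}: a conventional multiplicative noise model
#' for count data with a floor that keeps zero counts informative.
#'
#' @param matrix a \code{CountMatrix}.
#' @param fraction multiplicative noise fraction in (0, 1].
#' @param floor minimum standard deviation, > 0.
#' @return A dense numeric matrix of the same shape as the counts, every
#'   entry >= \code{floor}.
#' @export
estimate_uncertainty <- function(matrix, fraction = 0.1, floor = 0.1) {
  stopifnot(is_count_matrix(matrix))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (floor <= 0) stop("floor must be > 0")
  s <- as.matrix(matrix$values) * fraction
  s[s < floor] <- floor
  dimnames(s) <- dimnames(matrix$values)
  s
}

#' Chi-squared goodness of fit of a factorization
#'
#' \deqn{\chi^2 = \sum_{ij} ((C - AP)_{ij} / \Sigma_{ij})^2}
#'
#' @param matrix a \code{CountMatrix} (the data C).
#' @param sigma per-element standard deviation matrix, same shape as C.
#' @param A features x n amplitude matrix.
#' @param P n x cells pattern matrix.
#' @return The chi-squared statistic (a scalar).
#' @export
chi_squared <- function(matrix, sigma, A, P) {
  stopifnot(is_count_matrix(matrix))
  C <- as.matrix(matrix$values)
  if (!all(dim(sigma) == dim(C))) stop("sigma shape does not match C")
  if (nrow(A) != nrow(C) || ncol(P) != ncol(C) || ncol(A) != nrow(P))
    stop("A/P shapes do not conform to C")
  if (any(sigma == 0)) stop("sigma contains zero entries")
  sum(((C - A %*% P) / sigma)^2)
}

#' Fit the sparse Bayesian NMF by Gibbs sampling
#'
#' Decomposes the counts C (features x cells) into a non-negative amplitude
#' matrix A (features x n) and pattern matrix P (n x cells) under the model
#' \eqn{p(A,P|C,\Sigma) \propto p(C|A,P,\Sigma) p(A) p(P)} with an
#' element-wise Gaussian likelihood of mean AP and standard deviation
#' \eqn{\Sigma}, and a sparsity prior on every element of A and P that is
#' either exactly zero or gamma-distributed. The sampler runs
#' \code{n_iterations} burn-in sweeps then \code{n_iterations} sampling
#' sweeps; A and P are the posterior means over the sampling phase. Patterns
#' are ordered by descending row sum of P, which removes label-switching
#' nondeterminism.
#'
#' @param matrix a filtered \code{CountMatrix} (no all-zero rows or columns).
#' @param sigma optional uncertainty matrix; computed by
#'   \code{\link{estimate_uncertainty}} from the config when omitted.
#' @param config a \code{\link{factorization_config}}.
#' @return A \code{FactorizationResult}: list with non-negative \code{A}
#'   (with feature ids as rownames), \code{P} (with cell ids as colnames),
#'   \code{chi2_trace}, \code{init_chi2}, \code{final_chi2} (chi-squared at
#'   the posterior mean) and \code{config}.
#' @export
run_cogaps <- function(matrix, sigma = NULL, config) {
  stopifnot(is_count_matrix(matrix), inherits(config, "FactorizationConfig"))
  C <- as.matrix(matrix$values)
  if (!all(is.finite(C))) stop("input matrix contains non-finite values")
  if (config$n_patterns >= min(dim(C)))
    stop(sprintf("n_patterns (%d) must be smaller than min(features, cells) = %d",
                 config$n_patterns, min(dim(C))))
  if (any(Matrix::rowSums(matrix$values != 0) == 0) ||
      any(Matrix::colSums(matrix$values != 0) == 0))
    stop("matrix has all-zero rows or columns; run filter_sparse() first")
  if (is.null(sigma))
    sigma <- estimate_uncertainty(matrix, config$uncertainty_fraction,
                                  config$uncertainty_floor)
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  n <- config$n_patterns
  set.seed(config$seed)
  A0 <- base::matrix(rgamma(nrow(C) * n, shape = 1, scale = config$sparsity_scale),
                     nrow(C), n)
  P0 <- base::matrix(rgamma(n * ncol(C), shape = 1, scale = config$sparsity_scale),
                     n, ncol(C))
  trace_every <- max(1L, (2L * config$n_iterations) %/% 50L)
  fit <- .gibbs_nmf(C, sigma^2, A0, P0,
                    n_burn = config$n_iterations,
                    n_sample = config$n_iterations,
                    zero_prob = config$zero_prob,
                    sparsity_scale = config$sparsity_scale,
                    trace_every = trace_every)
  .finish_result(fit$A, fit$P, matrix, config,
                 chi2_trace = as.numeric(fit$chi2_trace),
                 init_chi2 = fit$init_chi2, final_chi2 = fit$final_chi2)
}

## canonicalize pattern order, attach dimnames, wrap as FactorizationResult
.finish_result <- function(A, P, matrix, config, chi2_trace, init_chi2,
                           final_chi2) {
  ord <- order(rowSums(P), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  P <- P[ord, , drop = FALSE]
  pat <- paste0("Pattern_", seq_len(ncol(A)))
  dimnames(A) <- list(feature_ids(matrix), pat)
  dimnames(P) <- list(pat, cell_ids(matrix))
  structure(list(A = A, P = P, chi2_trace = chi2_trace,
                 init_chi2 = init_chi2, final_chi2 = final_chi2,
                 config = config),
            class = "FactorizationResult")
}

#' @export
print.FactorizationResult <- function(x, ...) {
  cat(sprintf("FactorizationResult: %d features x %d patterns x %d cells, final chi^2 = %.4g\n",
              nrow(x$A), ncol(x$A), ncol(x$P), x$final_chi2))
  invisible(x)
}

#' Scan candidate pattern counts by goodness of fit
#'
#' Runs one independent, seeded factorization per candidate n and tabulates
#' the final chi-squared fit statistic. No automatic selection is performed:
#' the table is the deliverable, to be read alongside prior knowledge of the
#' cell populations.
#'
#' @param matrix a filtered \code{CountMatrix}.
#' @param sigma optional uncertainty matrix shared by all runs.
#' @param candidate_ns integer vector of pattern counts to try.
#' @param base_config a \code{\link{factorization_config}} whose
#'   \code{n_patterns} is overridden per run (each run uses seed
#'   \code{base_config$seed + index}).
#' @return data.frame with columns \code{n} and \code{final_chi2}.
#' @export
scan_dimensionality <- function(matrix, sigma = NULL, candidate_ns, base_config) {
  if (length(candidate_ns) == 0) stop("candidate_ns must be non-empty")
  if (any(candidate_ns < 1)) stop("candidate pattern counts must be >= 1")
  rows <- lapply(seq_along(candidate_ns), function(i) {
    cfg <- base_config
    cfg$n_patterns <- as.integer(candidate_ns[i])
    cfg$seed <- base_config$seed + i - 1L
    fit <- run_cogaps(matrix, sigma, cfg)
    data.frame(n = candidate_ns[i], final_chi2 = fit$final_chi2)
  })
  do.call(rbind, rows)
}

#' Genome-wide (distributed) factorization across random feature subsets
#'
#' Partitions features uniformly at random into \code{n_feature_subsets}
#' subsets, runs an independent Gibbs chain per subset, matches patterns
#' across chains by greedy maximum cosine similarity of P rows against the
#' first chain, averages matched rows into a consensus P, and re-estimates
#' each feature's amplitude row against the consensus P by non-negative
#' least squares. With one subset this is identical to
#' \code{\link{run_cogaps}}.
#'
#' @inheritParams run_cogaps
#' @return A \code{FactorizationResult}.
#' @export
run_distributed <- function(matrix, sigma = NULL, config) {
  stopifnot(is_count_matrix(matrix), inherits(config, "FactorizationConfig"))
  if (config$n_feature_subsets == 1L) return(run_cogaps(matrix, sigma, config))
  nf <- nrow(matrix$values)
  ns <- config$n_feature_subsets
  if (ns > nf)
    stop(sprintf("cannot split %d features into %d subsets", nf, ns))
  if (is.null(sigma))
    sigma <- estimate_uncertainty(matrix, config$uncertainty_fraction,
                                  config$uncertainty_floor)
  set.seed(config$seed)
  assign <- sample(rep_len(seq_len(ns), nf))
  if (min(table(assign)) <= config$n_patterns)
    stop("a feature subset is not larger than n_patterns; use fewer subsets")
  chains <- lapply(seq_len(ns), function(s) {
    keep <- assign == s
    sub <- count_matrix(matrix$values[keep, , drop = FALSE],
                        feature_ids = feature_ids(matrix)[keep],
                        cell_ids = cell_ids(matrix),
                        feature_kind = matrix$feature_kind,
                        cell_labels = matrix$cell_labels)
    cfg <- config
    cfg$n_feature_subsets <- 1L
    cfg$seed <- config$seed + s
    run_cogaps(sub, sigma[keep, , drop = FALSE], cfg)
  })
  n <- config$n_patterns
  ref <- chains[[1]]$P
  matched <- lapply(chains, function(ch) {
    ch$P[.match_patterns(ref, ch$P), , drop = FALSE]
  })
  P <- Reduce(`+`, matched) / length(matched)
  ## re-estimate A per feature by NNLS against the consensus P
  Pt <- t(P)
  C <- as.matrix(matrix$values)
  A <- t(vapply(seq_len(nf), function(i) {
    pracma::lsqnonneg(Pt, C[i, ])$x
  }, numeric(n)))
  ## chains share n_iterations, so traces align; their sum tracks total fit
  trace <- Reduce(`+`, lapply(chains, `[[`, "chi2_trace"))
  final <- chi_squared(matrix, sigma, A, P)
  init <- sum(vapply(chains, `[[`, numeric(1), "init_chi2"))
  .finish_result(A, P, matrix, config, chi2_trace = trace,
                 init_chi2 = init, final_chi2 = final)
}

## Greedy one-to-one matching of rows of P2 to rows of ref by cosine
## similarity; returns the permutation of P2 rows aligning them to ref.
.match_patterns <- function(ref, P2) {
  n <- nrow(ref)
  normalize <- function(M) M / pmax(sqrt(rowSums(M^2)), .Machine$double.eps)
  S <- normalize(ref) %*% t(normalize(P2))
  perm <- integer(n)
  used_r <- used_c <- rep(FALSE, n)
  for (step in seq_len(n)) {
    S_masked <- S
    S_masked[used_r, ] <- -Inf
    S_masked[, used_c] <- -Inf
    idx <- arrayInd(which.max(S_masked), dim(S))
    perm[idx[1]] <- idx[2]
    used_r[idx[1]] <- TRUE
    used_c[idx[2]] <- TRUE
  }
  perm
}
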