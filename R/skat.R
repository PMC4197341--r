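# Variance-component (kernel) score test for a region.

#' MAF-based variant weights for the variance-component test
#'
#' Evaluates the Beta(a1, a2) density at each estimated MAF and, by default,
#' squares it — the standard convention in which the quadratic-form weight
#' is the square of the per-variant weight `w_j = dbeta(maf_j; a1, a2)`.
#' With the defaults (1, 25), weights increase steeply as MAF decreases
#' (density 25 at MAF 0, about 19.64 at MAF 1%).
#'
#' @param maf_hat Estimated MAFs in (0, 1).
#' @param a1,a2 Beta shape parameters (defaults 1 and 25).
#' @param squared If `TRUE` (default) return the squared density; `FALSE`
#'   returns the plain density.
#' @return Positive weight vector.
#' @examples
#' skat_weights(0.01)               # ~ 385.8
#' skat_weights(0.5, 1, 1)          # 1: uniform weights
#' @export
skat_weights <- function(maf_hat, a1 = 1, a2 = 25, squared = TRUE) {
  if (any(maf_hat <= 0 | maf_hat >= 1)) {
    stop("'maf_hat' must lie strictly in (0, 1)")
  }
  d <- stats::dbeta(maf_hat, a1, a2)
  if (squared) d^2 else d
}

#' Variance-component (kernel) score test
#'
#' Tests the joint null that all variant effects in the region are zero via
#' the quadratic form `Q = sum_j w_j S_j^2`, with per-variant scores
#' `S_j = sum_i G_ij (y_i - mu0_i)` computed from residuals of the
#' covariate-only linear fit. Under the null, `Q / sigma^2` is distributed
#' as a mixture of 1-df chi-squares whose weights are the eigenvalues of
#' the weighted, covariate-projected genotype cross-product; the p-value is
#' evaluated with [pchisqmix()]. Missing dosages are scored 0.
#'
#' @param y Phenotype vector.
#' @param region A filtered `"genotype_region"`.
#' @param Z Covariate matrix including an intercept; `NULL` for intercept
#'   only.
#' @param weights Per-variant weights; default [skat_weights()] at the
#'   region's estimated MAFs.
#' @param n_perm If positive, additionally compute a permutation p-value by
#'   permuting the null residuals `n_perm` times (add-one correction).
#' @param seed Optional integer seed for the permutations.
#' @return An `"assoc_result"`; `details` carries the eigenvalues and the
#'   residual variance estimate.
#' @export
skat_test <- function(y, region, Z = NULL, weights = NULL, n_perm = 0,
                      seed = NULL) {
  stopifnot(inherits(region, "genotype_region"))
  n <- length(y)
  if (nrow(region$dosages) != n) {
    stop("phenotype and genotype region cover different numbers of individuals")
  }
  if (region$spec$n_variants == 0L) {
    return(new_assoc_result("skat", 0, 1,
                            details = list(note = "empty region")))
  }
  Z <- check_covariates(Z, n)
  G <- dosage_zero(region)
  if (is.null(weights)) {
    weights <- skat_weights(compute_variant_stats(region)$maf_hat)
  }
  if (length(weights) != ncol(G)) {
    stop("'weights' must have one entry per variant")
  }
  Q <- z_basis(Z)
  r <- project_out(Q, y)
  sigma2 <- sum(r^2) / (n - ncol(Z))
  S <- crossprod(G, r)
  q_stat <- sum(weights * S^2)
  G_t <- G - Q %*% crossprod(Q, G)          # covariate-projected genotypes
  Gw <- sweep(G_t, 2L, sqrt(weights), "*")
  lambda <- eigen(crossprod(Gw), symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda, 0)]
  if (length(lambda) == 0L || q_stat == 0) {
    return(new_assoc_result("skat", q_stat, 1,
                            details = list(lambda = lambda, sigma2 = sigma2)))
  }
  p <- as.numeric(pchisqmix(q_stat / sigma2, lambda))
  p_perm <- NA_real_
  if (n_perm > 0) {
    maybe_seed(seed)
    perm <- replicate(n_perm, r[sample.int(n)])
    perm <- perm - Q %*% crossprod(Q, perm) # re-orthogonalise to covariates
    q_perm <- colSums(weights * crossprod(G, perm)^2)
    p_perm <- (1 + sum(q_perm >= q_stat)) / (1 + n_perm)
  }
  new_assoc_result("skat", q_stat, min(max(p, 0), 1), p_perm,
                   details = list(lambda = lambda, sigma2 = sigma2))
}
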