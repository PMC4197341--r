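# Weighted score test with permutation p-values.

#' Weighted score test for a region
#'
#' Collapses the region to the per-individual scalar `S_i = xi' G_i` and
#' tests its association with the phenotype through the score statistic
#'
#' `U = sum_i (Y_i - gamma' Z_i) S_i`,
#' `V = sigma2 * (sum_i S_i^2 - (sum S_i Z_i)' (sum Z_i Z_i')^{-1} (sum S_i Z_i))`,
#'
#' where `gamma` is the least-squares fit of `Y` on the covariates alone and
#' `sigma2 = mean((Y - gamma' Z)^2)`. Under the null `T = U / sqrt(V)` is
#' asymptotically standard normal; the two-sided normal p-value is returned,
#' and optionally a permutation p-value obtained by permuting the null
#' residual vector and re-evaluating `|T|` (add-one correction, so the
#' smallest attainable value is `1 / (n_perm + 1)`).
#'
#' The statistic is invariant to rescaling `xi` by any positive constant, so
#' only the relative weighting of variants matters. The default `xi` weights
#' all variants equally; `xi = "mb"` uses the inverse Madsen-Browning
#' weights `1 / sqrt(n p (1-p))`.
#'
#' @param y Phenotype vector.
#' @param region A filtered `"genotype_region"`.
#' @param Z Covariate matrix including an intercept; `NULL` for intercept
#'   only.
#' @param xi Per-variant weight vector, or `"ones"` (default) / `"mb"`.
#' @param n_perm Number of permutations (0 for asymptotic only).
#' @param seed Optional integer seed for the permutations.
#' @return An `"assoc_result"` with statistic `T`, the asymptotic normal
#'   p-value, and (if `n_perm > 0`) the permutation p-value; `details`
#'   carries `U`, `V` and `sigma2`.
#' @examples
#' r <- simulate_genotypes(sample_region_spec(10, seed = 1), 200, seed = 2)
#' scoreseq_test(rnorm(200), r, n_perm = 200, seed = 3)
#' @export
scoreseq_test <- function(y, region, Z = NULL, xi = c("ones", "mb"),
                          n_perm = 0, seed = NULL) {
  stopifnot(inherits(region, "genotype_region"))
  n <- length(y)
  if (nrow(region$dosages) != n) {
    stop("phenotype and genotype region cover different numbers of individuals")
  }
  G <- dosage_zero(region)
  if (is.character(xi)) {
    xi <- match.arg(xi)
    xi <- switch(xi,
      ones = rep(1, ncol(G)),
      mb = {
        p_hat <- compute_variant_stats(region)$maf_hat
        1 / sqrt(n * p_hat * (1 - p_hat))
      })
  }
  if (length(xi) != ncol(G)) stop("'xi' must have one entry per variant")
  Z <- check_covariates(Z, n)
  S <- as.vector(G %*% xi)
  Q <- z_basis(Z)
  r <- project_out(Q, y)                    # Y - gamma' Z
  s_t <- project_out(Q, S)
  v0 <- sum(s_t^2)                          # sum S^2 - quadratic correction
  sigma2 <- sum(r^2) / n
  if (v0 <= 1e-12 * max(sum(S^2), 1)) {
    if (max(S) - min(S) < 1e-12) {
      # no genotype information at all (e.g. xi = 0): score carries nothing
      return(new_assoc_result("scoreseq", 0, 1,
                              details = list(U = 0, V = 0, sigma2 = sigma2)))
    }
    stop("degenerate variance: collapsed score is constant after ",
         "projection on the covariates")
  }
  U <- sum(r * S)
  V <- sigma2 * v0
  T_stat <- U / sqrt(V)
  p <- 2 * stats::pnorm(-abs(T_stat))
  p_perm <- NA_real_
  if (n_perm > 0) {
    maybe_seed(seed)
    p_perm <- scoreseq_perm_p(r, Q, s_t, v0, n, abs(T_stat), n_perm)
  }
  new_assoc_result("scoreseq", T_stat, p, p_perm,
                   details = list(U = U, V = V, sigma2 = sigma2))
}

# Permutation p-value for the weighted score test. The phenotype is
# reconstructed as fitted + permuted residuals; after re-projection on the
# covariates the statistic only needs the permuted residual vector.
# Vectorised over permutations (n x n_perm residual matrix).
scoreseq_perm_p <- function(r, Q, s_t, v0, n, t_obs, n_perm) {
  perm <- matrix(r[vapply(seq_len(n_perm), function(b) sample.int(n),
                          integer(n))], n, n_perm)
  perm <- perm - Q %*% crossprod(Q, perm)
  U_perm <- as.vector(crossprod(perm, s_t))
  sigma2_perm <- colSums(perm^2) / n
  t_perm <- abs(U_perm) / sqrt(sigma2_perm * v0)
  (1 + sum(t_perm >= t_obs)) / (1 + n_perm)
}
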