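# Aggregate burden scores and their regression test.

new_assoc_result <- function(method, statistic, p_value, p_value_perm = NA_real_,
                             details = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 p_value_perm = p_value_perm, details = details),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.na(x$p_value_perm)) {
    cat(", permutation p =", format(x$p_value_perm, digits = 4))
  }
  cat("\n")
  invisible(x)
}

#' Unweighted carrier count (T1) burden score
#'
#' For each individual, counts the variants in the region at which that
#' individual carries at least one rare allele. Missing dosages count as 0
#' carriers. The region should already be filtered to rare variants.
#'
#' @param region A filtered `"genotype_region"`.
#' @return Integer vector of per-individual counts with attribute
#'   `scheme = "t1_count"`.
#' @examples
#' r <- simulate_genotypes(sample_region_spec(5, seed = 1), 50, seed = 2)
#' t1_collapse(r)
#' @export
t1_collapse <- function(region) {
  stopifnot(inherits(region, "genotype_region"))
  s <- as.integer(rowSums(dosage_zero(region) >= 1L))
  attr(s, "scheme") <- "t1_count"
  s
}

#' MAF-weighted burden score
#'
#' Weighted allele count `S_i = sum_j G_ij / w_j` with
#' `w_j = sqrt(n * p_j * (1 - p_j))`, where `p_j` is the estimated MAF of
#' variant `j`; rarer variants contribute more per allele. Missing dosages
#' count 0.
#'
#' @param region A filtered `"genotype_region"`.
#' @param stats Optional precomputed [compute_variant_stats()] result.
#' @param n Sample size used in the weight (default: number of individuals
#'   in the region).
#' @return Numeric vector of per-individual weighted scores with attribute
#'   `scheme = "mb_weighted"`.
#' @export
mb_score <- function(region, stats = NULL, n = NULL) {
  stopifnot(inherits(region, "genotype_region"))
  if (is.null(stats)) stats <- compute_variant_stats(region)
  if (is.null(n)) n <- nrow(region$dosages)
  p_hat <- stats$maf_hat
  if (any(p_hat <= 0 | p_hat >= 1)) {
    stop("degenerate weight: estimated MAF of 0 or 1 for variant(s) ",
         paste(which(p_hat <= 0 | p_hat >= 1), collapse = ", "),
         " (such variants should have been filtered)")
  }
  w <- sqrt(n * p_hat * (1 - p_hat))
  s <- as.vector(dosage_zero(region) %*% (1 / w))
  attr(s, "scheme") <- "mb_weighted"
  s
}

#' Burden regression test
#'
#' Fits the linear model `y ~ Z + s` for a per-individual burden score `s`
#' and returns the two-sided t-test of the score coefficient. Equivalent to
#' `summary(lm(...))` but computed via residual projections so the same
#' code path serves the replicate engines.
#'
#' @param score Burden score vector ([t1_collapse()] or [mb_score()]).
#' @param y Phenotype vector.
#' @param Z Covariate matrix including an intercept; `NULL` (default) for
#'   intercept only.
#' @return An `"assoc_result"` with the t statistic and p-value; `details`
#'   holds the coefficient estimate and residual degrees of freedom.
#' @export
burden_regression <- function(score, y, Z = NULL) {
  n <- length(y)
  if (length(score) != n) stop("'score' and 'y' lengths differ")
  Z <- check_covariates(Z, n)
  Q <- z_basis(Z)
  s_t <- project_out(Q, score)
  ss <- sum(s_t^2)
  if (ss <= 1e-12 * max(sum(score^2), 1)) {
    stop("burden score is collinear with the covariates (constant score?); ",
         "p-value undefined")
  }
  r <- project_out(Q, y)
  bhat <- sum(s_t * r) / ss
  rss <- max(sum(r^2) - bhat^2 * ss, 0)
  df <- n - ncol(Z) - 1L
  if (df < 1L) stop("not enough observations for the burden regression")
  se <- sqrt(rss / df / ss)
  tstat <- if (se == 0) sign(bhat) * Inf else bhat / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  new_assoc_result(attr(score, "scheme") %||% "burden", tstat, p,
                   details = list(estimate = bhat, df = df))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
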