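# Internal helpers shared across modules.

# round half away from zero; R's round() ties to even, which is not what the
# causal-count rules use
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Validate and normalise a covariate matrix: default is intercept-only.
# The design must be full column rank and contain an intercept (a column
# spanning the constant vector), since all tests assume location invariance.
check_covariates <- function(Z, n) {
  if (is.null(Z)) {
    Z <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  Z <- as.matrix(Z)
  if (nrow(Z) != n) {
    stop("covariate matrix has ", nrow(Z), " rows but the phenotype has ", n)
  }
  if (qr(Z)$rank < ncol(Z)) {
    stop("covariate matrix is not full column rank")
  }
  # intercept present iff the constant vector lies in the column span
  ones <- rep(1, n)
  fit <- qr.fitted(qr(Z), ones)
  if (max(abs(fit - ones)) > 1e-8) {
    stop("covariate matrix must include an intercept column")
  }
  Z
}

# Orthonormal basis of the column span of Z, for residual projections.
z_basis <- function(Z) {
  qr.Q(qr(Z))
}

project_out <- function(Q, x) {
  x - Q %*% crossprod(Q, x)
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("'seed' must be a single number or NULL")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
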