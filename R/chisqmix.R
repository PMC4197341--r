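#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k lambda_k X_k > q)` for independent 1-df chi-square
#' variables `X_k`, the null distribution of variance-component score
#' statistics. The evaluation is exact characteristic-function inversion
#' (Imhof's method) with special cases where exactness is cheaper, and a
#' moment-matching fallback where the inversion integral cannot be
#' truncated at a practical length:
#'
#' * one eigenvalue: scaled chi-square, exact;
#' * two eigenvalues: one-dimensional convolution of chi-square tails,
#'   exact to integration tolerance;
#' * three or more: Imhof inversion truncated where the classical tail
#'   bound of the inversion integrand falls below `tol`; if the required
#'   truncation point is impractically large or quadrature fails, the
#'   Liu-Tang-Zhang non-central chi-square moment match is used.
#'
#' Eigenvalues below `1e-6 * max(lambda)` are dropped; they are numerical
#' rank-deficiency noise and contribute nothing at the tolerances used.
#'
#' @param q Quantile (scalar).
#' @param lambda Positive weights (eigenvalues of the quadratic form).
#' @param tol Absolute accuracy target for the inversion (default `1e-6`);
#'   tightened automatically when the first pass returns a small tail
#'   probability, so small p-values keep relative accuracy.
#' @return Upper-tail probability in `[0, 1]`. The attribute `"method"`
#'   records which evaluation route was used.
#' @examples
#' pchisqmix(3.84, 1)                  # = pchisq(3.84, 1, lower.tail = FALSE)
#' pchisqmix(10, c(3, 2, 1, 0.5))
#' @export
pchisqmix <- function(q, lambda, tol = 1e-6) {
  stopifnot(length(q) == 1L, is.finite(q))
  lambda <- lambda[lambda > 1e-6 * max(lambda, 0)]
  if (length(lambda) == 0L || all(lambda <= 0)) {
    return(structure(as.numeric(q <= 0), method = "degenerate"))
  }
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  if (q <= 0) return(structure(1, method = "degenerate"))
  p <- length(lambda)
  if (p == 1L) {
    return(structure(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                     method = "exact"))
  }
  if (p == 2L) {
    return(structure(chisqmix_conv2(q, lambda), method = "conv2"))
  }
  out <- chisqmix_imhof(q, lambda, tol)
  if (!is.na(out) && out < 1e-4 && tol > 1e-10) {
    refined <- chisqmix_imhof(q, lambda, tol = 1e-10)
    if (!is.na(refined)) out <- refined
  }
  if (is.na(out)) {
    return(structure(chisqmix_liu(q, lambda), method = "liu"))
  }
  structure(min(max(out, 0), 1), method = "imhof")
}

# exact convolution for two eigenvalues: condition on the larger component
chisqmix_conv2 <- function(q, lambda) {
  l1 <- max(lambda); l2 <- min(lambda)
  f <- function(x) {
    stats::dchisq(x, 1) *
      stats::pchisq((q - l1 * x) / l2, 1, lower.tail = FALSE)
  }
  v <- stats::integrate(f, 0, q / l1, rel.tol = 1e-10,
                        subdivisions = 2000L)$value
  min(max(v + stats::pchisq(q / l1, 1, lower.tail = FALSE), 0), 1)
}

# Imhof (1961) inversion. The integrand decays like u^{-(p/2 + 1)}, and the
# truncation error beyond U is bounded by [pi * (p/2) * U^(p/2) *
# prod(lambda)^(1/2)]^{-1}; U is chosen so that bound < tol. For small p or
# very unbalanced eigenvalues U can be enormous (heavily oscillatory
# integral), in which case NA is returned and the caller falls back.
chisqmix_imhof <- function(q, lambda, tol) {
  p <- length(lambda)
  log_u <- (log(2) - log(pi * p) - 0.5 * sum(log(lambda)) - log(tol)) /
    (p / 2)
  upper <- exp(log_u)
  if (!is.finite(upper) || upper > 1e5) return(NA_real_)
  integrand <- function(u) {
    lu <- outer(lambda, u)
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * q * u
    log_rho <- 0.25 * colSums(log1p(lu^2))
    sin(theta) * exp(-log_rho) / u
  }
  v <- tryCatch(
    stats::integrate(integrand, 0, upper, subdivisions = 10000L,
                     rel.tol = 1e-8, abs.tol = tol / 10)$value,
    error = function(e) NA_real_
  )
  if (is.na(v)) return(NA_real_)
  0.5 + v / pi
}

# Liu-Tang-Zhang moment matching to a (possibly non-central) chi-square
chisqmix_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
    a <- sqrt(df)
  }
  mu_q <- c1
  sigma_q <- sqrt(2 * c2)
  t_star <- (q - mu_q) / sigma_q
  mu_x <- df + delta
  sigma_x <- sqrt(2 * (df + 2 * delta))
  stats::pchisq(t_star * sigma_x + mu_x, df = df, ncp = delta,
                lower.tail = FALSE)
}
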