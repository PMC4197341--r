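#' Sign matrix of the trait-doubling construction
#'
#' Builds the matrix of component signs produced by an iterative doubling
#' scheme for generating correlated quantitative traits. The construction
#' starts from a single trait equal to one shared random component. At each
#' iteration `m` a single new component is drawn, and the trait list is
#' doubled: the first half adds the new component to each existing trait, the
#' second half adds it to the negative of each existing trait. After `k`
#' iterations there are `2^k` traits, each a signed sum of the same `k + 1`
#' components, so the correlation between traits `a` and `b` is exactly
#' `sum(signs[a, ] * signs[b, ]) / (k + 1)`.
#'
#' With the default `n_iterations = 4` the first 11 of the 16 traits have the
#' target correlation structure used throughout this package: all pairwise
#' correlations lie in `{-0.6, -0.2, 0.2, 0.6}`.
#'
#' @param n_iterations Number of doubling iterations (at least 1).
#' @return An integer matrix with `2^n_iterations` rows and
#'   `n_iterations + 1` columns, entries in `{-1, 1}`, of class
#'   `"sign_matrix"`. The final column (the component added last) is all `+1`.
#' @examples
#' S <- build_sign_matrix(4)
#' dim(S)                       # 16 x 5
#' implied_trait_correlation(S)[1, 2]  # 0.6
#' @export
build_sign_matrix <- function(n_iterations = 4) {
  if (!is.numeric(n_iterations) || length(n_iterations) != 1L ||
      is.na(n_iterations) || n_iterations < 1) {
    stop("'n_iterations' must be a single integer >= 1")
  }
  n_iterations <- as.integer(n_iterations)
  signs <- matrix(1L, 1L, 1L)
  for (m in seq_len(n_iterations)) {
    signs <- rbind(cbind(signs, 1L), cbind(-signs, 1L))
  }
  dimnames(signs) <- list(paste0("trait_", seq_len(nrow(signs))),
                          paste0("component_", seq_len(ncol(signs))))
  class(signs) <- c("sign_matrix", class(signs))
  signs
}

#' Exact correlation matrix implied by a sign matrix
#'
#' Because every trait is the sum of the same independent components with
#' signs `+1`/`-1`, the population correlation between two traits is the dot
#' product of their sign rows divided by the number of components.
#'
#' @param signs A sign matrix from [build_sign_matrix()].
#' @param n_traits Number of leading traits to retain (default 11, capped at
#'   the number of rows).
#' @return A symmetric `n_traits` x `n_traits` correlation matrix.
#' @export
implied_trait_correlation <- function(signs, n_traits = 11L) {
  signs <- unclass(signs)
  n_traits <- min(as.integer(n_traits), nrow(signs))
  s <- signs[seq_len(n_traits), , drop = FALSE]
  r <- tcrossprod(s) / ncol(s)
  dimnames(r) <- list(rownames(s), rownames(s))
  r
}

#' Generate correlated quantitative traits
#'
#' Draws, for each individual, one independent Student-t value per component
#' of the sign matrix and forms each trait as the signed sum given by the
#' corresponding row. Components are drawn in individual-major order (all
#' components of individual 1, then individual 2, ...), so runs are
#' reproducible for a fixed seed. The first `n_traits` traits are returned.
#'
#' Each trait is a sum of `k + 1` independent t(df) variables, so its
#' variance is `(k + 1) * df / (df - 2)`; with the defaults (5 components,
#' df = 15) this is 75/13, approximately 5.769. Traits are intentionally left
#' on this raw scale: the association tests are location/scale equivariant,
#' and genetic effects are added directly to these values.
#'
#' @param n_individuals Number of individuals (at least 2).
#' @param sign_matrix Sign matrix from [build_sign_matrix()].
#' @param df Degrees of freedom of the t components; must exceed 2 so the
#'   variance is finite and correlations are defined.
#' @param n_traits Number of leading traits to return (default 11).
#' @param seed Optional integer seed.
#' @return A numeric matrix (`n_individuals` x `n_traits`) of class
#'   `"trait_matrix"` with columns `trait_1`, ..., and attribute
#'   `target_corr`, the exact correlation matrix implied by the sign rows.
#' @examples
#' y <- generate_traits(2000, seed = 1)
#' round(cor(y[, 1], y[, 2]), 2)  # close to 0.6
#' @export
generate_traits <- function(n_individuals, sign_matrix = build_sign_matrix(4),
                            df = 15, n_traits = 11L, seed = NULL) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 2) {
    stop("'n_individuals' must be a single integer >= 2")
  }
  if (!is.numeric(df) || length(df) != 1L || df <= 2) {
    stop("'df' must exceed 2: the t distribution needs a finite variance ",
         "for the correlation targets to exist")
  }
  n <- as.integer(n_individuals)
  signs <- unclass(sign_matrix)
  n_traits <- min(as.integer(n_traits), nrow(signs))
  k <- ncol(signs)
  maybe_seed(seed)
  # one column per individual => draws are consumed individual-major
  components <- matrix(stats::rt(n * k, df = df), nrow = k, ncol = n)
  values <- t(signs[seq_len(n_traits), , drop = FALSE] %*% components)
  colnames(values) <- paste0("trait_", seq_len(n_traits))
  attr(values, "target_corr") <- implied_trait_correlation(sign_matrix, n_traits)
  class(values) <- c("trait_matrix", class(values))
  values
}

#' Sample correlation matrix of a trait matrix
#'
#' @param traits Numeric matrix of traits (individuals x traits).
#' @return Symmetric Pearson correlation matrix with unit diagonal.
#' @export
trait_correlation <- function(traits) {
  traits <- unclass(traits)
  attr(traits, "target_corr") <- NULL
  if (nrow(traits) < 2L) {
    stop("need at least 2 individuals to compute correlations")
  }
  sds <- apply(traits, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("correlation undefined: constant trait column(s) ",
         paste(which(sds == 0), collapse = ", "))
  }
  stats::cor(traits)
}

#' Write traits to a tab-separated file
#'
#' @param traits Trait matrix from [generate_traits()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traits_tsv <- function(traits, path) {
  df <- data.frame(individual_id = seq_len(nrow(traits)),
                   unclass(traits)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sign matrix to a tab-separated file
#'
#' @param signs Sign matrix from [build_sign_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sign_matrix_tsv <- function(signs, path) {
  utils::write.table(unclass(signs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
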