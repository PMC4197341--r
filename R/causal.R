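#' Select causal variants for a region
#'
#' Applies, in order, the four selection rules used to guarantee a workable
#' number of causal variants per region while prioritising high-risk
#' (non-synonymous / stop-gain / splicing) variants:
#'
#' 1. fewer than 10 variants in the region: all variants are causal;
#' 2. fewer than 5 high-risk variants and 10 to 100 variants in total: all
#'    high-risk variants plus a random additional 50% of the region's
#'    variant count, drawn from the non-high-risk variants;
#' 3. fewer than 5 high-risk variants and more than 100 variants in total:
#'    all high-risk variants plus a random 5% of the non-high-risk variants;
#' 4. five or more high-risk variants: exactly the high-risk set.
#'
#' Fractional counts are rounded half-up, and random draws in rules 2-3 are
#' capped at the number of non-high-risk variants available. The region
#' should already be filtered (rare, well-called variants only).
#'
#' @param region A filtered `"genotype_region"`.
#' @param seed Optional integer seed for the random draws in rules 2-3.
#' @return Sorted integer vector of causal variant indices (columns of the
#'   region's dosage matrix).
#' @export
select_causal_variants <- function(region, seed = NULL) {
  stopifnot(inherits(region, "genotype_region"))
  n_total <- region$spec$n_variants
  if (n_total < 1L) stop("cannot select causal variants in an empty region")
  hr <- which(region$spec$high_risk)
  non_hr <- setdiff(seq_len(n_total), hr)
  maybe_seed(seed)
  idx <- if (n_total < 10L) {
    seq_len(n_total)                                     # rule 1
  } else if (length(hr) >= 5L) {
    hr                                                   # rule 4
  } else if (n_total <= 100L) {                          # rule 2
    extra <- min(round_half_up(0.5 * n_total), length(non_hr))
    c(hr, sample(non_hr, extra))
  } else {                                               # rule 3
    extra <- min(round_half_up(0.05 * length(non_hr)), length(non_hr))
    c(hr, sample(non_hr, extra))
  }
  sort(idx)
}

#' Effect sizes from minor allele frequencies
#'
#' Assigns each causal variant the effect magnitude
#' `scale * |log10(maf)|`, so rarer variants receive larger effects
#' (e.g. 0.8 at MAF 1%, 1.2 at MAF 0.1% with the default scale 0.4).
#'
#' @param maf_hat Estimated MAFs of the causal variants, in (0, 0.5).
#' @param scale Multiplier (default 0.4).
#' @return Positive numeric vector of effect magnitudes.
#' @export
assign_effect_sizes <- function(maf_hat, scale = 0.4) {
  if (any(!is.finite(maf_hat)) || any(maf_hat <= 0) || any(maf_hat >= 0.5)) {
    stop("'maf_hat' must lie strictly in (0, 0.5); a zero MAF would give an ",
         "infinite effect")
  }
  scale * abs(log10(maf_hat))
}

#' Assign effect directions
#'
#' In unidirectional mode all effects stay positive. In bidirectional mode
#' the first half of the causal variants (in variant order) keep positive
#' signs and the second half become negative; with an odd count the extra
#' variant is positive (ceiling split).
#'
#' @param beta Positive effect magnitudes, in variant order.
#' @param mode `"unidirectional"` or `"bidirectional"`.
#' @return Signed numeric vector, same length as `beta`.
#' @export
assign_directions <- function(beta,
                              mode = c("unidirectional", "bidirectional")) {
  mode <- match.arg(mode)
  if (mode == "unidirectional" || length(beta) == 0L) return(beta)
  p <- length(beta)
  n_pos <- ceiling(p / 2)
  sign_vec <- rep(c(1, -1), c(n_pos, p - n_pos))
  beta * sign_vec
}

#' Build a causal model for a region
#'
#' Convenience wrapper: selects causal variants, computes MAF-based effect
#' magnitudes from the region's estimated MAFs, and applies the direction
#' mode.
#'
#' @param region A filtered `"genotype_region"`.
#' @param direction_mode `"unidirectional"` or `"bidirectional"`.
#' @param scale Effect-size multiplier (default 0.4).
#' @param seed Optional integer seed for the causal-variant draw.
#' @return A list of class `"causal_model"` with elements `region_id`,
#'   `causal_indices`, `beta` (signed), `direction_mode`, `seed`.
#' @export
causal_model <- function(region,
                         direction_mode = c("unidirectional", "bidirectional"),
                         scale = 0.4, seed = NULL) {
  direction_mode <- match.arg(direction_mode)
  idx <- select_causal_variants(region, seed = seed)
  st <- compute_variant_stats(region)
  beta <- assign_directions(assign_effect_sizes(st$maf_hat[idx], scale),
                            direction_mode)
  structure(list(region_id = region$spec$region_id, causal_indices = idx,
                 beta = beta, direction_mode = direction_mode, seed = seed),
            class = "causal_model")
}

# per-individual genetic component sum(beta_j * G_ij), missing dosage -> 0
genetic_component <- function(region, model) {
  dos <- dosage_zero(region)
  as.vector(dos[, model$causal_indices, drop = FALSE] %*% model$beta)
}

#' Add genetic effects to a null phenotype
#'
#' Computes `y_p = y_0 + sum_j beta_j G_j` over the sampled individuals,
#' with missing dosages contributing 0.
#'
#' @param y0 Numeric null phenotype vector.
#' @param region A `"genotype_region"` over the same individuals.
#' @param model A `"causal_model"` for that region.
#' @return Numeric phenotype vector under the alternative.
#' @export
apply_genetic_effects <- function(y0, region, model) {
  if (length(y0) != nrow(region$dosages)) {
    stop("phenotype and genotype region cover different numbers of ",
         "individuals (", length(y0), " vs ", nrow(region$dosages), ")")
  }
  y0 + genetic_component(region, model)
}

#' Proportion of phenotypic variance explained by the causal variants
#'
#' `R^2 = var(sum_j beta_j G_j) / var(y_p)`, both sample variances computed
#' over the analyzed individuals.
#'
#' @param region A `"genotype_region"`.
#' @param model A `"causal_model"`.
#' @param yp Phenotype vector under the alternative (see
#'   [apply_genetic_effects()]).
#' @return The variance ratio (non-negative; about 0-1 up to sampling noise).
#' @export
proportion_variance <- function(region, model, yp) {
  v_y <- stats::var(yp)
  if (!is.finite(v_y) || v_y == 0) {
    stop("R^2 undefined: phenotype variance is zero")
  }
  stats::var(genetic_component(region, model)) / v_y
}

#' Write a causal model to JSON
#'
#' @param model A `"causal_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_causal_model_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
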