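#' Case-cohort sampling configuration
#'
#' Describes the two-stage design: a random subcohort followed by per-trait
#' extreme selection with exclusion (an individual selected for one trait is
#' not eligible for later traits or repeated selection). The defaults mirror
#' a targeted-sequencing design of 504 random subcohort members plus the top
#' 50 extremes for each of ten traits and the top 92 for an eleventh, from a
#' population of 12,000 (1096 individuals in total).
#'
#' @param cohort_size Size of the random subcohort (default 504).
#' @param extremes_per_trait Non-negative integer vector: number of extremes
#'   to select per trait, in trait order (default `c(rep(50, 10), 92)`).
#' @param tail Which extreme to take: `"upper"` (largest values, the
#'   default), `"lower"`, or `"both"` (largest absolute values).
#' @param trait_order Order in which traits claim their extremes (default
#'   `seq_along(extremes_per_trait)`). Earlier traits exclude their
#'   selections from later ones.
#' @param seed Optional integer seed used by [sample_case_cohort()].
#' @return A list of class `"sampling_config"`.
#' @export
sampling_config <- function(cohort_size = 504L,
                            extremes_per_trait = c(rep(50L, 10L), 92L),
                            tail = c("upper", "lower", "both"),
                            trait_order = NULL, seed = NULL) {
  tail <- match.arg(tail)
  if (cohort_size < 0 || any(extremes_per_trait < 0)) {
    stop("'cohort_size' and 'extremes_per_trait' must be non-negative")
  }
  if (is.null(trait_order)) trait_order <- seq_along(extremes_per_trait)
  if (!setequal(trait_order, seq_along(extremes_per_trait))) {
    stop("'trait_order' must be a permutation of the trait indices")
  }
  structure(list(cohort_size = as.integer(cohort_size),
                 extremes_per_trait = as.integer(extremes_per_trait),
                 tail = tail, trait_order = as.integer(trait_order),
                 seed = seed),
            class = "sampling_config")
}

#' Draw a case-cohort sample from a population of traits
#'
#' Stage 1 draws `cohort_size` individuals uniformly without replacement.
#' Stage 2 walks the traits in `trait_order`; for each trait it ranks the
#' not-yet-selected individuals on that trait and takes the configured
#' number from the configured tail. Ties are broken by individual index so
#' the sample is fully determined by the seed.
#'
#' @param traits Trait matrix (individuals x traits), e.g. from
#'   [generate_traits()].
#' @param config A [sampling_config()].
#' @return A data frame of class `"case_cohort_sample"` with columns
#'   `index` (row in `traits`; unique) and `source` (`"subcohort"` or
#'   `"extreme_trait_<k>"`), in selection order.
#' @examples
#' y <- generate_traits(12000, seed = 1)
#' s <- sample_case_cohort(y, sampling_config(seed = 2))
#' nrow(s)                      # 1096
#' sum(s$source != "subcohort") # 592
#' @export
sample_case_cohort <- function(traits, config = sampling_config()) {
  stopifnot(inherits(config, "sampling_config"))
  traits <- unclass(traits)
  n <- nrow(traits)
  need <- config$cohort_size + sum(config$extremes_per_trait)
  if (n < need) {
    stop("infeasible sampling: design needs ", need,
         " individuals but the population has ", n,
         " (shortfall ", need - n, ")")
  }
  if (ncol(traits) < length(config$extremes_per_trait)) {
    stop("trait matrix has fewer traits than 'extremes_per_trait'")
  }
  maybe_seed(config$seed)
  selected <- integer(0)
  source <- character(0)
  if (config$cohort_size > 0L) {
    selected <- sample.int(n, config$cohort_size)
    source <- rep("subcohort", config$cohort_size)
  }
  available <- rep(TRUE, n)
  available[selected] <- FALSE
  for (k in config$trait_order) {
    m <- config$extremes_per_trait[k]
    if (m == 0L) next
    cand <- which(available)
    v <- traits[cand, k]
    key <- switch(config$tail, upper = -v, lower = v, both = -abs(v))
    take <- cand[order(key, cand)][seq_len(m)]
    selected <- c(selected, take)
    source <- c(source, rep(paste0("extreme_trait_", k), m))
    available[take] <- FALSE
  }
  out <- data.frame(index = selected, source = source)
  class(out) <- c("case_cohort_sample", class(out))
  attr(out, "config") <- config
  out
}

#' Write a case-cohort sample to TSV
#'
#' @param sample A `"case_cohort_sample"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_tsv <- function(sample, path) {
  utils::write.table(data.frame(individual_id = sample$index,
                                source = sample$source),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
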