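# Shared fixtures, all built in code.

# Target 11 x 11 trait correlation matrix, transcribed by hand (independent
# of the package's sign-matrix construction).
target_corr_11 <- local({
  m <- rbind(
    c( 1.0, 0.6, 0.2, 0.6, -0.2, 0.2, 0.6, 0.2, -0.6, -0.2, 0.2),
    c( 0.6, 1.0, 0.6, 0.2, 0.2, -0.2, 0.2, 0.6, -0.2, -0.6, -0.2),
    c( 0.2, 0.6, 1.0, 0.6, 0.6, 0.2, -0.2, 0.2, 0.2, -0.2, -0.6),
    c( 0.6, 0.2, 0.6, 1.0, 0.2, 0.6, 0.2, -0.2, -0.2, 0.2, -0.2),
    c(-0.2, 0.2, 0.6, 0.2, 1.0, 0.6, 0.2, 0.6, 0.6, 0.2, -0.2),
    c( 0.2, -0.2, 0.2, 0.6, 0.6, 1.0, 0.6, 0.2, 0.2, 0.6, 0.2),
    c( 0.6, 0.2, -0.2, 0.2, 0.2, 0.6, 1.0, 0.6, -0.2, 0.2, 0.6),
    c( 0.2, 0.6, 0.2, -0.2, 0.6, 0.2, 0.6, 1.0, 0.2, -0.2, 0.2),
    c(-0.6, -0.2, 0.2, -0.2, 0.6, 0.2, -0.2, 0.2, 1.0, 0.6, 0.2),
    c(-0.2, -0.6, -0.2, 0.2, 0.2, 0.6, 0.2, -0.2, 0.6, 1.0, 0.6),
    c( 0.2, -0.2, -0.6, -0.2, -0.2, 0.2, 0.6, 0.2, 0.2, 0.6, 1.0))
  dimnames(m) <- list(paste0("trait_", 1:11), paste0("trait_", 1:11))
  m
})

# small genotype region built directly from a dosage matrix
make_region <- function(dosages, maf = NULL, high_risk = FALSE,
                        missing_rate = 0, region_id = "toy") {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(maf)) {
    maf <- pmax(colMeans(dosages, na.rm = TRUE) / 2, 1e-4)
    maf <- pmin(maf, 0.5)
  }
  sp <- region_spec(maf = maf, high_risk = high_risk,
                    missing_rate = missing_rate, region_id = region_id)
  structure(list(dosages = dosages, spec = sp), class = "genotype_region")
}

# region with given numbers of high-risk and total variants, rare MAFs,
# enough individuals that nothing is monomorphic
make_flagged_region <- function(n_total, n_high_risk, n_individuals = 4000,
                                seed = 99) {
  sp <- sample_region_spec(n_total, high_risk_prob = 0,
                           maf_range = c(0.004, 0.009),
                           missing_beta = NULL, seed = seed)
  sp$high_risk <- seq_len(n_total) <= n_high_risk
  simulate_genotypes(sp, n_individuals, seed = seed + 1)
}

# scaled-down sampling design used by engine tests (same structure as the
# default: random subcohort + 10 traits x k extremes + one larger trait)
small_sampling <- function(seed = NULL) {
  sampling_config(cohort_size = 100L,
                  extremes_per_trait = c(rep(10L, 10L), 18L),
                  seed = seed)
}
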