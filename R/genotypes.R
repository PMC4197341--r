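#' Construct a region specification
#'
#' A region specification describes the variants of one targeted sequencing
#' region: per-variant minor allele frequencies, high-risk annotation flags
#' (standing in for non-synonymous / stop-gain / splicing labels), and
#' per-variant missingness rates.
#'
#' @param maf Numeric vector of minor allele frequencies in (0, 0.5].
#' @param high_risk Logical vector of high-risk flags (recycled).
#' @param missing_rate Numeric vector of per-variant missing-call rates in
#'   `[0, 1)` (recycled).
#' @param region_id Region label.
#' @return A list of class `"region_spec"` with elements `region_id`,
#'   `n_variants`, `maf`, `high_risk`, `missing_rate`.
#' @export
region_spec <- function(maf, high_risk = FALSE, missing_rate = 0,
                        region_id = "region_1") {
  if (length(maf) < 1L) stop("a region must contain at least one variant")
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("'maf' entries must lie in (0, 0.5]")
  }
  n <- length(maf)
  high_risk <- rep_len(as.logical(high_risk), n)
  missing_rate <- rep_len(missing_rate, n)
  if (any(missing_rate < 0) || any(missing_rate >= 1)) {
    stop("'missing_rate' entries must lie in [0, 1)")
  }
  structure(list(region_id = region_id, n_variants = n, maf = maf,
                 high_risk = high_risk, missing_rate = missing_rate),
            class = "region_spec")
}

#' Draw a random region specification
#'
#' Samples per-variant MAFs from a rare-skewed (log-uniform) distribution,
#' high-risk flags as independent Bernoulli draws, and missing rates from a
#' Beta distribution. The default MAF range (5e-4, 0.01) keeps all variants
#' rare (MAF < 1%) while giving expected minor-allele counts large enough to
#' be informative at the sample sizes used here; the log-uniform shape
#' mimics the excess of very rare variants seen in site-frequency spectra.
#'
#' @param n_variants Number of variants (>= 1).
#' @param high_risk_prob Probability that a variant is flagged high risk.
#' @param maf_range Length-2 range for the log-uniform MAF draw.
#' @param missing_beta Length-2 Beta shape parameters for per-variant missing
#'   rates (default `c(1, 30)`, mean about 3%, occasional variants above the
#'   10% removal threshold), or `NULL` for no missingness.
#' @param region_id Region label.
#' @param seed Optional integer seed.
#' @return A `"region_spec"`.
#' @examples
#' sp <- sample_region_spec(257, seed = 1)
#' all(sp$maf < 0.01)
#' @export
sample_region_spec <- function(n_variants, high_risk_prob = 0.1,
                               maf_range = c(5e-4, 0.01),
                               missing_beta = c(1, 30),
                               region_id = "region_1", seed = NULL) {
  if (!is.numeric(n_variants) || length(n_variants) != 1L || n_variants < 1) {
    stop("'n_variants' must be a single integer >= 1")
  }
  if (high_risk_prob < 0 || high_risk_prob > 1) {
    stop("'high_risk_prob' must lie in [0, 1]")
  }
  n <- as.integer(n_variants)
  maybe_seed(seed)
  maf <- 10^stats::runif(n, log10(maf_range[1L]), log10(maf_range[2L]))
  hr <- stats::runif(n) < high_risk_prob
  miss <- if (is.null(missing_beta)) {
    rep(0, n)
  } else {
    stats::rbeta(n, missing_beta[1L], missing_beta[2L])
  }
  region_spec(maf = maf, high_risk = hr, missing_rate = miss,
              region_id = region_id)
}

#' Simulate genotype dosages for a region
#'
#' Dosages are independent Binomial(2, MAF) draws per variant
#' (Hardy-Weinberg, no linkage disequilibrium), and calls are masked as
#' missing (`NA`) independently at each variant's missing rate.
#'
#' @param spec A `"region_spec"`.
#' @param n_individuals Number of individuals (>= 1).
#' @param seed Optional integer seed.
#' @return A list of class `"genotype_region"` with elements `dosages`
#'   (integer matrix, `n_individuals` x `n_variants`, entries 0/1/2 or `NA`)
#'   and `spec`.
#' @export
simulate_genotypes <- function(spec, n_individuals, seed = NULL) {
  stopifnot(inherits(spec, "region_spec"))
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1) {
    stop("'n_individuals' must be a single integer >= 1")
  }
  n <- as.integer(n_individuals)
  p <- spec$n_variants
  maybe_seed(seed)
  dos <- matrix(stats::rbinom(n * p, 2L, rep(spec$maf, each = n)), n, p)
  if (any(spec$missing_rate > 0)) {
    mask <- matrix(stats::runif(n * p) <
                     rep(spec$missing_rate, each = n), n, p)
    dos[mask] <- NA_integer_
  }
  colnames(dos) <- paste0(spec$region_id, "_v", seq_len(p))
  structure(list(dosages = dos, spec = spec), class = "genotype_region")
}

#' Per-variant summary statistics
#'
#' Estimates each variant's minor allele frequency from the non-missing
#' dosages, folding to the minor allele when the estimated frequency exceeds
#' 0.5, and reports the observed missing fraction and the minor-allele count.
#'
#' @param region A `"genotype_region"`.
#' @return A data frame with one row per variant: `maf_hat`, `missing_frac`,
#'   `allele_count` (minor alleles among non-missing calls), `folded`.
#' @examples
#' r <- simulate_genotypes(sample_region_spec(5, seed = 1), 100, seed = 2)
#' compute_variant_stats(r)
#' @export
compute_variant_stats <- function(region) {
  stopifnot(inherits(region, "genotype_region"))
  dos <- region$dosages
  n_obs <- colSums(!is.na(dos))
  if (any(n_obs == 0L)) {
    stop("all genotypes missing for variant(s) ",
         paste(which(n_obs == 0L), collapse = ", "))
  }
  ac_raw <- colSums(dos, na.rm = TRUE)
  p_hat <- ac_raw / (2 * n_obs)
  folded <- p_hat > 0.5
  maf_hat <- ifelse(folded, 1 - p_hat, p_hat)
  allele_count <- ifelse(folded, 2 * n_obs - ac_raw, ac_raw)
  data.frame(maf_hat = maf_hat, missing_frac = 1 - n_obs / nrow(dos),
             allele_count = as.integer(allele_count), folded = folded,
             row.names = colnames(dos))
}

#' Filter variants on MAF and missingness
#'
#' Keeps variants that are polymorphic (estimated MAF > 0), rare
#' (estimated MAF strictly below `maf_max`) and well called (missing
#' fraction at most `missing_max`). Variant order is preserved. Monomorphic
#' variants are removed because downstream MAF-based weights are undefined
#' for them. An empty result is legal and flagged via the `"empty"`
#' attribute together with a warning.
#'
#' @param region A `"genotype_region"`.
#' @param maf_max Exclusive upper MAF bound (default 0.01).
#' @param missing_max Inclusive upper bound on the missing fraction
#'   (default 0.10: variants with a missing rate above 10% are removed).
#' @return A `"genotype_region"` restricted to the kept variants, with the
#'   spec subset accordingly and attribute `"empty"` set if nothing is kept.
#' @export
filter_variants <- function(region, maf_max = 0.01, missing_max = 0.10) {
  stopifnot(inherits(region, "genotype_region"))
  st <- compute_variant_stats(region)
  keep <- st$maf_hat > 0 & st$maf_hat < maf_max & st$missing_frac <= missing_max
  out <- subset_region(region, which(keep))
  if (!any(keep)) {
    warning("no variants pass the filters in ", region$spec$region_id)
    attr(out, "empty") <- TRUE
  }
  out
}

# index a region's variants, keeping the spec in sync
subset_region <- function(region, idx) {
  sp <- region$spec
  sp$maf <- sp$maf[idx]
  sp$high_risk <- sp$high_risk[idx]
  sp$missing_rate <- sp$missing_rate[idx]
  sp$n_variants <- length(idx)
  structure(list(dosages = region$dosages[, idx, drop = FALSE], spec = sp),
            class = "genotype_region")
}

# dosage matrix with missing calls scored as 0 (the convention used by all
# four tests, applied after the missingness filter)
dosage_zero <- function(region) {
  dos <- region$dosages
  dos[is.na(dos)] <- 0L
  dos
}

#' Preset region sizes
#'
#' Variant counts spanning the range of targeted-region sizes the package is
#' designed to emulate, from very small regions (3-9 rare variants) to large
#' ones (194 and 257).
#'
#' @return A data frame with columns `region_id` and `n_variants`.
#' @export
region_presets <- function() {
  data.frame(
    region_id = paste0("preset_", c(3, 4, 6, 9, 34, 50, 194, 257)),
    n_variants = c(3L, 4L, 6L, 9L, 34L, 50L, 194L, 257L)
  )
}

#' Write a region's dosages to TSV
#'
#' @param region A `"genotype_region"`.
#' @param path Output file path. Missing dosages are written as `NA`.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(region, path) {
  df <- data.frame(individual_id = seq_len(nrow(region$dosages)),
                   region$dosages, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region specification to JSON
#'
#' @param spec A `"region_spec"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_spec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read targeted-region genotypes from a VCF file
#'
#' Optional real-data path: reads biallelic variants from a VCF and returns
#' one `"genotype_region"` per row of a BED-style region table. Dosage is
#' the ALT allele count parsed from the GT field; missing or partially
#' missing GT calls become `NA`. Requires the `vcfR` package.
#'
#' @param file Path to a VCF file (plain or bgzipped).
#' @param regions Data frame with columns `region_id`, `chrom`, `start`,
#'   `end` (0-based half-open intervals), or `NULL` to return the whole file
#'   as a single region named after the file.
#' @return A named list of `"genotype_region"` objects.
#' @export
read_region_vcf <- function(file, regions = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF files requires the 'vcfR' package")
  }
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  fix <- fix[biallelic, , drop = FALSE]
  gt <- gt[biallelic, , drop = FALSE]
  dose_all <- gt_to_dosage(gt)
  pos <- as.numeric(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  if (is.null(regions)) {
    regions <- data.frame(region_id = basename(file), chrom = chrom[1L],
                          start = 0, end = max(pos))
  }
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    # BED convention: 0-based half-open, VCF POS is 1-based
    in_r <- chrom == r$chrom & pos > r$start & pos <= r$end
    dos <- t(dose_all[in_r, , drop = FALSE])
    colnames(dos) <- rownames(dose_all)[in_r]
    n_obs <- pmax(colSums(!is.na(dos)), 1L)
    p_hat <- colSums(dos, na.rm = TRUE) / (2 * n_obs)
    maf <- pmin(pmax(ifelse(p_hat > 0.5, 1 - p_hat, p_hat), 1e-12), 0.5)
    sp <- region_spec(maf = maf, high_risk = FALSE,
                      missing_rate = colMeans(is.na(dos)),
                      region_id = as.character(r$region_id))
    structure(list(dosages = dos, spec = sp), class = "genotype_region")
  })
  names(out) <- regions$region_id
  out
}

# "0/1", "0|1", "1/1", ".", "./." ... -> 0/1/2/NA
gt_to_dosage <- function(gt) {
  parse1 <- function(x) {
    alleles <- strsplit(x, "[/|]")
    vapply(alleles, function(a) {
      if (length(a) == 0L || anyNA(a) || any(a == ".")) return(NA_integer_)
      sum(a != "0")
    }, integer(1L))
  }
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out[] <- parse1(as.character(gt))
  out[is.na(gt)] <- NA_integer_
  out
}
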