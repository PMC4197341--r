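# Replicate engines for empirical type I error and power.

#' Replicate grid for an evaluation run
#'
#' @param n_replicates Number of simulation replicates (>= 1).
#' @param alphas Nominal significance levels (default 0.001, 0.01, 0.05).
#' @param methods Subset of `c("t1", "mb", "skat", "scoreseq")`.
#' @param seed Master seed for the whole run. One sequential RNG stream
#'   drives every replicate, including permutation sub-streams, so runs are
#'   exactly reproducible.
#' @return A list of class `"replicate_grid"`.
#' @export
replicate_grid <- function(n_replicates,
                           alphas = c(0.001, 0.01, 0.05),
                           methods = c("t1", "mb", "skat", "scoreseq"),
                           seed = 1L) {
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (any(alphas <= 0 | alphas >= 1)) stop("'alphas' must lie in (0, 1)")
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(n_replicates = as.integer(n_replicates), alphas = alphas,
                 methods = methods, seed = as.integer(seed)),
            class = "replicate_grid")
}

# Precompute everything about a region that does not change across
# replicates: projected burden scores, eigenvalues of the weighted kernel,
# and the projected collapsed score.
prepare_region_methods <- function(region, Q, k, methods, xi = "ones",
                                   skat_a = c(1, 25)) {
  G <- dosage_zero(region)
  n <- nrow(G)
  st <- compute_variant_stats(region)
  prep <- list(n = n, k = k, n_variants = ncol(G))
  if ("t1" %in% methods) {
    s <- t1_collapse(region)
    s_t <- project_out(Q, s)
    prep$t1 <- list(s_t = s_t, ss = sum(s_t^2))
  }
  if ("mb" %in% methods) {
    s <- mb_score(region, stats = st, n = n)
    s_t <- project_out(Q, s)
    prep$mb <- list(s_t = s_t, ss = sum(s_t^2))
  }
  if ("skat" %in% methods) {
    w <- skat_weights(st$maf_hat, skat_a[1L], skat_a[2L])
    G_t <- G - Q %*% crossprod(Q, G)
    lambda <- eigen(crossprod(sweep(G_t, 2L, sqrt(w), "*")),
                    symmetric = TRUE, only.values = TRUE)$values
    prep$skat <- list(G = G, w = w,
                      lambda = lambda[lambda > 1e-10 * max(lambda, 0)])
  }
  if ("scoreseq" %in% methods) {
    xi_vec <- if (is.character(xi)) {
      switch(match.arg(xi, c("ones", "mb")),
             ones = rep(1, ncol(G)),
             mb = 1 / sqrt(n * st$maf_hat * (1 - st$maf_hat)))
    } else xi
    S <- as.vector(G %*% xi_vec)
    s_t <- project_out(Q, S)
    prep$scoreseq <- list(s_t = s_t, v0 = sum(s_t^2))
  }
  prep
}

# One replicate's p-values for one region given the projected phenotype
# residuals r (and Q for permutation re-projection).
run_prepared <- function(prep, r, Q, n_perm) {
  n <- prep$n; k <- prep$k
  rr <- sum(r^2)
  out <- c()
  burden_p <- function(b) {
    bhat <- sum(b$s_t * r) / b$ss
    rss <- max(rr - bhat^2 * b$ss, 0)
    df <- n - k - 1L
    tt <- bhat / sqrt(rss / df / b$ss)
    2 * stats::pt(-abs(tt), df = df)
  }
  if (!is.null(prep$t1)) out["t1"] <- tryCatch(burden_p(prep$t1),
                                               error = function(e) NA_real_)
  if (!is.null(prep$mb)) out["mb"] <- tryCatch(burden_p(prep$mb),
                                               error = function(e) NA_real_)
  if (!is.null(prep$skat)) {
    out["skat"] <- tryCatch({
      S <- crossprod(prep$skat$G, r)
      q_stat <- sum(prep$skat$w * S^2)
      sigma2 <- rr / (n - k)
      as.numeric(pchisqmix(q_stat / sigma2, prep$skat$lambda))
    }, error = function(e) NA_real_)
  }
  if (!is.null(prep$scoreseq)) {
    out["scoreseq"] <- tryCatch({
      sq <- prep$scoreseq
      T_stat <- sum(r * sq$s_t) / sqrt((rr / n) * sq$v0)
      if (n_perm > 0) {
        scoreseq_perm_p(r, Q, sq$s_t, sq$v0, n, abs(T_stat), n_perm)
      } else {
        2 * stats::pnorm(-abs(T_stat))
      }
    }, error = function(e) NA_real_)
  }
  out
}

# shared driver for the null and power engines
run_replicates <- function(grid, regions, sampling, trait, sign_matrix,
                           n_population, df, mode, n_perm, Z, xi, skat_a,
                           models = NULL) {
  stopifnot(inherits(grid, "replicate_grid"))
  if (inherits(regions, "genotype_region")) regions <- list(regions)
  if (is.null(names(regions)) || any(names(regions) == "")) {
    names(regions) <- vapply(regions, function(r) r$spec$region_id,
                             character(1L))
  }
  n_sample <- sampling$cohort_size + sum(sampling$extremes_per_trait)
  for (rg in regions) {
    if (nrow(rg$dosages) != n_sample) {
      stop("region ", rg$spec$region_id, " has genotypes for ",
           nrow(rg$dosages), " individuals but the design samples ", n_sample)
    }
  }
  Z <- check_covariates(Z, n_sample)
  Q <- z_basis(Z)
  k <- ncol(Z)
  set.seed(grid$seed)
  preps <- lapply(regions, prepare_region_methods, Q = Q, k = k,
                  methods = grid$methods, xi = xi, skat_a = skat_a)
  gcs <- if (!is.null(models)) {
    mapply(function(rg, m) genetic_component(rg, m), regions, models,
           SIMPLIFY = FALSE)
  }
  sampling_inner <- sampling
  sampling_inner$seed <- NULL             # draws come from the master stream
  if (mode == "permute") {
    base_traits <- generate_traits(n_population, sign_matrix, df)
    base_y <- base_traits[sample_case_cohort(base_traits,
                                             sampling_inner)$index, trait]
  }
  n_regions <- length(regions)
  n_methods <- length(grid$methods)
  R <- grid$n_replicates
  pmat <- matrix(NA_real_, R, n_regions * n_methods)
  r2mat <- if (!is.null(models)) matrix(NA_real_, R, n_regions)
  for (rep_i in seq_len(R)) {
    y0 <- if (mode == "permute") {
      base_y[sample.int(n_sample)]
    } else {
      traits <- generate_traits(n_population, sign_matrix, df)
      y_sel <- traits[sample_case_cohort(traits, sampling_inner)$index, trait]
      # random assignment of the selected phenotypes to the genotype rows:
      # the sampler returns extremes in rank order, and without this shuffle
      # the largest trait values would hit the same genotype rows in every
      # replicate, silently breaking the independence null
      y_sel[sample.int(n_sample)]
    }
    for (g in seq_len(n_regions)) {
      y <- if (is.null(models)) y0 else y0 + gcs[[g]]
      r <- project_out(Q, y)
      pmat[rep_i, ((g - 1L) * n_methods + 1L):(g * n_methods)] <-
        run_prepared(preps[[g]], r, Q, n_perm)[grid$methods]
      if (!is.null(models)) {
        r2mat[rep_i, g] <- stats::var(gcs[[g]]) / stats::var(y)
      }
    }
  }
  # long format: replicate varies slowest, then region, then method --
  # matching the column layout of pmat row by row
  long <- expand.grid(method = grid$methods, region = seq_len(n_regions),
                      replicate = seq_len(R), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(replicate = long$replicate,
                    region_id = names(regions)[long$region],
                    method = long$method,
                    p_value = as.vector(t(pmat)),
                    stringsAsFactors = FALSE)
  if (!is.null(models)) {
    out$r_squared <- rep(as.vector(t(r2mat)), each = n_methods)
  }
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  out
}

#' Null-hypothesis replicate run (type I error)
#'
#' For each replicate, a fresh population of correlated traits is drawn,
#' the case-cohort sampler is re-run, and the selected individuals' trait
#' values are paired with the fixed genotype matrices — so phenotypes are
#' assigned to genotypes at random while preserving the selection-induced
#' trait structure. A cheaper `mode = "permute"` draws one phenotype vector
#' and permutes it across replicates (useful for smoke tests).
#'
#' @param grid A [replicate_grid()].
#' @param regions One `"genotype_region"` or a list of them, with genotypes
#'   for exactly the sampled individuals.
#' @param sampling A [sampling_config()]; its size determines the analysis
#'   sample.
#' @param trait Which trait column is analyzed (default 1).
#' @param sign_matrix,n_population,df Trait-generation settings (see
#'   [generate_traits()]).
#' @param mode `"redraw"` (default, full pipeline per replicate) or
#'   `"permute"`.
#' @param n_perm Permutations for the score test's permutation p-value per
#'   replicate; 0 (default) uses its asymptotic normal p-value.
#' @param Z Optional covariate matrix over the sample (intercept added when
#'   `NULL`).
#' @param xi,skat_a Weight settings passed to the score and kernel tests.
#' @return Long data frame: `replicate`, `region_id`, `method`, `p_value`
#'   (`NA` with the failure recorded when a method fails on a replicate).
#' @export
run_null_replicates <- function(grid, regions, sampling = sampling_config(),
                                trait = 1L,
                                sign_matrix = build_sign_matrix(4),
                                n_population = 12000L, df = 15,
                                mode = c("redraw", "permute"), n_perm = 0,
                                Z = NULL, xi = "ones", skat_a = c(1, 25)) {
  mode <- match.arg(mode)
  run_replicates(grid, regions, sampling, trait, sign_matrix, n_population,
                 df, mode, n_perm, Z, xi, skat_a, models = NULL)
}

#' Alternative-hypothesis replicate run (power)
#'
#' Identical to [run_null_replicates()] except that each region's fixed
#' causal model adds `sum_j beta_j G_j` to the freshly drawn null phenotype
#' before testing, and the per-replicate explained-variance ratio
#' `R^2 = var(sum beta G) / var(y_p)` is recorded.
#'
#' @inheritParams run_null_replicates
#' @param models A `"causal_model"` or list of them, parallel to `regions`.
#' @return Long data frame as in [run_null_replicates()], plus `r_squared`.
#' @export
run_power_replicates <- function(grid, regions, models,
                                 sampling = sampling_config(), trait = 1L,
                                 sign_matrix = build_sign_matrix(4),
                                 n_population = 12000L, df = 15,
                                 mode = c("redraw", "permute"), n_perm = 0,
                                 Z = NULL, xi = "ones", skat_a = c(1, 25)) {
  mode <- match.arg(mode)
  if (inherits(models, "causal_model")) models <- list(models)
  if (inherits(regions, "genotype_region")) regions <- list(regions)
  if (length(models) != length(regions)) {
    stop("'models' must supply one causal model per region")
  }
  run_replicates(grid, regions, sampling, trait, sign_matrix, n_population,
                 df, mode, n_perm, Z, xi, skat_a, models = models)
}

#' Empirical type I error with a binomial confidence interval
#'
#' Estimate = rejections / replicates with rejection at `p <= alpha`
#' (boundary included). The 95% CI uses the normal approximation to the
#' binomial by default (truncated to `[0, 1]`); `"clopper-pearson"` gives
#' the exact interval, preferable for very small counts.
#'
#' @param pvals Vector of replicate p-values.
#' @param alpha Nominal level.
#' @param n_replicates Denominator (defaults to `length(pvals)`).
#' @param ci_method `"wald"` or `"clopper-pearson"`.
#' @param conf Confidence level (default 0.95).
#' @return One-row data frame: `alpha`, `rejections`, `estimate`, `ci_low`,
#'   `ci_high`.
#' @examples
#' type1_error(runif(1000), 0.05)
#' @export
type1_error <- function(pvals, alpha, n_replicates = length(pvals),
                        ci_method = c("wald", "clopper-pearson"),
                        conf = 0.95) {
  ci_method <- match.arg(ci_method)
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  if (anyNA(pvals)) {
    warning(sum(is.na(pvals)), " missing p-value(s) dropped from the ",
            "numerator but kept in the denominator")
  }
  rej <- sum(pvals <= alpha, na.rm = TRUE)
  est <- rej / n_replicates
  if (ci_method == "wald") {
    half <- stats::qnorm(1 - (1 - conf) / 2) *
      sqrt(est * (1 - est) / n_replicates)
    lo <- max(0, est - half); hi <- min(1, est + half)
  } else {
    ci <- stats::binom.test(rej, n_replicates, conf.level = conf)$conf.int
    lo <- ci[1L]; hi <- ci[2L]
  }
  data.frame(alpha = alpha, rejections = rej, estimate = est,
             ci_low = lo, ci_high = hi)
}

#' Empirical power
#'
#' Same estimator as [type1_error()] applied under the alternative:
#' the fraction of replicates with `p <= alpha`.
#'
#' @inheritParams type1_error
#' @return Rejection fraction in `[0, 1]`.
#' @export
empirical_power <- function(pvals, alpha, n_replicates = length(pvals)) {
  sum(pvals <= alpha, na.rm = TRUE) / n_replicates
}

#' Calibration-adjusted power
#'
#' Rescales empirical power by `alpha / type1` so methods with unequal
#' empirical type I error can be compared at the same effective level.
#'
#' @param power Empirical power.
#' @param type1 Empirical type I error of the same method/region/level;
#'   must be positive.
#' @param alpha Nominal level.
#' @return `power * alpha / type1`.
#' @export
adjusted_power <- function(power, type1, alpha) {
  if (any(type1 <= 0)) {
    stop("adjusted power undefined: empirical type I error is zero; ",
         "report raw power instead")
  }
  power * alpha / type1
}

#' Summarize replicate runs into an evaluation table
#'
#' Produces one row per (method, region, alpha) with the empirical type I
#' error and its binomial CI and, when a power run is supplied, the raw and
#' calibration-adjusted power and the mean per-replicate explained
#' variance.
#'
#' @param null_pvalues Output of [run_null_replicates()] (or `NULL`).
#' @param power_pvalues Output of [run_power_replicates()] (or `NULL`).
#' @param alphas Nominal levels (default taken from the null run's grid).
#' @param ci_method Passed to [type1_error()].
#' @return Long-format data frame of class `"evaluation_summary"`.
#' @export
summarize_evaluation <- function(null_pvalues, power_pvalues = NULL,
                                 alphas = NULL, ci_method = "wald") {
  if (is.null(alphas)) {
    grid <- attr(null_pvalues %||% power_pvalues, "grid")
    alphas <- if (!is.null(grid)) grid$alphas else c(0.001, 0.01, 0.05)
  }
  has_null <- !is.null(null_pvalues) && nrow(null_pvalues) > 0
  has_power <- !is.null(power_pvalues) && nrow(power_pvalues) > 0
  src <- if (has_null) null_pvalues else power_pvalues
  cells <- unique(src[, c("region_id", "method")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    rg <- cells$region_id[i]; me <- cells$method[i]
    for (a in alphas) {
      row <- data.frame(region_id = rg, method = me, alpha = a,
                        rejections = NA_integer_, type1 = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        power = NA_real_, adjusted_power = NA_real_,
                        r_squared_mean = NA_real_)
      if (has_null) {
        pv <- null_pvalues$p_value[null_pvalues$region_id == rg &
                                     null_pvalues$method == me]
        cell <- type1_error(pv, a, n_replicates = length(pv),
                            ci_method = ci_method)
        row$rejections <- cell$rejections
        row$type1 <- cell$estimate
        row$ci_low <- cell$ci_low
        row$ci_high <- cell$ci_high
      }
      if (has_power) {
        sel <- power_pvalues$region_id == rg & power_pvalues$method == me
        pw <- empirical_power(power_pvalues$p_value[sel], a,
                              n_replicates = sum(sel))
        row$power <- pw
        if (has_null && !is.na(row$type1) && row$type1 > 0) {
          row$adjusted_power <- adjusted_power(pw, row$type1, a)
        }
        if (!is.null(power_pvalues$r_squared)) {
          row$r_squared_mean <- mean(power_pvalues$r_squared[sel])
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_summary", class(out))
  out
}

#' Plot per-region type I error with confidence intervals
#'
#' One panel per method at a chosen nominal level, with the nominal level
#' as a horizontal reference line. Requires `ggplot2`.
#'
#' @param summary An `"evaluation_summary"`.
#' @param alpha Which nominal level to display.
#' @return A ggplot object.
#' @export
plot_type1_ci <- function(summary, alpha = 0.01) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package")
  }
  d <- summary[abs(summary$alpha - alpha) < 1e-12 & !is.na(summary$type1), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region_id, y = .data$type1)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "region", y = "empirical type I error",
                  title = paste0("nominal level ", alpha)) +
    ggplot2::theme_bw()
}
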