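make_engine_fixture <- function(n_variants = 12, seed = 80) {
  sampling <- small_sampling()
  n_sample <- sampling$cohort_size + sum(sampling$extremes_per_trait)
  sp <- sample_region_spec(n_variants, maf_range = c(0.01, 0.05),
                           missing_beta = NULL, seed = seed)
  region <- simulate_genotypes(sp, n_sample, seed = seed + 1)
  list(sampling = sampling, region = region, n_sample = n_sample)
}

test_that("null engine returns a complete, reproducible p-value table", {
  fx <- make_engine_fixture()
  grid <- replicate_grid(8, methods = c("t1", "skat"), seed = 81)
  tab <- run_null_replicates(grid, fx$region, sampling = fx$sampling,
                             n_population = 2000)
  expect_equal(nrow(tab), 8 * 2)
  expect_setequal(unique(tab$method), c("t1", "skat"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_false(anyNA(tab$p_value))
  tab2 <- run_null_replicates(grid, fx$region, sampling = fx$sampling,
                              n_population = 2000)
  expect_identical(tab, tab2)
  # region size must match the design
  expect_error(run_null_replicates(grid, fx$region,
                                   sampling = sampling_config()),
               "samples")
})

test_that("null p-values are approximately uniform", {
  fx <- make_engine_fixture()
  grid <- replicate_grid(1000, methods = "t1", seed = 82)
  tab <- run_null_replicates(grid, fx$region, sampling = fx$sampling,
                             n_population = 2000, mode = "permute")
  ks <- suppressWarnings(ks.test(tab$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # redraw mode at a smaller replicate count: same behaviour
  grid2 <- replicate_grid(300, methods = "t1", seed = 83)
  tab2 <- run_null_replicates(grid2, fx$region, sampling = fx$sampling,
                              n_population = 2000)
  ks2 <- suppressWarnings(ks.test(tab2$p_value, "punif"))
  expect_gt(ks2$p.value, 0.001)
})

test_that("power engine records R^2 and reduces to the null when beta = 0", {
  fx <- make_engine_fixture()
  st <- compute_variant_stats(fx$region)
  model <- structure(list(region_id = "region_1", causal_indices = 1:6,
                          beta = assign_effect_sizes(st$maf_hat[1:6]),
                          direction_mode = "unidirectional"),
                     class = "causal_model")
  grid <- replicate_grid(40, methods = c("t1", "scoreseq"), seed = 84)
  tab <- run_power_replicates(grid, fx$region, model,
                              sampling = fx$sampling, n_population = 2000)
  expect_true("r_squared" %in% names(tab))
  expect_true(all(tab$r_squared > 0 & tab$r_squared < 1))
  gc_var <- var(ccrvsim:::genetic_component(fx$region, model))
  # denominator is the case-cohort phenotype variance (inflated by extreme
  # sampling relative to the population 75/13), so bracket rather than pin
  expect_gt(mean(tab$r_squared), gc_var / (gc_var + 30))
  expect_lt(mean(tab$r_squared), gc_var / (gc_var + 3))
  # beta = 0 is the null: p-values roughly uniform
  null_model <- model; null_model$beta <- rep(0, 6)
  grid2 <- replicate_grid(400, methods = "t1", seed = 85)
  tab0 <- run_power_replicates(grid2, fx$region, null_model,
                               sampling = fx$sampling, n_population = 2000,
                               mode = "permute")
  ks <- suppressWarnings(ks.test(tab0$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.07)
  expect_equal(unique(tab0$r_squared), 0)
})

test_that("stronger effects increase rejection rates", {
  fx <- make_engine_fixture()
  st <- compute_variant_stats(fx$region)
  beta <- assign_effect_sizes(st$maf_hat[1:6])
  weak <- structure(list(region_id = "r", causal_indices = 1:6,
                         beta = 0.5 * beta,
                         direction_mode = "unidirectional"),
                    class = "causal_model")
  strong <- weak; strong$beta <- 2 * beta
  grid <- replicate_grid(150, methods = "scoreseq", seed = 86)
  p_weak <- run_power_replicates(grid, fx$region, weak,
                                 sampling = fx$sampling,
                                 n_population = 2000)$p_value
  p_strong <- run_power_replicates(grid, fx$region, strong,
                                   sampling = fx$sampling,
                                   n_population = 2000)$p_value
  expect_gt(empirical_power(p_strong, 0.05), empirical_power(p_weak, 0.05))
})

test_that("type I error cells match the binomial arithmetic", {
  pv <- c(rep(0.005, 100), rep(0.5, 9900))
  cell <- type1_error(pv, 0.01)
  expect_equal(cell$rejections, 100L)
  expect_equal(cell$estimate, 0.01)
  expect_equal(cell$ci_low, 0.01 - 1.96 * sqrt(0.01 * 0.99 / 1e4),
               tolerance = 1e-4)
  expect_equal(cell$ci_high, 0.01 + 1.96 * sqrt(0.01 * 0.99 / 1e4),
               tolerance = 1e-4)
  # zero rejections truncate at 0
  cell0 <- type1_error(rep(0.9, 50), 0.05)
  expect_equal(cell0$estimate, 0)
  expect_equal(cell0$ci_low, 0)
  # boundary included: p == alpha rejects
  expect_equal(type1_error(c(0.05, 0.5), 0.05)$rejections, 1L)
  cp <- type1_error(pv, 0.01, ci_method = "clopper-pearson")
  expect_lt(cp$ci_low, 0.01)
  expect_gt(cp$ci_high, 0.01)
})

test_that("power estimators and the calibration adjustment", {
  expect_equal(empirical_power(rep(1e-9, 20), 0.01), 1)
  expect_equal(empirical_power(rep(0.2, 20), 0.01), 0)
  expect_equal(empirical_power(c(rep(0.001, 258), rep(0.9, 742)), 0.05),
               0.258)
  expect_equal(adjusted_power(0.20, 0.05, 0.05), 0.20)
  expect_equal(adjusted_power(0.20, 0.10, 0.05), 0.10)
  expect_error(adjusted_power(0.2, 0, 0.05), "undefined")
})

test_that("summaries aggregate cells and carry power and R^2 columns", {
  fx <- make_engine_fixture()
  st <- compute_variant_stats(fx$region)
  model <- structure(list(region_id = "region_1", causal_indices = 1:6,
                          beta = 2 * assign_effect_sizes(st$maf_hat[1:6]),
                          direction_mode = "unidirectional"),
                     class = "causal_model")
  grid <- replicate_grid(60, methods = c("t1", "skat"), seed = 87)
  null_tab <- run_null_replicates(grid, fx$region, sampling = fx$sampling,
                                  n_population = 2000, mode = "permute")
  power_tab <- run_power_replicates(grid, fx$region, model,
                                    sampling = fx$sampling,
                                    n_population = 2000, mode = "permute")
  s <- summarize_evaluation(null_tab, power_tab)
  expect_equal(nrow(s), 2 * 3)          # 2 methods x 3 alphas
  expect_true(all(s$ci_low <= s$type1 + 1e-12))
  expect_true(all(s$type1 <= s$ci_high + 1e-12))
  i <- which(s$method == "t1" & s$alpha == 0.05)
  expect_equal(s$power[i],
               empirical_power(power_tab$p_value[power_tab$method == "t1"],
                               0.05))
  sel <- power_tab$method == "t1"
  expect_equal(s$r_squared_mean[i], mean(power_tab$r_squared[sel]),
               tolerance = 1e-12)
  # null-only summary has empty power columns
  s0 <- summarize_evaluation(null_tab)
  expect_true(all(is.na(s0$power)))
  expect_false(anyNA(s0$type1))
})
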