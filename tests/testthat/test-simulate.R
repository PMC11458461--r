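test_that("simulation is deterministic given a seed", {
  cfg <- sim_config(n_features = 40, n_daf = 8, n_samples = 4,
                    n_timepoints = 3, zero_prop = 0.4, seed = 10)
  s1 <- simulate_timecourse(cfg)
  s2 <- simulate_timecourse(cfg)
  expect_identical(s1$experiment$counts, s2$experiment$counts)
  expect_identical(s1$truth$daf, s2$truth$daf)
  expect_identical(s1$truth$depth_factors, s2$truth$depth_factors)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_features = 10, n_daf = 20))
  expect_error(sim_config(zero_prop = 1))
  expect_error(sim_config(rho = 1))
  expect_error(sim_test_config(5))
  cfg2 <- sim_test_config(2)
  expect_equal(cfg2$zero_prop, 0.7)
  expect_equal(cfg2$dispersion, 500)
  cfg3 <- sim_test_config(3)
  expect_equal(cfg3$zero_prop, 0.3)
  expect_equal(cfg3$dispersion, 150)
})

test_that("the ZINB quantile map has the configured moments", {
  set.seed(12)
  u <- runif(50000)
  mu <- 50; size <- 10; pi <- 0.3
  x <- timenorm:::qzinb(u, rep(mu, length(u)), rep(size, length(u)),
                        rep(pi, length(u)))
  # mass at zero: structural plus NB zeros
  p0_total <- pi + (1 - pi) * dnbinom(0, mu = mu, size = size)
  expect_lt(abs(mean(x == 0) - p0_total), 3 * sqrt(p0_total / 5e4))
  # the non-inflated component keeps the NB mean and variance
  expect_lt(abs(mean(x) / ((1 - pi) * mu) - 1), 0.02)
  nb_var <- mu + mu^2 / size
  zinb_var <- (1 - pi) * nb_var + pi * (1 - pi) * mu^2
  expect_lt(abs(var(x) / zinb_var - 1), 0.05)
})

test_that("DAF labels and trajectories follow the design", {
  cfg <- sim_config(n_features = 120, n_daf = 30, n_samples = 4,
                    n_timepoints = 5, zero_prop = 0.3, seed = 14)
  sim <- simulate_timecourse(cfg)
  truth <- sim$truth
  expect_identical(sum(truth$daf), 30L)
  meta <- sim$experiment$sample_meta
  tm <- truth$true_means
  ctrl1 <- meta$sample_id[meta$condition == "control" & meta$timepoint == 1][1]
  for (k in c(1, 3, 5)) {
    trt <- meta$sample_id[meta$condition == "treatment" & meta$timepoint == k][1]
    ctl <- meta$sample_id[meta$condition == "control" & meta$timepoint == k][1]
    # non-DAF means are identical across conditions and constant in time
    expect_equal(tm[!truth$daf, trt], tm[!truth$daf, ctl])
    expect_equal(tm[!truth$daf, ctl], tm[!truth$daf, ctrl1])
    # DAFs ramp linearly in the treatment condition only
    mult <- 1 + (cfg$daf_max_fold - 1) * (k - 1) / (cfg$n_timepoints - 1)
    expect_equal(tm[truth$daf, trt], tm[truth$daf, ctrl1] * mult,
                 tolerance = 1e-12)
    expect_equal(tm[truth$daf, ctl], tm[truth$daf, ctrl1])
  }
})

test_that("latent temporal correlation matches the copula parameter", {
  sim <- simulate_timecourse(sim_config(n_features = 200, n_daf = 40,
                                        n_samples = 8, n_timepoints = 6,
                                        zero_prop = 0.3, rho = 0.6,
                                        seed = 15))
  Z <- sim$truth$latent$control
  lag1 <- cor(as.vector(Z[, -6]), as.vector(Z[, -1]))
  lag2 <- cor(as.vector(Z[, 1:4]), as.vector(Z[, 3:6]))
  expect_lt(abs(lag1 - 0.6), 0.02)
  expect_lt(abs(lag2 - 0.36), 0.03)  # AR1 decay

  exch <- simulate_timecourse(sim_config(n_features = 200, n_daf = 40,
                                         n_samples = 8, n_timepoints = 6,
                                         zero_prop = 0.3, rho = 0.6,
                                         corr = "exchangeable", seed = 15))
  Ze <- exch$truth$latent$control
  expect_lt(abs(cor(as.vector(Ze[, 1:4]), as.vector(Ze[, 3:6])) - 0.6), 0.02)
})

test_that("scenario B doubles the last-timepoint treatment samples", {
  base <- simulate_timecourse(sim_config(n_features = 80, n_daf = 16,
                                         n_samples = 5, n_timepoints = 4,
                                         zero_prop = 0.4, scenario = "A",
                                         seed = 16))
  withB <- simulate_timecourse(sim_config(n_features = 80, n_daf = 16,
                                          n_samples = 5, n_timepoints = 4,
                                          zero_prop = 0.4, scenario = "B",
                                          seed = 16))
  meta <- base$experiment$sample_meta
  last_trt <- meta$sample_id[meta$condition == "treatment" & meta$timepoint == 4]
  others <- setdiff(meta$sample_id, last_trt)
  expect_identical(withB$experiment$counts[, others],
                   base$experiment$counts[, others])
  expect_identical(withB$experiment$counts[, last_trt],
                   base$experiment$counts[, last_trt] * 2)
  expect_true(all(withB$truth$depth_factors[last_trt] == 2))
  expect_true(all(withB$truth$depth_factors[others] == 1))
})

test_that("scenario C halves exactly two treatment samples per timepoint", {
  sim <- simulate_timecourse(sim_config(n_features = 80, n_daf = 16,
                                        n_samples = 6, n_timepoints = 4,
                                        zero_prop = 0.4, scenario = "C",
                                        seed = 17))
  meta <- sim$experiment$sample_meta
  f <- sim$truth$depth_factors
  for (k in 1:4) {
    trt <- meta$sample_id[meta$condition == "treatment" & meta$timepoint == k]
    expect_identical(sum(f[trt] == 0.5), 2L)
    expect_identical(sum(f[trt] == 1), length(trt) - 2L)
  }
  expect_true(all(f[meta$sample_id[meta$condition == "control"]] == 1))
  expect_error(
    simulate_timecourse(sim_config(n_features = 20, n_daf = 2,
                                   n_samples = 1, n_timepoints = 2,
                                   scenario = "C", seed = 1)),
    ">= 2 treatment samples")
})

test_that("scenario D equalizes treatment sample totals", {
  sim <- simulate_timecourse(sim_config(n_features = 80, n_daf = 16,
                                        n_samples = 5, n_timepoints = 4,
                                        zero_prop = 0.4, scenario = "D",
                                        seed = 18))
  meta <- sim$experiment$sample_meta
  trt <- meta$sample_id[meta$condition == "treatment"]
  tots <- colSums(sim$experiment$counts[, trt])
  # equal up to rounding of individual cells
  expect_lt(diff(range(tots)) / mean(tots), 0.02)
  # recorded factors are exactly the pre-rounding multipliers
  base <- simulate_timecourse(sim_config(n_features = 80, n_daf = 16,
                                         n_samples = 5, n_timepoints = 4,
                                         zero_prop = 0.4, scenario = "A",
                                         seed = 18))
  f <- sim$truth$depth_factors[trt]
  tots_base <- colSums(base$experiment$counts[, trt])
  expect_equal(unname(f), unname(mean(tots_base) / tots_base),
               tolerance = 1e-12)
})

test_that("realized zero fractions track the configured proportion", {
  for (zp in c(0.3, 0.7)) {
    sim <- simulate_timecourse(sim_config(n_features = 300, n_daf = 60,
                                          n_samples = 8, n_timepoints = 4,
                                          zero_prop = zp, seed = 19))
    meta <- sim$experiment$sample_meta
    ctrl <- meta$sample_id[meta$condition == "control"]
    zf <- mean(sim$experiment$counts[!sim$truth$daf, ctrl] == 0)
    n_cells <- sum(!sim$truth$daf) * length(ctrl)
    expect_lt(abs(zf - zp), 3 * sqrt(zp * (1 - zp) / n_cells) + 0.01)
  }
})
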