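test_that("ratios divide by the divisor's per-sample sum", {
  counts <- rbind(f1 = c(4, 0, 8),
                  d1 = c(1, 3, 2),
                  d2 = c(1, 2, 2))
  colnames(counts) <- paste0("s", 1:3)
  r <- compute_ratios(counts, c("d1", "d2"))
  expect_equal(unname(r["f1", ]), c(2, 0, 2))
  # a feature divided by itself gives ratio 1 everywhere
  expect_equal(unname(compute_ratios(counts, "d1")["d1", ]), c(1, 1, 1))
  # zero divisor in one sample is an error
  bad <- counts; bad["d1", 2] <- 0
  expect_error(compute_ratios(bad, "d1"), "zero total")
})

test_that("candidate divisors are cluster intersections across groups", {
  mkfits <- function(mu) {
    data.frame(rho = 0, mu = mu, sigma2 = 1, usable = TRUE,
               row.names = sprintf("f%02d", seq_along(mu)))
  }
  two_blocks <- mkfits(rep(c(0, 5), each = 10))
  # identical block structure in both groups: two candidates of size 10
  cands <- candidate_divisor_clusters(two_blocks, two_blocks,
                                      n_clusters = 2, min_cluster_size = 3)
  expect_length(cands, 2L)
  expect_setequal(lengths(cands), c(10L, 10L))
  expect_setequal(cands[[1]], sprintf("f%02d", 1:10))

  # all features identical: a single candidate containing everything
  same <- mkfits(rep(1, 8))
  one <- candidate_divisor_clusters(same, same, n_clusters = 3,
                                    min_cluster_size = 3)
  expect_length(one, 1L)
  expect_setequal(one[[1]], sprintf("f%02d", 1:8))

  # a group-A cluster split across two B clusters survives only as pieces
  fits_a <- mkfits(rep(c(0, 5), each = 10))
  fits_b <- mkfits(c(rep(0, 5), rep(5, 5), rep(0, 10)))
  pieces <- candidate_divisor_clusters(fits_a, fits_b,
                                       n_clusters = 2, min_cluster_size = 3)
  expect_setequal(lengths(pieces), c(5L, 5L, 10L))
  sizes <- lengths(pieces)
  big <- pieces[[which(sizes == 10L)]]
  expect_setequal(big, sprintf("f%02d", 11:20))

  # unusable-everywhere input is an error
  dead <- mkfits(rep(0, 5)); dead$usable <- FALSE
  expect_error(candidate_divisor_clusters(dead, dead), "usable")
})

test_that("the likelihood-ratio test separates shifted ratio distributions", {
  # identical groups: statistic near zero, p near one
  set.seed(41)
  r <- rziln(30, 0.2, 0.5, 0.4)
  same <- ziln_lr_test(r, r)
  expect_lt(same$statistic, 1e-8)
  expect_gt(same$p_value, 0.999)

  # strongly separated log-normal groups are rejected almost always
  hits <- 0L
  for (i in 1:40) {
    a <- rlnorm(20, 0, 0.5)
    b <- rlnorm(20, 3, 0.5)
    hits <- hits + (ziln_lr_test(a, b)$p_value < 0.01)
  }
  expect_gte(hits / 40, 0.95)

  # degenerate group: p-value 1 with a flag
  deg <- ziln_lr_test(c(0, 0, 0), r)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("the null rejection rate is calibrated at the 1% level", {
  set.seed(77)
  rej <- 0L
  n_tests <- 1000L
  for (i in seq_len(n_tests)) {
    a <- rziln(100, 0.3, 1, 0.5)
    b <- rziln(100, 0.3, 1, 0.5)
    rej <- rej + (ziln_lr_test(a, b)$p_value < 0.01)
  }
  band <- 3 * sqrt(0.01 * 0.99 / n_tests)
  expect_lt(abs(rej / n_tests - 0.01), band)
})

test_that("vectorized LR p-values match the scalar test", {
  set.seed(52)
  RA <- matrix(rziln(8 * 15, 0.2, 0, 0.5), nrow = 8)
  RB <- matrix(rziln(8 * 15, 0.2, 0.5, 0.5), nrow = 8)
  rownames(RA) <- rownames(RB) <- paste0("f", 1:8)
  p <- timenorm:::ziln_lr_pvalues(RA, RB)
  for (i in 1:8) {
    expect_equal(unname(p[i]), ziln_lr_test(RA[i, ], RB[i, ])$p_value,
                 tolerance = 1e-10)
  }
})

test_that("stable-set selection minimizes the DA count and breaks ties by size", {
  set.seed(61)
  n <- 24; m <- 8
  mu <- exp(runif(n, log(30), log(120)))
  counts_a <- matrix(rpois(n * m, mu), n, m,
                     dimnames = list(sprintf("f%02d", 1:n), paste0("a", 1:m)))
  counts_b <- matrix(rpois(n * m, mu), n, m,
                     dimnames = list(sprintf("f%02d", 1:n), paste0("b", 1:m)))
  # feature f24 shifts four-fold between the groups
  counts_b["f24", ] <- counts_b["f24", ] * 4
  stable_cand <- sprintf("f%02d", 1:8)
  shifted_cand <- c("f21", "f22", "f23", "f24")
  pick <- select_stable_set(list(stable_cand, shifted_cand),
                            counts_a, counts_b, alpha = 0.05)
  expect_identical(pick$features, stable_cand)
  expect_lte(pick$n_da_at_alpha, min(pick$da_counts))

  # single candidate: returned as-is with its DA count
  single <- select_stable_set(list(stable_cand), counts_a, counts_b)
  expect_identical(single$features, stable_cand)

  # exact tie (identical groups -> zero DA calls everywhere): larger set wins
  tie <- select_stable_set(list(sprintf("f%02d", 1:3), sprintf("f%02d", 4:11)),
                           counts_a, counts_a)
  expect_length(tie$features, 8L)

  # rank = 2 returns the runner-up candidate
  second <- select_stable_set(list(stable_cand, shifted_cand),
                              counts_a, counts_b, rank = 2L)
  expect_identical(second$features, shifted_cand)
})

test_that("bridge factors are stable-set total ratios", {
  prev <- matrix(c(60, 40, 30, 70), 2,
                 dimnames = list(c("f1", "f2"), c("p1", "p2")))
  nxt <- matrix(c(120, 80, 60, 140), 2,
                dimnames = list(c("f1", "f2"), c("n1", "n2")))
  expect_equal(bridge_factor(c("f1", "f2"), prev, nxt)$delta, 2)
  expect_equal(bridge_factor(c("f1", "f2"), prev, prev)$delta, 1)
  # homogeneity: scaling the next group scales delta by the same factor
  expect_equal(bridge_factor(c("f1", "f2"), prev, nxt * 3.5)$delta, 7)
  zero_prev <- prev; zero_prev[] <- 0
  expect_error(bridge_factor(c("f1", "f2"), zero_prev, nxt), "stability")
})

test_that("a single group passes through bridge normalization unchanged", {
  exp <- make_experiment(conditions = "only", timepoints = 1,
                         samples_per_group = 5, seed = 17)
  res <- timenorm_normalize(exp, seed = 1)
  intra <- intra_time_normalize_all(exp)
  expect_equal(res$normalized, intra$normalized)
  expect_length(res$transitions, 0L)
  expect_true(all(res$factors$bridge_factor == 1))
})

test_that("an injected depth confound between timepoints is removed", {
  exp <- make_depth_chain_experiment(factors = c(1, 2), seed = 19)
  res <- timenorm_normalize(exp, seed = 19)
  meta <- exp$sample_meta
  m1 <- rowMeans(res$normalized[, meta$sample_id[meta$timepoint == 1]])
  m2 <- rowMeans(res$normalized[, meta$sample_id[meta$timepoint == 2]])
  # all features are truly stable: group means agree after bridging
  expect_lt(abs(log(sum(m2) / sum(m1))), log(1.05))
})

test_that("sequential bridging accumulates the chained scale factors", {
  exp <- make_depth_chain_experiment(factors = c(1, 2, 6), seed = 23)
  res <- timenorm_normalize(exp, seed = 23)
  deltas <- vapply(res$transitions, function(t) t$delta, 0)
  expect_equal(unname(deltas[1]), 2, tolerance = 0.1)
  # the recorded factor at t3 is cumulative (2 x 3)
  expect_equal(unname(deltas[2]), 6, tolerance = 0.1 * 6)
})

test_that("bridge normalization is reproducible for a fixed seed", {
  exp <- make_experiment(conditions = c("a", "b"), timepoints = 1:3,
                         samples_per_group = 5, seed = 29)
  r1 <- timenorm_normalize(exp, seed = 4)
  r2 <- timenorm_normalize(exp, seed = 4)
  expect_identical(r1$normalized, r2$normalized)
  expect_identical(vapply(r1$transitions, function(t) t$delta, 0),
                   vapply(r2$transitions, function(t) t$delta, 0))
  # normalized counts are reproducible from the recorded factors
  rebuilt <- sweep(exp$counts, 2L, r1$factors$combined_factor, "/")
  expect_equal(rebuilt, r1$normalized, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("rank-1 and rank-2 stable sets give close normalizations", {
  sim <- simulate_timecourse(sim_test_config(2, scenario = "D",
                                             n_features = 150, n_daf = 30,
                                             n_samples = 5, n_timepoints = 4,
                                             seed = 31))
  r1 <- timenorm_normalize(sim$experiment, seed = 31, stable_rank = 1L)
  r2 <- timenorm_normalize(sim$experiment, seed = 31, stable_rank = 2L)
  e1 <- rrmse(sim$truth$true_means, r1$normalized)
  e2 <- rrmse(sim$truth$true_means, r2$normalized)
  expect_lt(abs(e1 - e2) / e1, 0.2)
})
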