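#' Simulation configuration for time-course microbiome counts
#'
#' Defaults reproduce the study conditions of the benchmark: 500 features
#' over 6 time points, 10 samples (subjects) per condition, 100
#' differentially abundant features (DAFs), zero proportion 0.3 (low) or
#' 0.7 (high), negative binomial size `dispersion / mu` (500 = low
#' dispersion, 150 = high), and within-subject temporal correlation 0.6
#' under an AR1 (or exchangeable) Gaussian copula.
#'
#' Feature base means are drawn log-uniformly on `base_mean_range`.  DAFs
#' follow a linear multiplicative trend in the treatment condition,
#' reaching `daf_max_fold` times baseline at the last time point; all other
#' feature/condition means are constant over time.  Zero probabilities are
#' abundance-dependent: feature `i` has total zero probability
#' `plogis(zero_decay * (a - log mu_i))` with `a` calibrated so that the
#' average over features equals `zero_prop` -- abundant features are nearly
#' always observed while rare ones are mostly zero, as in real 16S data
#' (a single common zero probability would leave no feature present in all
#' samples of a group, and no normalization relying on shared features
#' could run).  The default slope makes presence/absence close to bimodal:
#' dominant taxa are observed in essentially every sample while rare taxa
#' are mostly absent, which is the pattern bridge normalization's
#' everywhere-present divisor features rely on.
#'
#' @param n_features,n_daf,n_samples,n_timepoints design dimensions
#'   (`n_samples` is per condition).
#' @param zero_prop target mean zero proportion in `[0, 1)`.
#' @param dispersion NB size numerator: all features share the size
#'   parameter `dispersion / mean(mu)`, where `mean(mu)` is the average
#'   feature mean in the control condition (500 gives mild, 150 strong
#'   overdispersion at the default base-mean range).
#' @param corr `"ar1"` or `"exchangeable"` latent correlation.
#' @param rho latent correlation parameter in `(-1, 1)`.
#' @param scenario `"A"` (none), `"B"` (treatment counts doubled at the
#'   last time point), `"C"` (two random treatment samples halved per time
#'   point), `"D"` (treatment sample totals equalized per time point).
#' @param daf_max_fold fold change reached by DAFs at the last time point.
#' @param base_mean_range range of the log-uniform base mean distribution.
#' @param zero_decay slope of the abundance/zero-probability curve.
#' @param seed integer seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_features = 500L, n_daf = 100L, n_samples = 10L,
                       n_timepoints = 6L, zero_prop = 0.7,
                       dispersion = 500, corr = c("ar1", "exchangeable"),
                       rho = 0.6, scenario = c("A", "B", "C", "D"),
                       daf_max_fold = 3, base_mean_range = c(5, 500),
                       zero_decay = 4, seed = 1L) {
  corr <- match.arg(corr)
  scenario <- match.arg(scenario)
  stopifnot(n_daf <= n_features, n_features >= 1L, n_samples >= 1L,
            n_timepoints >= 1L, zero_prop >= 0, zero_prop < 1,
            rho > -1, rho < 1, dispersion > 0, daf_max_fold >= 1,
            length(base_mean_range) == 2L, all(base_mean_range > 0))
  structure(list(n_features = as.integer(n_features),
                 n_daf = as.integer(n_daf),
                 n_samples = as.integer(n_samples),
                 n_timepoints = as.integer(n_timepoints),
                 zero_prop = zero_prop, dispersion = dispersion,
                 corr = corr, rho = rho, scenario = scenario,
                 daf_max_fold = daf_max_fold,
                 base_mean_range = base_mean_range,
                 zero_decay = zero_decay, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Shortcut for the four zero-proportion/dispersion test settings
#'
#' Test 1: zero proportion 0.3, size `500/mu`; Test 2: 0.7, `500/mu`;
#' Test 3: 0.3, `150/mu`; Test 4: 0.7, `150/mu`.
#'
#' @param test integer 1-4.
#' @param ... further arguments to [sim_config()].
#' @return A `SimConfig`.
#' @export
sim_test_config <- function(test, ...) {
  stopifnot(test %in% 1:4)
  zp <- c(0.3, 0.7, 0.3, 0.7)[test]
  disp <- c(500, 500, 150, 150)[test]
  sim_config(zero_prop = zp, dispersion = disp, ...)
}

# Zero-inflated negative binomial quantile function: u below pi maps to 0,
# the rest is pushed through the NB quantile.  Used as the copula margin.
qzinb <- function(u, mu, size, pi) {
  out <- numeric(length(u))
  pos <- u > pi
  if (any(pos)) {
    out[pos] <- stats::qnbinom((u[pos] - pi[pos]) / (1 - pi[pos]),
                               mu = mu[pos], size = size[pos])
  }
  out
}

# Calibrate the intercept of the abundance-dependent zero curve so that
# the mean total zero probability over features equals the target.
calibrate_zero_curve <- function(log_mu, target, slope) {
  if (target <= 0) return(-Inf)
  f <- function(a) mean(stats::plogis(slope * (a - log_mu))) - target
  stats::uniroot(f, lower = min(log_mu) - 50, upper = max(log_mu) + 50,
                 tol = 1e-10)$root
}

#' Simulate a two-condition time-course microbiome experiment
#'
#' Draws zero-inflated negative binomial counts whose within-subject
#' temporal dependence comes from a Gaussian copula: each feature-subject
#' pair receives one latent Gaussian vector over the time points with the
#' configured correlation structure, which is mapped through the standard
#' normal CDF and the ZINB quantile function.  Zero inflation lives inside
#' the quantile map, so zeros are temporally correlated too.  Features are
#' independent of each other.
#'
#' The structural zero probability of each cell is back-solved from the
#' feature's target total zero probability and the NB's own mass at zero,
#' so the realized zero fraction matches the configured `zero_prop` on
#' average.  DAFs ramp up linearly in the treatment condition; scenario
#' depth manipulations are applied afterwards via [apply_scenario()].
#'
#' @param config a [sim_config()].
#' @return list (class `TimeCourseSimulation`) with `experiment` (a
#'   [TimeCourseExperiment()]; conditions `"treatment"`, `"control"`) and
#'   `truth` (class `SimTruth`): `true_means` (NB-component mean per
#'   feature and sample), `daf` (named logical), `depth_factors` (named
#'   per-sample multipliers injected by the scenario), `latent` (list of
#'   per-condition latent Gaussian matrices, feature-subject rows by time
#'   columns), `pi_target` (per-feature total zero probability) and the
#'   `config` echo.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n_features; m <- config$n_samples; K <- config$n_timepoints
  conditions <- c("treatment", "control")

  mu_base <- exp(stats::runif(n, log(config$base_mean_range[1L]),
                              log(config$base_mean_range[2L])))
  names(mu_base) <- sprintf("otu%04d", seq_len(n))
  # one NB size for all features: dispersion numerator over the average
  # feature mean in the control condition
  size <- rep(config$dispersion / mean(mu_base), n)

  daf <- stats::setNames(rep(FALSE, n), names(mu_base))
  daf[sample.int(n, config$n_daf)] <- TRUE

  trend <- if (K > 1) {
    1 + (config$daf_max_fold - 1) * (seq_len(K) - 1) / (K - 1)
  } else {
    1
  }
  # M[i, k, l]: NB mean for feature i at time k under condition l
  M <- array(mu_base, dim = c(n, K, 2L))
  for (k in seq_len(K)) M[daf, k, 1L] <- mu_base[daf] * trend[k]

  log_mu <- log(mu_base)
  pi_target <- if (config$zero_prop > 0) {
    a <- calibrate_zero_curve(log_mu, config$zero_prop, config$zero_decay)
    stats::plogis(config$zero_decay * (a - log_mu))
  } else {
    rep(0, n)
  }

  Sigma <- if (config$corr == "ar1") {
    config$rho^abs(outer(seq_len(K), seq_len(K), "-"))
  } else {
    matrix(config$rho, K, K) + diag(1 - config$rho, K)
  }
  Rchol <- chol(Sigma)

  counts <- matrix(0, n, 2L * m * K)
  ids <- character(2L * m * K)
  meta_rows <- vector("list", 2L * m * K)
  true_means <- matrix(0, n, 2L * m * K)
  latent <- list()
  col <- 0L
  for (l in 1:2) {
    Z <- matrix(stats::rnorm(n * m * K), n * m, K) %*% Rchol
    latent[[conditions[l]]] <- Z
    U <- stats::pnorm(Z)
    for (k in seq_len(K)) {
      p0 <- stats::dnbinom(0, size = size, mu = M[, k, l])
      pi_star <- pmax(0, (pi_target - p0) / (1 - p0))
      for (j in seq_len(m)) {
        col <- col + 1L
        u <- U[(j - 1L) * n + seq_len(n), k]
        counts[, col] <- qzinb(u, mu = M[, k, l], size = size, pi = pi_star)
        ids[col] <- sprintf("%s_s%02d_t%02d", conditions[l], j, k)
        meta_rows[[col]] <- data.frame(
          sample_id = ids[col],
          subject_id = sprintf("%s_s%02d", conditions[l], j),
          condition = conditions[l], timepoint = k,
          stringsAsFactors = FALSE)
        true_means[, col] <- M[, k, l]
      }
    }
  }
  dimnames(counts) <- list(names(mu_base), ids)
  dimnames(true_means) <- dimnames(counts)
  meta <- do.call(rbind, meta_rows)
  meta$condition <- factor(meta$condition, levels = conditions)

  exp <- TimeCourseExperiment(counts, meta)
  truth <- structure(list(
    true_means = true_means,
    daf = daf,
    depth_factors = stats::setNames(rep(1, length(ids)), ids),
    latent = latent,
    pi_target = stats::setNames(pi_target, names(mu_base)),
    config = config), class = "SimTruth")
  sim <- structure(list(experiment = exp, truth = truth),
                   class = "TimeCourseSimulation")
  if (config$scenario != "A") {
    sim <- apply_scenario(sim$experiment, sim$truth, config$scenario)
  }
  sim
}

#' Inject a depth-confound scenario into simulated data
#'
#' Scenario `"A"` is the identity.  `"B"` doubles every treatment sample at
#' the last time point.  `"C"` halves two randomly selected treatment
#' samples at every time point (seeded through the caller's RNG state).
#' `"D"` rescales every treatment sample so that the per-sample totals are
#' equal at every time point (to the grand mean of the treatment totals),
#' removing the depth trend that the DAF ramp would otherwise leave in the
#' library sizes.  Scaled counts are rounded half-to-even to stay integral;
#' the recorded `depth_factors` are the exact pre-rounding multipliers.
#'
#' @param experiment a [TimeCourseExperiment()] from [simulate_timecourse()].
#' @param truth the matching `SimTruth`.
#' @param scenario one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return An updated `TimeCourseSimulation` list.
#' @export
apply_scenario <- function(experiment, truth, scenario = c("A", "B", "C", "D")) {
  scenario <- match.arg(scenario)
  counts <- experiment$counts
  meta <- experiment$sample_meta
  factors <- truth$depth_factors
  treat <- as.character(meta$condition) == "treatment"
  K <- max(meta$timepoint)
  if (scenario == "B") {
    sel <- meta$sample_id[treat & meta$timepoint == K]
    counts[, sel] <- counts[, sel] * 2
    factors[sel] <- factors[sel] * 2
  } else if (scenario == "C") {
    for (k in seq_len(K)) {
      pool <- meta$sample_id[treat & meta$timepoint == k]
      if (length(pool) < 2L) {
        stop("scenario C needs >= 2 treatment samples per time point",
             call. = FALSE)
      }
      sel <- sample(pool, 2L)
      counts[, sel] <- round(counts[, sel] * 0.5)
      factors[sel] <- factors[sel] * 0.5
    }
  } else if (scenario == "D") {
    sel <- meta$sample_id[treat]
    tot <- colSums(counts[, sel, drop = FALSE])
    target <- mean(tot)
    f <- target / tot
    counts[, sel] <- round(sweep(counts[, sel, drop = FALSE], 2L, f, "*"))
    factors[sel] <- factors[sel] * f
  }
  exp2 <- TimeCourseExperiment(counts, data.frame(
    sample_id = meta$sample_id, subject_id = meta$subject_id,
    condition = meta$condition, timepoint = meta$timepoint_label,
    stringsAsFactors = FALSE))
  truth$depth_factors <- factors
  structure(list(experiment = exp2, truth = truth),
            class = "TimeCourseSimulation")
}
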