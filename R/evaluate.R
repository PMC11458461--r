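#' Root of relative mean square error against simulation truth
#'
#' `RRMSE = sqrt( mean over all cells of ((est - mu) / mu)^2 )`, the mean
#' running over every feature, sample, condition and time point (i.e. every
#' cell of the feature-by-sample matrix).  Scaling normalizations only
#' define relative abundances, while the truth is on an absolute scale, so
#' by default the estimate is first rescaled by a single global constant
#' (the geometric mean of `est / mu` over cells where both are positive);
#' without this alignment the formula is not scale-invariant and would
#' measure each method's centring convention instead of its quality.
#'
#' @param truth matrix of true mean abundances (all positive), or a
#'   `SimTruth` object.
#' @param estimate normalized matrix with the same dimnames.
#' @param align rescale the estimate by the global log-scale constant
#'   before computing the error (default `TRUE`).
#' @return non-negative scalar.
#' @examples
#' mu <- matrix(c(10, 20, 30, 40), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' rrmse(mu, mu)            # 0
#' rrmse(mu, 1.5 * mu, align = FALSE)  # 0.5
#' @export
rrmse <- function(truth, estimate, align = TRUE) {
  if (inherits(truth, "SimTruth")) truth <- truth$true_means
  truth <- as.matrix(truth)
  estimate <- as.matrix(estimate)
  if (!identical(dim(truth), dim(estimate))) {
    stop("truth and estimate shapes differ", call. = FALSE)
  }
  if (!is.null(dimnames(truth)) && !is.null(dimnames(estimate)) &&
      !identical(dimnames(truth), dimnames(estimate))) {
    stop("truth and estimate dimnames differ", call. = FALSE)
  }
  if (any(truth <= 0)) stop("true means must be positive", call. = FALSE)
  if (align) {
    pos <- estimate > 0
    if (!any(pos)) stop("estimate is identically zero", call. = FALSE)
    estimate <- estimate / exp(mean(log(estimate[pos] / truth[pos])))
  }
  sqrt(mean(((estimate - truth) / truth)^2))
}

#' Permutation spline test for differential abundance over time
#'
#' A generic spline-based two-condition test for time-course data, used to
#' compare normalizations downstream.  Per feature, each condition's mean
#' trajectory is fitted by least squares on a natural cubic spline basis
#' over the time points, and the statistic is the integrated squared
#' difference between the two fitted trajectories.  The null distribution
#' comes from permuting the subjects' condition labels (subjects keep their
#' whole trajectory), and p-values are Benjamini-Hochberg adjusted across
#' features.  The design must be balanced over time within subject.
#'
#' @param normalized feature-by-sample matrix (e.g.
#'   `NormalizationResult$normalized`), or a `NormalizationResult`.
#' @param meta sample metadata (`sample_meta` of the experiment): needs
#'   `sample_id`, `subject_id`, `condition` (exactly 2 levels present,
#'   >= 3 subjects each), `timepoint` (>= 2 levels).
#' @param n_permutations number of label permutations.
#' @param spline_df degrees of freedom of the natural spline basis (capped
#'   at `timepoints - 1`).
#' @param n_grid number of grid points for the integral.
#' @param alpha significance level applied to the adjusted p-values.
#' @param seed integer seed for the permutations.
#' @return data.frame with one row per feature: `feature_id`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`, and the detected interval
#'   (`interval_start`, `interval_end`: the time range over which the
#'   fitted squared difference exceeds half its maximum; `NA` for
#'   non-significant features).
#' @export
da_spline_test <- function(normalized, meta, n_permutations = 999L,
                           spline_df = 4L, n_grid = 101L, alpha = 0.05,
                           seed = NULL) {
  if (inherits(normalized, "NormalizationResult")) {
    normalized <- normalized$normalized
  }
  if (!is.null(seed)) set.seed(seed)
  meta <- as.data.frame(meta)
  conds <- unique(as.character(meta$condition))
  if (length(conds) != 2L) {
    stop("the test needs exactly 2 conditions", call. = FALSE)
  }
  tps <- sort(unique(meta$timepoint))
  K <- length(tps)
  if (K < 2L) stop("the test needs >= 2 time points", call. = FALSE)

  subjects <- unique(meta[, c("subject_id", "condition")])
  subj_cond <- stats::setNames(as.character(subjects$condition),
                               subjects$subject_id)
  n_per <- table(factor(subj_cond, levels = conds))
  if (any(n_per < 3L)) {
    stop("the permutation null needs >= 3 subjects per condition",
         call. = FALSE)
  }
  subj_ids <- names(subj_cond)
  n_subj <- length(subj_ids)
  n_feat <- nrow(normalized)

  # per-subject time profiles, features x (subject x time); replicate
  # samples of a subject at one time point are averaged
  prof <- array(NA_real_, dim = c(n_feat, n_subj, K),
                dimnames = list(rownames(normalized), subj_ids, NULL))
  for (s in seq_len(n_subj)) {
    for (k in seq_len(K)) {
      sel <- meta$sample_id[meta$subject_id == subj_ids[s] &
                              meta$timepoint == tps[k]]
      if (length(sel) == 0L) {
        stop("unbalanced design: subject ", subj_ids[s],
             " missing time point ", tps[k], call. = FALSE)
      }
      prof[, s, k] <- rowMeans(normalized[, sel, drop = FALSE])
    }
  }
  # flatten to features x subjects blocks for fast permutation averaging
  prof_flat <- matrix(aperm(prof, c(1L, 3L, 2L)), n_feat * K, n_subj)

  df <- min(spline_df, K - 1L)
  X <- cbind(1, splines::ns(tps, df = df))
  grid <- seq(min(tps), max(tps), length.out = n_grid)
  Xg <- cbind(1, stats::predict(splines::ns(tps, df = df), grid))
  smoother <- Xg %*% solve(crossprod(X), t(X))   # n_grid x K
  dt <- (max(tps) - min(tps)) / (n_grid - 1L)

  stat_for <- function(assign) {
    m1 <- rowMeans(prof_flat[, assign == conds[1L], drop = FALSE])
    m2 <- rowMeans(prof_flat[, assign == conds[2L], drop = FALSE])
    d <- matrix(m1 - m2, n_feat, K)           # mean profile difference
    g <- d %*% t(smoother)                    # features x n_grid
    list(stat = rowSums(g^2) * dt, curves = g)
  }

  obs <- stat_for(unname(subj_cond))
  exceed <- rep(1L, n_feat)
  for (b in seq_len(n_permutations)) {
    perm <- sample(unname(subj_cond))
    exceed <- exceed + (stat_for(perm)$stat >= obs$stat)
  }
  p <- exceed / (n_permutations + 1L)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj < alpha

  int_start <- int_end <- rep(NA_real_, n_feat)
  if (any(sig)) {
    sq <- obs$curves[sig, , drop = FALSE]^2
    for (r in seq_len(nrow(sq))) {
      on <- which(sq[r, ] >= max(sq[r, ]) / 2)
      i <- which(sig)[r]
      int_start[i] <- grid[min(on)]
      int_end[i] <- grid[max(on)]
    }
  }
  data.frame(feature_id = rownames(normalized),
             statistic = obs$stat, p_value = p, p_adjusted = padj,
             significant = sig,
             interval_start = int_start, interval_end = int_end,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Normalize simulated data by dividing out the true injected depth
# factors; lower-bounds the RRMSE of any factor-estimating method on the
# same replication.
oracle_normalize <- function(exp, truth) {
  f <- truth$depth_factors[colnames(exp$counts)]
  normalization_result(exp,
                       normalized = sweep(exp$counts, 2L, f, "/"),
                       dss = f,
                       bridge = stats::setNames(rep(1, length(f)), names(f)),
                       method = "oracle")
}

#' Benchmark normalization methods on simulated time-course data
#'
#' For each replication: simulate a dataset from `config` (with a
#' replication-specific seed), normalize it with every requested method,
#' score the normalized matrices against the truth with [rrmse()], run the
#' permutation spline DA test, and record the post-adjustment type I error
#' (fraction of non-DAF features called significant), the power (fraction
#' of DAFs called), and ROC points obtained by sweeping the raw p-value
#' threshold.  Method `"oracle"` divides by the true injected depth
#' factors.
#'
#' @param config a [sim_config()]; its `seed` seeds replication `r` as
#'   `seed + r - 1`.
#' @param methods character vector from `"timenorm"`, `"tc"`, `"tmm"`,
#'   `"css"`, `"gmpr"`, `"oracle"`.
#' @param n_replications number of simulated datasets.
#' @param alpha significance level for type I error and power.
#' @param n_permutations permutations for [da_spline_test()].
#' @param roc_points number of threshold points per ROC curve.
#' @return list (class `BenchmarkReport`) with `summary` (per-method mean
#'   and sd of RRMSE, type I error, power), `replications` (per
#'   method x replication rows), `roc` (long data.frame of FPR/TPR
#'   points), and the `config`.
#' @export
benchmark_normalizations <- function(config,
                                     methods = c("timenorm", "tc", "tmm",
                                                 "css", "gmpr"),
                                     n_replications = 10L, alpha = 0.05,
                                     n_permutations = 199L,
                                     roc_points = 21L) {
  stopifnot(inherits(config, "SimConfig"), length(methods) >= 1L)
  known <- c("timenorm", "tc", "tmm", "css", "gmpr", "oracle")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ",
         paste(setdiff(methods, known), collapse = ", "), call. = FALSE)
  }
  rows <- list()
  roc <- list()
  thresholds <- seq(0, 1, length.out = roc_points)
  for (r in seq_len(n_replications)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    sim <- simulate_timecourse(cfg)
    exp <- sim$experiment
    truth <- sim$truth
    daf <- truth$daf[rownames(exp$counts)]
    for (method in methods) {
      res <- if (method == "oracle") {
        oracle_normalize(exp, truth)
      } else if (method == "timenorm") {
        normalize_counts(exp, "timenorm", seed = cfg$seed)
      } else {
        normalize_counts(exp, method)
      }
      err <- rrmse(truth$true_means, res$normalized)
      da <- da_spline_test(res$normalized, exp$sample_meta,
                           n_permutations = n_permutations,
                           alpha = alpha, seed = cfg$seed)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, replication = r, rrmse = err,
        type1 = mean(da$p_adjusted[!daf] < alpha),
        power = mean(da$p_adjusted[daf] < alpha),
        stringsAsFactors = FALSE)
      roc[[length(roc) + 1L]] <- data.frame(
        method = method, replication = r, threshold = thresholds,
        fpr = vapply(thresholds,
                     function(t) mean(da$p_value[!daf] <= t), 0),
        tpr = vapply(thresholds,
                     function(t) mean(da$p_value[daf] <= t), 0),
        stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows)
  agg <- function(v) {
    s <- stats::aggregate(reps[[v]], by = list(method = reps$method),
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
    out <- data.frame(method = s$method, mean = s$x[, "mean"],
                      sd = s$x[, "sd"], stringsAsFactors = FALSE)
    names(out)[2:3] <- paste0(v, c("_mean", "_sd"))
    out
  }
  summary <- Reduce(function(a, b) merge(a, b, by = "method"),
                    lapply(c("rrmse", "type1", "power"), agg))
  structure(list(summary = summary, replications = reps,
                 roc = do.call(rbind, roc), config = config,
                 alpha = alpha, n_replications = n_replications),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("BenchmarkReport:", x$n_replications, "replication(s), alpha =",
      x$alpha, "\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
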