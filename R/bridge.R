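#' Ratios of counts to a divisor feature set
#'
#' For each sample, divides every feature's count by the summed count of
#' the divisor features in that sample.  With a single divisor feature this
#' is the plain feature ratio; with a cluster of features the divisor is the
#' "combined" feature obtained by summing its members.  Zeros in the
#' numerator give ratio 0 (the zero component of the ZILN mixture); a zero
#' divisor sum in any sample is an error, because a valid divisor must be
#' observed everywhere.
#'
#' @param counts_group numeric matrix, features x samples (raw or
#'   intra-time normalized).
#' @param divisor_features character vector of feature ids.
#' @return matrix of ratios, same shape as `counts_group`.
#' @export
compute_ratios <- function(counts_group, divisor_features) {
  counts_group <- as.matrix(counts_group)
  divisor_features <- as.character(divisor_features)
  if (!all(divisor_features %in% rownames(counts_group))) {
    stop("divisor features missing from the count matrix", call. = FALSE)
  }
  div <- colSums(counts_group[divisor_features, , drop = FALSE])
  if (any(div <= 0)) {
    stop("divisor has zero total count in ", sum(div <= 0),
         " sample(s); choose a divisor observed in every sample",
         call. = FALSE)
  }
  sweep(counts_group, 2L, div, "/")
}

#' Candidate divisor clusters from two groups' ratio fits
#'
#' Features are clustered separately within each of the two groups by
#' average-linkage hierarchical clustering of the pairwise Bhattacharyya
#' distances between their fitted ratio distributions; the candidate
#' divisors are the pairwise intersections of a cluster from group A with a
#' cluster from group B, i.e. sets of features that behave homogeneously in
#' both groups.  Only features with usable fits in both groups take part;
#' intersections smaller than `min_cluster_size` are dropped.
#'
#' Each tree is cut into `n_clusters` clusters (default 2: the cut only
#' has to offer the downstream likelihood-ratio screen a few coarse
#' alternatives, and finer cuts fragment the pool into candidates too
#' small to give stable bridge factors).  A group whose distances are all
#' (numerically) zero is a single cluster.
#'
#' @param fits_a,fits_b per-feature ZILN fits for the two groups: data
#'   frames with columns `mu`, `sigma2`, `usable` and feature ids as row
#'   names (as produced internally by the bridge pipeline, or assembled by
#'   the caller).
#' @param n_clusters number of clusters per group; `NULL` for the default.
#' @param min_cluster_size minimum size of a candidate divisor.
#' @return list of character vectors of feature ids, ordered by the
#'   (A-cluster, B-cluster) index pair.
#' @export
candidate_divisor_clusters <- function(fits_a, fits_b, n_clusters = NULL,
                                       min_cluster_size = 3L) {
  common <- intersect(rownames(fits_a), rownames(fits_b))
  usable <- common[fits_a[common, "usable"] & fits_b[common, "usable"]]
  u <- length(usable)
  if (u < 2L) {
    stop("fewer than 2 features with usable ratio fits in both groups",
         call. = FALSE)
  }
  k <- if (is.null(n_clusters)) 2L else as.integer(n_clusters)
  k <- max(1L, min(k, u))
  cut_group <- function(fits) {
    d <- bhattacharyya_matrix(fits[usable, "mu"], fits[usable, "sigma2"])
    dimnames(d) <- list(usable, usable)
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    if (max(tree$height) < 1e-12) {
      stats::setNames(rep(1L, u), usable)  # exactly homogeneous group
    } else {
      stats::cutree(tree, k = k)
    }
  }
  cl_a <- cut_group(fits_a)
  cl_b <- cut_group(fits_b)
  candidates <- list()
  for (a in sort(unique(cl_a))) {
    in_a <- usable[cl_a[usable] == a]
    for (b in sort(unique(cl_b))) {
      members <- in_a[cl_b[in_a] == b]
      if (length(members) >= min_cluster_size) {
        candidates[[length(candidates) + 1L]] <- members
      }
    }
  }
  if (length(candidates) == 0L) {
    stop("no common cluster of size >= ", min_cluster_size,
         "; relax `min_cluster_size` or `n_clusters`", call. = FALSE)
  }
  candidates
}

#' Likelihood-ratio test for a shared ZILN ratio distribution
#'
#' Tests whether the ratios of one feature follow the same zero-inflated
#' log-normal distribution in two groups.  The null fits one ZILN to the
#' pooled ratios; the alternative fits each group separately; all three
#' parameters (`rho`, `mu`, `sigma2`) are free per group, so the statistic
#' `LR = 2 (l_A + l_B - l_pooled)` (floored at 0) is referred to a
#' chi-square with 3 degrees of freedom.
#'
#' Degenerate inputs (a group with every ratio zero, or fewer than two
#' nonzero ratios) cannot support the test; they return p-value 1 with
#' `degenerate = TRUE`.
#'
#' @param r_a,r_b non-negative ratio vectors, length >= 2 each.
#' @return list with `p_value`, `statistic`, `df`, `degenerate`.
#' @export
ziln_lr_test <- function(r_a, r_b) {
  fa <- fit_ziln(r_a)
  fb <- fit_ziln(r_b)
  if (!fa$usable || !fb$usable) {
    return(list(p_value = 1, statistic = NA_real_, df = 3L,
                degenerate = TRUE))
  }
  fp <- fit_ziln(c(r_a, r_b))
  lr <- max(0, 2 * (fa$loglik + fb$loglik - fp$loglik))
  list(p_value = stats::pchisq(lr, df = 3L, lower.tail = FALSE),
       statistic = lr, df = 3L, degenerate = FALSE)
}

# Vectorized per-feature LR p-values for two ratio matrices with matching
# rows.  Rows degenerate in either group get p = 1 (never counted as
# differentially abundant).
ziln_lr_pvalues <- function(ratios_a, ratios_b, sigma2_floor = 1e-6) {
  fa <- ziln_fit_matrix(ratios_a, sigma2_floor)
  fb <- ziln_fit_matrix(ratios_b, sigma2_floor)
  fp <- ziln_fit_matrix(cbind(ratios_a, ratios_b), sigma2_floor)
  lr <- pmax(0, 2 * (fa$loglik + fb$loglik - fp$loglik))
  p <- stats::pchisq(lr, df = 3L, lower.tail = FALSE)
  p[!(fa$usable & fb$usable)] <- 1
  names(p) <- rownames(ratios_a)
  p
}

#' Select the stable feature set among candidate divisors
#'
#' Each candidate divisor in turn defines ratios in both groups
#' ([compute_ratios()]), every feature is screened with the per-feature
#' likelihood-ratio test, and the candidate whose divisor yields the
#' minimum number of features called differentially abundant at level
#' `alpha` is the stable set.  Ties are broken in favour of the larger
#' candidate, then by lexicographic order of the sorted member ids.
#' `rank = 2` returns the runner-up candidate instead (sensitivity
#' variant).
#'
#' Candidates whose combined divisor is zero in some sample are skipped.
#'
#' @param candidates list of feature-id vectors
#'   ([candidate_divisor_clusters()]).
#' @param counts_a,counts_b the two groups' (intra-time normalized) count
#'   matrices with identical row names.
#' @param alpha significance level for the per-feature screen.
#' @param rank 1 for the minimum-DA candidate, 2 for the second smallest.
#' @return An object of class `StableFeatureSet`: list with `features`,
#'   `n_da_at_alpha`, `rank`, and `da_counts` (per evaluated candidate).
#' @export
select_stable_set <- function(candidates, counts_a, counts_b,
                              alpha = 0.05, rank = 1L) {
  stopifnot(length(candidates) >= 1L, rank %in% c(1L, 2L))
  evaluated <- list()
  for (cand in candidates) {
    div_a <- colSums(counts_a[cand, , drop = FALSE])
    div_b <- colSums(counts_b[cand, , drop = FALSE])
    if (any(div_a <= 0) || any(div_b <= 0)) next
    p <- ziln_lr_pvalues(sweep(counts_a, 2L, div_a, "/"),
                         sweep(counts_b, 2L, div_b, "/"))
    evaluated[[length(evaluated) + 1L]] <-
      list(features = cand, n_da = sum(p < alpha))
  }
  if (length(evaluated) == 0L) {
    stop("every candidate divisor is zero in some sample; ",
         "no stable set can be selected", call. = FALSE)
  }
  n_da <- vapply(evaluated, `[[`, 0, "n_da")
  size <- lengths(lapply(evaluated, `[[`, "features"))
  key <- vapply(evaluated,
                function(e) paste(sort(e$features), collapse = ","), "")
  ord <- order(n_da, -size, key)
  pick <- ord[min(rank, length(ord))]
  structure(list(features = evaluated[[pick]]$features,
                 n_da_at_alpha = evaluated[[pick]]$n_da,
                 rank = rank,
                 da_counts = n_da[ord]),
            class = "StableFeatureSet")
}

#' Bridge scale factor between two adjacent groups
#'
#' The scale factor carrying a later group onto an earlier, already
#' normalized one is the ratio of the stable features' grand totals:
#' `Delta = sum over stable features and samples of the next group /
#' sum over stable features and samples of the previous group`, where the
#' previous group's counts are already bridge-normalized (`c'`) and the
#' next group's are intra-time normalized (`c*`).  The next group is then
#' divided by `Delta`.
#'
#' @param stable a `StableFeatureSet` (or character vector of feature ids).
#' @param counts_prev previous group's matrix (bridge-normalized, `c'`).
#' @param counts_next next group's matrix (intra-time normalized, `c*`).
#' @return list with `delta` (positive scalar) and `features`.
#' @export
bridge_factor <- function(stable, counts_prev, counts_next) {
  features <- if (inherits(stable, "StableFeatureSet")) {
    stable$features
  } else {
    as.character(stable)
  }
  if (length(features) == 0L) stop("empty stable set", call. = FALSE)
  denom <- sum(counts_prev[features, , drop = FALSE])
  if (denom <= 0) {
    stop("stable features have zero total in the previous group; ",
         "this contradicts their stability", call. = FALSE)
  }
  num <- sum(counts_next[features, , drop = FALSE])
  if (num <= 0) {
    stop("stable features have zero total in the next group", call. = FALSE)
  }
  list(delta = num / denom, features = features)
}

# One bridge transition: select the stable set between two groups given
# their intra-time normalized matrices, then compute Delta against the
# previous group's bridge-normalized matrix.  Only features observed in
# every sample of both groups are eligible as stable-set candidates: a
# feature absent from samples cannot be stable, and clusters of mostly-zero
# features would both mask the likelihood-ratio screen (degenerate fits
# depress every candidate's DA count) and make Delta a ratio of small,
# high-variance totals.  The full feature set is still screened for
# differential abundance against each candidate divisor.
bridge_transition <- function(cstar_prev, cstar_next, cprime_prev,
                              alpha, n_clusters, min_cluster_size, rank) {
  eligible <- rownames(cstar_prev)[
    rowSums(cstar_prev == 0) == 0L & rowSums(cstar_next == 0) == 0L]
  if (length(eligible) == 0L) {
    stop("no feature has nonzero counts in all samples of both groups",
         call. = FALSE)
  }
  d0 <- sample(eligible, 1L)
  fits_a <- ziln_fit_matrix(compute_ratios(cstar_prev, d0))[eligible, ]
  fits_b <- ziln_fit_matrix(compute_ratios(cstar_next, d0))[eligible, ]
  # a fine cut of a small pool can leave every cluster intersection below
  # the size floor; coarsen the cut until a candidate divisor exists
  # (k = 1 yields the whole pool as one candidate)
  # default cut: two clusters per group.  The likelihood-ratio screen, not
  # the cut, discriminates stable from changing candidates; finer cuts
  # fragment the pool into stable sets so small that Delta becomes a
  # high-variance ratio (measured against simulation ground truth, chain
  # drift grows monotonically with the number of clusters).
  u <- sum(fits_a$usable & fits_b$usable)
  k <- if (is.null(n_clusters)) 2L else as.integer(n_clusters)
  candidates <- NULL
  while (is.null(candidates) && k >= 1L) {
    candidates <- tryCatch(
      candidate_divisor_clusters(fits_a, fits_b, k, min_cluster_size),
      error = function(e) NULL)
    if (is.null(candidates)) k <- k - 1L
  }
  if (is.null(candidates)) {
    stop("no common cluster of size >= ", min_cluster_size,
         " at any cut; too few usable features", call. = FALSE)
  }
  stable <- select_stable_set(candidates, cstar_prev, cstar_next,
                              alpha = alpha, rank = rank)
  bf <- bridge_factor(stable, cprime_prev, cstar_next)
  list(stable = stable, delta = bf$delta, initial_divisor = d0,
       n_candidates = length(candidates))
}

#' Bridge normalization across conditions and time points
#'
#' Chains the intra-time normalized groups together.  At the anchor time
#' point (the first for `direction = "forward"`, the last for
#' `"backward"`), the reference condition is held fixed and every other
#' condition is bridged onto it; then, within each condition, every
#' subsequent time point is bridged onto the previous normalized one.  Each
#' transition selects its stable feature set (random initial divisor,
#' ZILN fits, Bhattacharyya clustering, likelihood-ratio screen) on the
#' intra-time normalized counts `c*`, and the chain enters only through the
#' `Delta` denominator, which uses the already bridged counts `c'`; the
#' next group is then normalized as `c' = c* / Delta`.
#'
#' @param exp a [TimeCourseExperiment()].
#' @param intra result of [intra_time_normalize_all()] on `exp`.
#' @param alpha significance level of the stable-feature screen.
#' @param direction `"forward"` (anchor at the first time point) or
#'   `"backward"` (anchor at the last; use when conditions are comparable
#'   at the end of the series rather than the start).
#' @param reference_condition condition held fixed at the anchor time
#'   point; default is the first condition level.
#' @param n_clusters,min_cluster_size,stable_rank passed to
#'   [candidate_divisor_clusters()] and [select_stable_set()].
#' @param seed integer seed for the random initial divisor of each
#'   transition; with a fixed seed the selected stable sets and `Delta`
#'   values are reproducible.
#' @return A `NormalizationResult` (see [normalize_counts()]) whose
#'   `transitions` element logs, per transition, the stable set, the
#'   candidate DA counts and the `Delta` applied.
#' @export
bridge_normalize_all <- function(exp, intra, alpha = 0.05,
                                 direction = c("forward", "backward"),
                                 reference_condition = NULL,
                                 n_clusters = NULL, min_cluster_size = 3L,
                                 stable_rank = 1L, seed = NULL) {
  stopifnot(inherits(exp, "TimeCourseExperiment"))
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  meta <- exp$sample_meta
  conditions <- levels(meta$condition)
  conditions <- conditions[conditions %in% as.character(meta$condition)]
  if (is.null(reference_condition)) reference_condition <- conditions[1L]
  if (!reference_condition %in% conditions) {
    stop("unknown reference condition: ", reference_condition, call. = FALSE)
  }
  groups <- group_samples(exp)
  ginfo <- attr(groups, "groups")

  cstar <- intra$normalized
  cprime <- cstar
  bridge_applied <- stats::setNames(rep(1, ncol(cstar)), colnames(cstar))
  transitions <- list()

  tps_of <- function(cond) sort(ginfo$timepoint[ginfo$condition == cond])
  ids_of <- function(cond, tp) groups[[sprintf("%s@t%d", cond, tp)]]

  run_transition <- function(prev_ids, next_ids, label) {
    tr <- tryCatch(
      bridge_transition(cstar[, prev_ids, drop = FALSE],
                        cstar[, next_ids, drop = FALSE],
                        cprime[, prev_ids, drop = FALSE],
                        alpha, n_clusters, min_cluster_size, stable_rank),
      error = function(e) {
        stop("bridge transition ", label, " failed: ", conditionMessage(e),
             call. = FALSE)
      })
    cprime[, next_ids] <<- cstar[, next_ids, drop = FALSE] / tr$delta
    bridge_applied[next_ids] <<- tr$delta
    transitions[[label]] <<- list(label = label,
                                  delta = tr$delta,
                                  stable_features = tr$stable$features,
                                  n_da_at_alpha = tr$stable$n_da_at_alpha,
                                  da_counts = tr$stable$da_counts,
                                  initial_divisor = tr$initial_divisor)
  }

  # stage 1: bridge the other conditions onto the reference at the anchor
  anchor_of <- function(cond) {
    tps <- tps_of(cond)
    if (direction == "forward") tps[1L] else tps[length(tps)]
  }
  ref_anchor <- anchor_of(reference_condition)
  for (cond in setdiff(conditions, reference_condition)) {
    run_transition(ids_of(reference_condition, ref_anchor),
                   ids_of(cond, anchor_of(cond)),
                   sprintf("%s@t%d ~ %s@t%d", cond, anchor_of(cond),
                           reference_condition, ref_anchor))
  }

  # stage 2: chain adjacent time points within each condition
  for (cond in conditions) {
    tps <- tps_of(cond)
    if (direction == "backward") tps <- rev(tps)
    if (length(tps) < 2L) next
    for (s in seq_len(length(tps) - 1L)) {
      run_transition(ids_of(cond, tps[s]), ids_of(cond, tps[s + 1L]),
                     sprintf("%s: t%d -> t%d", cond, tps[s], tps[s + 1L]))
    }
  }

  normalization_result(exp, normalized = cprime,
                       dss = intra$dss, bridge = bridge_applied,
                       method = "timenorm", transitions = transitions)
}

#' TimeNorm normalization of a time-course experiment
#'
#' Runs the full two-stage pipeline: intra-time normalization of each
#' condition-by-timepoint group on its common dominant features, followed
#' by bridge normalization across conditions (at the anchor time point) and
#' adjacent time points.
#'
#' @param exp a [TimeCourseExperiment()].
#' @param alpha stable-feature screening level.
#' @param dominant_quantile abundance quantile for
#'   [dominant_features()] (0 = prevalence-only).
#' @inheritParams bridge_normalize_all
#' @return A `NormalizationResult`; see [normalize_counts()].
#' @examples
#' sim <- simulate_timecourse(sim_config(n_features = 60, n_daf = 10,
#'                                       n_samples = 5, n_timepoints = 3,
#'                                       zero_prop = 0.2, seed = 1))
#' res <- timenorm_normalize(sim$experiment, seed = 1)
#' head(res$factors)
#' @export
timenorm_normalize <- function(exp, alpha = 0.05, dominant_quantile = 0,
                               direction = c("forward", "backward"),
                               reference_condition = NULL,
                               n_clusters = NULL, min_cluster_size = 3L,
                               stable_rank = 1L, seed = NULL) {
  intra <- intra_time_normalize_all(exp, abundance_quantile = dominant_quantile)
  bridge_normalize_all(exp, intra, alpha = alpha,
                       direction = match.arg(direction),
                       reference_condition = reference_condition,
                       n_clusters = n_clusters,
                       min_cluster_size = min_cluster_size,
                       stable_rank = stable_rank, seed = seed)
}
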