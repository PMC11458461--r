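#' Select common dominant features for a sample group
#'
#' Dominant features carry the depth signal that intra-time normalization
#' relies on: they must be observed (nonzero) in every sample of a
#' condition-by-timepoint group.  Presence in all samples is mandatory; an
#' optional abundance filter additionally keeps only the features whose
#' group-mean count is at or above the given quantile of the group-mean
#' counts of the ubiquitous features (`abundance_quantile = 0` keeps the
#' prevalence-only rule).
#'
#' @param counts_group numeric matrix, features x samples, restricted to one
#'   (condition, timepoint) group with at least two samples.
#' @param abundance_quantile fraction in `[0, 1]`; quantile cut on
#'   group-mean abundance among ubiquitous features.
#' @return An object of class `DominantFeatureSet`: list with `features`
#'   (character vector), `abundance_quantile`, and `n0` (set size).
#' @export
dominant_features <- function(counts_group, abundance_quantile = 0) {
  counts_group <- as.matrix(counts_group)
  if (ncol(counts_group) < 2L) {
    stop("a group must contain at least 2 samples to be normalized",
         call. = FALSE)
  }
  if (abundance_quantile < 0 || abundance_quantile > 1) {
    stop("`abundance_quantile` must be in [0, 1]", call. = FALSE)
  }
  ubiquitous <- rownames(counts_group)[rowSums(counts_group == 0) == 0L]
  if (length(ubiquitous) == 0L) {
    stop("no feature is nonzero in all samples of the group; ",
         "intra-time normalization cannot proceed", call. = FALSE)
  }
  features <- ubiquitous
  if (abundance_quantile > 0) {
    means <- rowMeans(counts_group[ubiquitous, , drop = FALSE])
    cut <- stats::quantile(means, probs = abundance_quantile, names = FALSE)
    features <- ubiquitous[means >= cut]
    if (length(features) == 0L) {
      stop("abundance filter removed every ubiquitous feature; ",
           "lower `abundance_quantile`", call. = FALSE)
    }
  }
  structure(list(features = features,
                 abundance_quantile = abundance_quantile,
                 n0 = length(features)),
            class = "DominantFeatureSet")
}

#' Intra-time normalization of one sample group
#'
#' Scales the samples of one condition-by-timepoint group so that they are
#' comparable, using only the common dominant features to estimate each
#' sample's scale.  With `c_ij` the count of dominant feature `i` in sample
#' `j` (of `m` samples, `n0` dominant features):
#'
#' * feature proportions `p_i = sum_j c_ij / sum_i sum_j c_ij`,
#' * sample scales `s_j = sum_i c_ij p_i / n0`,
#' * scale factors `DSS_j = s_j / median(s_1, ..., s_m)` (the even-size
#'   median is the mean of the two central order statistics),
#'
#' and every count of the group -- all features, not only the dominant ones
#' -- is divided by its sample's `DSS_j`.  Zeros stay zeros; no pseudocount
#' is added.
#'
#' @param counts_group numeric matrix, features x samples, one group.
#' @param dominant a [dominant_features()] result (or a character vector of
#'   feature ids that are nonzero in every sample of the group).
#' @return list with `normalized` (matrix, same shape) and `factors`, an
#'   `IntraTimeFactors` list holding `proportions` (sums to 1 over the
#'   dominant set), `sample_scales`, and `dss` (median 1 over the group).
#' @export
intra_time_normalize <- function(counts_group, dominant) {
  counts_group <- as.matrix(counts_group)
  features <- if (inherits(dominant, "DominantFeatureSet")) {
    dominant$features
  } else {
    as.character(dominant)
  }
  if (length(features) == 0L) stop("empty dominant feature set", call. = FALSE)
  if (!all(features %in% rownames(counts_group))) {
    stop("dominant features missing from the count matrix", call. = FALSE)
  }
  sub <- counts_group[features, , drop = FALSE]
  if (any(colSums(sub) <= 0)) {
    stop("a sample has zero total count over the dominant features; ",
         "this contradicts the dominant-set definition", call. = FALSE)
  }
  n0 <- length(features)
  p_hat <- rowSums(sub) / sum(sub)
  s <- as.vector(crossprod(sub, p_hat)) / n0
  names(s) <- colnames(counts_group)
  dss <- s / stats::median(s)
  normalized <- sweep(counts_group, 2L, dss, "/")
  factors <- structure(list(proportions = p_hat,
                            sample_scales = s,
                            dss = dss),
                       class = "IntraTimeFactors")
  list(normalized = normalized, factors = factors)
}

#' Intra-time normalization of a whole experiment
#'
#' Applies [dominant_features()] and [intra_time_normalize()] independently
#' to every condition-by-timepoint group of the experiment.  Dominant sets
#' are not shared across groups.
#'
#' @param exp a [TimeCourseExperiment()].
#' @param abundance_quantile passed to [dominant_features()].
#' @return list with `normalized` (full matrix of intra-time normalized
#'   counts, `c*`), `dss` (named per-sample scale factors), and `groups`
#'   (per-group list with the dominant set and the `IntraTimeFactors`).
#' @export
intra_time_normalize_all <- function(exp, abundance_quantile = 0) {
  stopifnot(inherits(exp, "TimeCourseExperiment"))
  groups <- group_samples(exp)
  normalized <- exp$counts
  dss <- stats::setNames(rep(NA_real_, ncol(exp$counts)),
                         colnames(exp$counts))
  per_group <- list()
  for (nm in names(groups)) {
    ids <- groups[[nm]]
    if (length(ids) < 2L) {
      stop("group ", nm, " has fewer than 2 samples; intra-time ",
           "normalization is undefined", call. = FALSE)
    }
    sub <- exp$counts[, ids, drop = FALSE]
    dom <- dominant_features(sub, abundance_quantile)
    res <- intra_time_normalize(sub, dom)
    normalized[, ids] <- res$normalized
    dss[ids] <- res$factors$dss
    per_group[[nm]] <- list(dominant = dom, factors = res$factors)
  }
  list(normalized = normalized, dss = dss, groups = per_group)
}
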