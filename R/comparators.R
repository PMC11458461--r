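#' Total-count (library size) scaling factors
#'
#' Each sample's factor is its library size divided by the median library
#' size, so that the median factor is 1 and factors are on a scale
#' comparable with the other methods.
#'
#' @param counts feature-by-sample count matrix; every sample total must be
#'   positive.
#' @return An object of class `ScalingFactors`: named numeric vector of
#'   positive per-sample factors with attribute `method`.
#' @export
tc_factors <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample(s) with zero library size", call. = FALSE)
  scaling_factors(lib / stats::median(lib), "tc")
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Computes the TMM composition factor of each sample against a reference
#' (weighted mean of log-fold changes with the published default trims:
#' 30% on M-values, 5% on average log expression, precision weights),
#' combines it with the library size into an effective scale, and centres
#' the factors to geometric mean 1.  The composition factors are computed
#' by `edgeR::calcNormFactors(method = "TMM")`.
#'
#' @param counts feature-by-sample count matrix with >= 2 samples.
#' @param reference optional sample id (or column index) used as the TMM
#'   reference; default lets the upper-quartile rule pick it.
#' @return `ScalingFactors` (geometric-mean-centred effective scales).
#' @export
tmm_factors <- function(counts, reference = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample(s) with zero library size", call. = FALSE)
  ref_col <- NULL
  if (!is.null(reference)) {
    ref_col <- if (is.character(reference)) {
      match(reference, colnames(counts))
    } else {
      as.integer(reference)
    }
    if (is.na(ref_col)) stop("unknown reference sample", call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_col)
  eff <- f * lib
  scaling_factors(eff / exp(mean(log(eff))), "tmm",
                  reference = if (!is.null(ref_col)) colnames(counts)[ref_col])
}

#' Cumulative sum scaling (CSS) factors
#'
#' Each sample's factor is the sum of its counts up to a sample-specific
#' quantile of its nonzero counts, divided by the median of these partial
#' sums (the global scale constant).  The quantile is either fixed or
#' chosen adaptively: sample quantile profiles are compared against their
#' across-sample median profile, and the smallest quantile at which the
#' relative change of the median absolute deviation between consecutive
#' quantile levels exceeds `rel_threshold` is used.  If the adaptive rule
#' is undefined (e.g. all samples identical), the median quantile 0.5 is
#' used and a message is emitted.
#'
#' @param counts feature-by-sample count matrix with >= 2 samples.
#' @param quantile fixed quantile in (0, 1]; `NULL` (default) uses the
#'   adaptive rule.
#' @param rel_threshold relative-change threshold of the adaptive rule.
#' @return `ScalingFactors` with attribute `quantile` (the level used).
#' @export
css_factors <- function(counts, quantile = NULL, rel_threshold = 0.1) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("CSS needs >= 2 samples", call. = FALSE)
  if (is.null(quantile)) {
    quantile <- css_adaptive_quantile(counts, rel_threshold)
  }
  if (quantile <= 0 || quantile > 1) {
    stop("`quantile` must be in (0, 1]", call. = FALSE)
  }
  partial <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      stop("sample ", colnames(counts)[j], " has no nonzero count",
           call. = FALSE)
    }
    q <- stats::quantile(pos, probs = quantile, names = FALSE)
    sum(x[x <= q])
  }, 0)
  names(partial) <- colnames(counts)
  f <- scaling_factors(partial / stats::median(partial), "css")
  attr(f, "quantile") <- quantile
  f
}

# Adaptive CSS quantile: smallest level at which the across-sample spread
# of the quantile profiles starts changing fast relative to the previous
# level.  Falls back to the median level for degenerate inputs.
css_adaptive_quantile <- function(counts, rel_threshold = 0.1) {
  probs <- seq(0.05, 1, by = 0.01)
  qs <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    stats::quantile(x[x > 0], probs = probs, names = FALSE)
  }, numeric(length(probs)))
  ref <- apply(qs, 1L, stats::median)
  spread <- apply(abs(qs - ref), 1L, stats::median)
  if (all(spread < .Machine$double.eps)) {
    message("CSS adaptive rule degenerate (identical quantile profiles); ",
            "using fixed quantile 0.5")
    return(0.5)
  }
  prev <- spread[-length(spread)]
  relch <- abs(diff(spread)) / pmax(prev, .Machine$double.eps)
  relch[prev < .Machine$double.eps] <- 0
  hit <- which(relch > rel_threshold)
  if (length(hit) == 0L) {
    message("CSS adaptive rule found no change point; ",
            "using fixed quantile 0.5")
    return(0.5)
  }
  probs[hit[1L] + 1L]
}

#' Geometric mean of pairwise ratios (GMPR) size factors
#'
#' For each pair of samples, the count ratio is summarized by the median
#' over the features nonzero in both; a sample's size factor is the
#' geometric mean of its median ratios against all samples (the self-ratio
#' is 1, and is included -- this is what makes the factors consistent, e.g.
#' proportional samples get factors in exactly their depth ratio).  Pairs
#' sharing fewer than `min_shared` mutually nonzero features are skipped; a
#' sample with no valid pair is an error.  Factors are centred to
#' geometric mean 1.
#'
#' @param counts feature-by-sample count matrix with >= 2 samples.
#' @param min_shared minimum number of mutually nonzero features for a
#'   pair to contribute.
#' @return `ScalingFactors`.
#' @export
gmpr_factors <- function(counts, min_shared = 1L) {
  counts <- as.matrix(counts)
  m <- ncol(counts)
  if (m < 2L) stop("GMPR needs >= 2 samples", call. = FALSE)
  sf <- numeric(m)
  nz <- counts > 0
  for (j in seq_len(m)) {
    ratios <- 1  # self-ratio
    for (j2 in seq_len(m)[-j]) {
      shared <- nz[, j] & nz[, j2]
      if (sum(shared) < min_shared) next
      ratios <- c(ratios, stats::median(counts[shared, j] /
                                          counts[shared, j2]))
    }
    if (length(ratios) == 1L) {
      stop("sample ", colnames(counts)[j],
           " shares no nonzero feature with any other sample",
           call. = FALSE)
    }
    sf[j] <- exp(mean(log(ratios)))
  }
  names(sf) <- colnames(counts)
  scaling_factors(sf / exp(mean(log(sf))), "gmpr")
}

scaling_factors <- function(x, method, reference = NULL) {
  stopifnot(all(is.finite(x)), all(x > 0))
  structure(x, class = c("ScalingFactors", "numeric"),
            method = method, reference = reference)
}

#' Normalize an experiment with a chosen method
#'
#' One entry point for all normalizations in the package.  `"timenorm"`
#' runs the two-stage pipeline ([timenorm_normalize()]); the comparator
#' methods (`"tc"`, `"tmm"`, `"css"`, `"gmpr"`) compute one positive factor
#' per sample over the whole dataset (set `per_group = TRUE` to apply them
#' independently within each condition-by-timepoint group) and divide every
#' count by its sample's factor.
#'
#' @param exp a [TimeCourseExperiment()].
#' @param method normalization method.
#' @param per_group apply a comparator per condition-by-timepoint group
#'   instead of globally.
#' @param ... passed on to the method ([timenorm_normalize()] arguments, or
#'   e.g. `quantile` for CSS).
#' @return A `NormalizationResult`: list with `normalized` (matrix),
#'   `factors` (per-sample data.frame with `dss_factor`, `bridge_factor`
#'   and their product `combined_factor`; comparators record their factor
#'   in `dss_factor` with `bridge_factor` 1), `transitions` (bridge log,
#'   empty for comparators) and `method`.
#' @export
normalize_counts <- function(exp,
                             method = c("timenorm", "tc", "tmm", "css",
                                        "gmpr"),
                             per_group = FALSE, ...) {
  stopifnot(inherits(exp, "TimeCourseExperiment"))
  method <- match.arg(method)
  if (method == "timenorm") {
    return(timenorm_normalize(exp, ...))
  }
  fn <- switch(method, tc = tc_factors, tmm = tmm_factors,
               css = css_factors, gmpr = gmpr_factors)
  ids <- colnames(exp$counts)
  if (per_group) {
    f <- stats::setNames(rep(NA_real_, length(ids)), ids)
    groups <- group_samples(exp)
    for (g in groups) {
      f[g] <- fn(exp$counts[, g, drop = FALSE], ...)
    }
  } else {
    f <- stats::setNames(as.numeric(fn(exp$counts, ...)), ids)
  }
  normalization_result(exp,
                       normalized = sweep(exp$counts, 2L, f, "/"),
                       dss = f,
                       bridge = stats::setNames(rep(1, length(ids)), ids),
                       method = method)
}
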