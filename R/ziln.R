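#' Fit a zero-inflated log-normal model to a ratio vector
#'
#' Bridge normalization models count ratios `r` as a mixture of a point
#' mass at zero (probability `rho`) and a log-normal with log-scale mean
#' `mu` and variance `sigma2`.  Because the log-normal component has zero
#' mass at 0, mixture membership is observable and the maximum-likelihood
#' estimate is closed-form: `rho` is the zero fraction, `mu` and `sigma2`
#' are the mean and (divide-by-count) variance of `log(r)` over the nonzero
#' entries.  The EM iteration (`method = "em"`) is retained as an
#' alternative path and converges to the same values.
#'
#' `sigma2` is floored at `sigma2_floor` so that degenerate zero-variance
#' fits cannot break the Bhattacharyya distance or the likelihood.  A fit is
#' `usable` for clustering and testing only when `rho < 1` and at least two
#' entries are nonzero.
#'
#' @param r numeric vector of non-negative ratios, length >= 2.
#' @param method `"closed_form"` (default) or `"em"`.
#' @param sigma2_floor lower bound for the variance estimate.
#' @param tol,max_iter EM convergence controls.
#' @return An object of class `ZILNParams`: list with `rho`, `mu`,
#'   `sigma2`, `n`, `n_nonzero`, `usable`, `loglik`.
#' @examples
#' fit_ziln(c(1, exp(2)))            # rho 0, mu 1, sigma2 1
#' fit_ziln(c(0, 0.5, 1, 2, 0))      # rho 0.4
#' @export
fit_ziln <- function(r, method = c("closed_form", "em"),
                     sigma2_floor = 1e-6, tol = 1e-12, max_iter = 200L) {
  method <- match.arg(method)
  r <- as.numeric(r)
  if (length(r) < 2L) stop("need at least 2 ratios", call. = FALSE)
  if (anyNA(r) || any(r < 0)) {
    stop("ratios must be non-negative and non-missing", call. = FALSE)
  }
  if (method == "closed_form") {
    fit <- ziln_closed_form(r, sigma2_floor)
  } else {
    fit <- ziln_em(r, sigma2_floor, tol, max_iter)
  }
  structure(fit, class = "ZILNParams")
}

ziln_closed_form <- function(r, sigma2_floor) {
  n <- length(r)
  nz <- r > 0
  n_nonzero <- sum(nz)
  rho <- (n - n_nonzero) / n
  if (n_nonzero == 0L) {
    return(list(rho = 1, mu = NA_real_, sigma2 = NA_real_, n = n,
                n_nonzero = 0L, usable = FALSE, loglik = 0))
  }
  lx <- log(r[nz])
  mu <- mean(lx)
  sigma2 <- max(sum((lx - mu)^2) / n_nonzero, sigma2_floor)
  list(rho = rho, mu = mu, sigma2 = sigma2, n = n, n_nonzero = n_nonzero,
       usable = rho < 1 && n_nonzero >= 2L,
       loglik = ziln_loglik(r, rho, mu, sigma2))
}

# EM for the ZILN mixture.  The E-step responsibility of the zero
# component is 1 for r == 0 and 0 for r > 0 (the log-normal density at 0
# vanishes), so the iteration reaches the closed-form MLE immediately; the
# loop is kept as a faithful implementation of the general recipe.
ziln_em <- function(r, sigma2_floor, tol, max_iter) {
  n <- length(r)
  nz <- r > 0
  if (!any(nz)) {
    return(list(rho = 1, mu = NA_real_, sigma2 = NA_real_, n = n,
                n_nonzero = 0L, usable = FALSE, loglik = 0))
  }
  lx <- log(r[nz])
  rho <- 0.5
  mu <- mean(lx)
  sigma2 <- max(stats::var(lx) * (length(lx) - 1) / length(lx),
                sigma2_floor)
  if (!is.finite(sigma2)) sigma2 <- sigma2_floor
  for (it in seq_len(max_iter)) {
    # E-step: posterior probability that each observation is a structural
    # zero; the zero component has density d0 = 1{r == 0} and the
    # log-normal component vanishes at 0, so the posterior is an indicator.
    dens <- numeric(n)
    dens[nz] <- pmax(stats::dlnorm(r[nz], meanlog = mu,
                                   sdlog = sqrt(sigma2)),
                     .Machine$double.xmin)
    d0 <- as.numeric(r == 0)
    w_zero <- rho * d0 / (rho * d0 + (1 - rho) * dens)
    # M-step
    rho_new <- mean(w_zero)
    w_pos <- 1 - w_zero
    mu_new <- sum(w_pos[nz] * lx) / sum(w_pos[nz])
    sigma2_new <- max(sum(w_pos[nz] * (lx - mu_new)^2) / sum(w_pos[nz]),
                      sigma2_floor)
    delta <- max(abs(rho_new - rho), abs(mu_new - mu),
                 abs(sigma2_new - sigma2))
    rho <- rho_new; mu <- mu_new; sigma2 <- sigma2_new
    if (delta < tol) break
  }
  list(rho = rho, mu = mu, sigma2 = sigma2, n = n, n_nonzero = sum(nz),
       usable = rho < 1 && sum(nz) >= 2L,
       loglik = ziln_loglik(r, rho, mu, sigma2))
}

#' Log-likelihood of a ZILN parameter triple on a ratio vector
#'
#' @param r non-negative ratio vector.
#' @param rho,mu,sigma2 mixture parameters.
#' @return scalar log-likelihood.
#' @keywords internal
ziln_loglik <- function(r, rho, mu, sigma2) {
  n0 <- sum(r == 0)
  nz <- r > 0
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(rho)
  if (any(nz)) {
    ll <- ll + sum(nz) * log1p(-rho) +
      sum(stats::dlnorm(r[nz], meanlog = mu, sdlog = sqrt(sigma2),
                        log = TRUE))
  }
  ll
}

#' Draw from the zero-inflated log-normal distribution
#'
#' @param n number of draws.
#' @param rho zero probability.
#' @param mu,sigma2 log-scale mean and variance.
#' @return numeric vector of draws.
#' @export
rziln <- function(n, rho, mu, sigma2) {
  zero <- stats::runif(n) < rho
  x <- stats::rlnorm(n, meanlog = mu, sdlog = sqrt(sigma2))
  x[zero] <- 0
  x
}

# Vectorized closed-form ZILN fits, one per row of a ratio matrix.
# Returns a data.frame with one row per feature: rho, mu, sigma2,
# n_nonzero, usable, loglik.  Used on the hot path of bridge normalization.
ziln_fit_matrix <- function(R, sigma2_floor = 1e-6) {
  R <- as.matrix(R)
  n <- ncol(R)
  nz <- R > 0
  nnz <- rowSums(nz)
  n0 <- n - nnz
  rho <- n0 / n
  L <- matrix(0, nrow(R), n)
  L[nz] <- log(R[nz])
  mu <- rowSums(L) / pmax(nnz, 1L)
  ss <- rowSums((L - mu)^2 * nz)
  sigma2 <- pmax(ss / pmax(nnz, 1L), sigma2_floor)
  # log-likelihood at the (floored) MLE
  ll <- numeric(nrow(R))
  has0 <- n0 > 0
  ll[has0] <- ll[has0] + n0[has0] * log(rho[has0])
  haspos <- nnz > 0
  ll[haspos] <- ll[haspos] + nnz[haspos] * log1p(-rho[haspos]) -
    rowSums(L)[haspos] -
    nnz[haspos] / 2 * log(2 * pi * sigma2[haspos]) -
    ss[haspos] / (2 * sigma2[haspos])
  mu[!haspos] <- NA_real_
  sigma2[!haspos] <- NA_real_
  data.frame(rho = rho, mu = mu, sigma2 = sigma2,
             n_nonzero = nnz,
             usable = rho < 1 & nnz >= 2L,
             loglik = ll,
             row.names = rownames(R))
}

#' Bhattacharyya distance between two fitted ratio distributions
#'
#' Distance between the log-normal components of two ZILN fits, computed on
#' the normal distributions underlying the log scale:
#' `D = (mu1 - mu2)^2 / (4 (s1 + s2)) + log((s1 + s2) / (2 sqrt(s1 s2))) / 2`
#' with `s = sigma2`.  The zero-probability `rho` is deliberately not part
#' of the distance: similarity of features is judged on the location and
#' spread of their nonzero ratios.  Symmetric, non-negative, and zero
#' exactly when the two `(mu, sigma2)` pairs coincide.
#'
#' @param p1,p2 `ZILNParams` objects (or lists with `mu`, `sigma2`,
#'   `usable`).
#' @return non-negative scalar.
#' @examples
#' a <- fit_ziln(exp(rnorm(50)))
#' bhattacharyya_distance(a, a)  # 0
#' @export
bhattacharyya_distance <- function(p1, p2) {
  if (isFALSE(p1$usable) || isFALSE(p2$usable)) {
    stop("Bhattacharyya distance needs usable fits (rho < 1, >= 2 nonzero)",
         call. = FALSE)
  }
  ssum <- p1$sigma2 + p2$sigma2
  (p1$mu - p2$mu)^2 / (4 * ssum) +
    0.5 * log(ssum / (2 * sqrt(p1$sigma2 * p2$sigma2)))
}

# Full pairwise Bhattacharyya distance matrix from vectors of mu, sigma2.
bhattacharyya_matrix <- function(mu, sigma2) {
  ssum <- outer(sigma2, sigma2, "+")
  d <- outer(mu, mu, "-")^2 / (4 * ssum) +
    0.5 * log(ssum / (2 * sqrt(outer(sigma2, sigma2, "*"))))
  diag(d) <- 0
  d
}
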