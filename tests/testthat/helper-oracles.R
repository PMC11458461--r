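# Independent brute-force oracle for the published TMM definition:
# pairwise weighted mean of trimmed log-fold changes against a fixed
# reference, with the standard 30% M-trim, 5% A-trim and precision weights.
oracle_tmm_pair <- function(obs, ref) {
  nO <- sum(obs); nR <- sum(ref)
  keep <- obs > 0 & ref > 0
  logR <- log2((obs / nO) / (ref / nR))[keep]
  absE <- ((log2(obs / nO) + log2(ref / nR)) / 2)[keep]
  v <- ((nO - obs) / (nO * obs) + (nR - ref) / (nR * ref))[keep]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
  loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
  trim <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  2^(sum(logR[trim] / v[trim]) / sum(1 / v[trim]))
}

oracle_tmm_factors <- function(counts, ref_col) {
  f <- vapply(seq_len(ncol(counts)),
              function(j) oracle_tmm_pair(counts[, j], counts[, ref_col]), 0)
  f <- f / exp(mean(log(f)))
  eff <- f * colSums(counts)
  eff / exp(mean(log(eff)))
}

# brute-force GMPR: explicit double loop over all sample pairs, with the
# self-ratio (1) included in each sample's geometric mean
oracle_gmpr_factors <- function(counts) {
  m <- ncol(counts)
  sf <- numeric(m)
  for (j in 1:m) {
    meds <- 1
    for (j2 in setdiff(1:m, j)) {
      sh <- counts[, j] > 0 & counts[, j2] > 0
      if (!any(sh)) next
      meds <- c(meds, median(counts[sh, j] / counts[sh, j2]))
    }
    sf[j] <- exp(mean(log(meds)))
  }
  sf / exp(mean(log(sf)))
}

zero_heavy_fixture <- function(seed = 3, n = 40, m = 6) {
  set.seed(seed)
  counts <- matrix(rnbinom(n * m, mu = 20, size = 0.5), n, m,
                   dimnames = list(sprintf("f%02d", 1:n), paste0("s", 1:m)))
  counts[rowSums(counts) == 0, 1] <- 1  # keep every feature observed somewhere
  counts
}

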