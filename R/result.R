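# Internal constructor shared by timenorm and the comparator methods.
# normalized = counts / (dss * bridge) must hold to floating precision;
# the factors table makes every result reproducible from the raw counts.
normalization_result <- function(exp, normalized, dss, bridge, method,
                                 transitions = list()) {
  ids <- colnames(exp$counts)
  stopifnot(identical(colnames(normalized), ids))
  factors <- data.frame(sample_id = ids,
                        dss_factor = unname(dss[ids]),
                        bridge_factor = unname(bridge[ids]),
                        combined_factor = unname(dss[ids] * bridge[ids]),
                        stringsAsFactors = FALSE)
  structure(list(normalized = normalized,
                 factors = factors,
                 transitions = transitions,
                 method = method),
            class = "NormalizationResult")
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat("NormalizationResult (method:", x$method, ")\n")
  cat(" ", nrow(x$normalized), "features x", ncol(x$normalized),
      "samples\n")
  cat("  combined factor range: [",
      format(min(x$factors$combined_factor), digits = 4), ", ",
      format(max(x$factors$combined_factor), digits = 4), "]\n", sep = "")
  if (length(x$transitions)) {
    cat("  bridge transitions:\n")
    for (tr in x$transitions) {
      cat(sprintf("    %-28s Delta = %-10.5g |Omega| = %d (DA calls: %d)\n",
                  tr$label, tr$delta, length(tr$stable_features),
                  tr$n_da_at_alpha))
    }
  }
  invisible(x)
}

#' Write a normalization result to TSV files
#'
#' Writes the normalized feature-by-sample table (same layout as the input
#' count table) and a per-sample factors table with columns `sample_id`,
#' `dss_factor`, `cumulative_bridge_factor`, `combined_factor`.
#'
#' @param result a `NormalizationResult`.
#' @param counts_path output path for the normalized table.
#' @param factors_path output path for the factors table.
#' @param digits optional rounding for the normalized values; default
#'   writes full double precision.
#' @return `result`, invisibly.
#' @export
write_normalized <- function(result, counts_path, factors_path,
                             digits = NULL) {
  stopifnot(inherits(result, "NormalizationResult"))
  write_count_table(result$normalized, counts_path, digits = digits)
  fac <- result$factors
  out <- data.frame(sample_id = fac$sample_id,
                    dss_factor = fac$dss_factor,
                    cumulative_bridge_factor = fac$bridge_factor,
                    combined_factor = fac$combined_factor,
                    stringsAsFactors = FALSE)
  utils::write.table(out, factors_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(result)
}
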