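# Builders for small in-memory fixtures used across the suite.

toy_counts <- function() {
  matrix(c(10L, 5L,
           0L, 8L,
           3L, 7L),
         nrow = 2, ncol = 3,
         dimnames = list(c("otuA", "otuB"), c("s1", "s2", "s3")))
}

toy_meta <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             subject_id = c("m1", "m2", "m3"),
             condition = c("ctrl", "ctrl", "ctrl"),
             timepoint = c(1L, 1L, 1L),
             stringsAsFactors = FALSE)
}

# experiment with conditions x timepoints x samples-per-group and NB counts
make_experiment <- function(n_features = 30, conditions = c("a", "b"),
                            timepoints = 1:2, samples_per_group = 3,
                            mu_range = c(10, 200), size = 5, seed = 1) {
  set.seed(seed)
  mu <- exp(stats::runif(n_features, log(mu_range[1]), log(mu_range[2])))
  ids <- character(0)
  meta <- list()
  cols <- list()
  for (cond in conditions) {
    for (tp in timepoints) {
      for (j in seq_len(samples_per_group)) {
        id <- sprintf("%s_s%d_t%d", cond, j, tp)
        ids <- c(ids, id)
        meta[[id]] <- data.frame(sample_id = id,
                                 subject_id = sprintf("%s_s%d", cond, j),
                                 condition = cond, timepoint = tp,
                                 stringsAsFactors = FALSE)
        cols[[id]] <- stats::rnbinom(n_features, mu = mu, size = size)
      }
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("f%03d", seq_len(n_features))
  TimeCourseExperiment(counts, do.call(rbind, meta))
}

# one-condition experiment whose timepoint-k counts carry a known global
# depth factor on top of iid draws from the same NB model (all features
# truly stable)
make_depth_chain_experiment <- function(factors, n_features = 60,
                                        samples_per_group = 10, seed = 7) {
  set.seed(seed)
  mu <- exp(stats::runif(n_features, log(20), log(200)))
  cols <- list()
  meta <- list()
  for (tp in seq_along(factors)) {
    for (j in seq_len(samples_per_group)) {
      id <- sprintf("s%02d_t%d", j, tp)
      cols[[id]] <- round(stats::rnbinom(n_features, mu = mu, size = 5) *
                            factors[tp])
      meta[[id]] <- data.frame(sample_id = id,
                               subject_id = sprintf("sub%02d", j),
                               condition = "c", timepoint = tp,
                               stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- sprintf("f%03d", seq_len(n_features))
  TimeCourseExperiment(counts, do.call(rbind, meta))
}

# write an experiment's TSVs to a temporary directory; returns the paths
write_toy_tsvs <- function(counts = toy_counts(), meta = toy_meta()) {
  cp <- tempfile(fileext = ".tsv")
  mp <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(feature_id = rownames(counts), counts, check.names = FALSE),
    cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(counts = cp, meta = mp)
}
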