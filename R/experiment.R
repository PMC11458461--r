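#' Time-course microbiome experiment
#'
#' Bundles a feature-by-sample matrix of sequencing counts with per-sample
#' metadata (subject, condition, time point).  This is the input container
#' for every normalization in the package.
#'
#' Counts must be non-negative and integral; feature and sample identifiers
#' must be unique; every sample must carry exactly one
#' (condition, timepoint) assignment.  Timepoint labels may be arbitrary
#' (integers, week names, ...) and are mapped to ordered integer indices
#' `1..K` by sorted unique label; the mapping is kept in `timepoint_map`
#' because bridge normalization chains adjacent time points and therefore
#' needs a total order.
#'
#' @param counts numeric matrix, features as rows, samples as columns, with
#'   row and column names.  Values must be non-negative integers.
#' @param sample_meta data.frame with columns `sample_id`, `subject_id`,
#'   `condition`, `timepoint`, one row per sample.  Rows are matched to the
#'   columns of `counts` by `sample_id`; the column order of `counts` is
#'   preserved.
#'
#' @return An object of class `TimeCourseExperiment`: a list with elements
#'   `counts` (integer-valued matrix), `sample_meta` (data.frame with
#'   `condition` as a factor and `timepoint` as integer index, plus the
#'   original `timepoint_label`), and `timepoint_map` (named integer vector,
#'   label -> index).
#' @examples
#' counts <- matrix(c(10L, 5L, 0L, 8L, 3L, 7L), nrow = 2,
#'                  dimnames = list(c("otuA", "otuB"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                    subject_id = c("m1", "m2", "m3"),
#'                    condition = "control", timepoint = 1)
#' exp <- TimeCourseExperiment(counts, meta)
#' @export
TimeCourseExperiment <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate feature ids in `counts`", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids in `counts`", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral", call. = FALSE)
  }
  storage.mode(counts) <- "double"

  req <- c("sample_id", "subject_id", "condition", "timepoint")
  if (!is.data.frame(sample_meta) || !all(req %in% names(sample_meta))) {
    stop("`sample_meta` must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  sample_meta <- as.data.frame(sample_meta)
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  if (anyDuplicated(sample_meta$sample_id)) {
    stop("duplicate sample ids in `sample_meta`", call. = FALSE)
  }
  common <- intersect(colnames(counts), sample_meta$sample_id)
  if (length(common) == 0L) {
    stop("no samples in common between `counts` and `sample_meta`",
         call. = FALSE)
  }
  only_counts <- setdiff(colnames(counts), sample_meta$sample_id)
  only_meta <- setdiff(sample_meta$sample_id, colnames(counts))
  if (length(only_counts) || length(only_meta)) {
    stop("samples do not match between counts and metadata (",
         "counts-only: ", length(only_counts),
         ", metadata-only: ", length(only_meta), ")", call. = FALSE)
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  sample_meta$subject_id <- as.character(sample_meta$subject_id)
  if (!is.factor(sample_meta$condition)) {
    sample_meta$condition <- factor(sample_meta$condition,
                                    levels = unique(sample_meta$condition))
  }
  if (anyNA(sample_meta$condition) || anyNA(sample_meta$timepoint)) {
    stop("condition/timepoint assignments must be complete", call. = FALSE)
  }

  labels <- sort(unique(sample_meta$timepoint))
  timepoint_map <- stats::setNames(seq_along(labels), as.character(labels))
  sample_meta$timepoint_label <- sample_meta$timepoint
  sample_meta$timepoint <-
    unname(timepoint_map[as.character(sample_meta$timepoint)])

  structure(list(counts = counts,
                 sample_meta = sample_meta,
                 timepoint_map = timepoint_map),
            class = "TimeCourseExperiment")
}

#' @export
print.TimeCourseExperiment <- function(x, ...) {
  meta <- x$sample_meta
  cat("TimeCourseExperiment:",
      nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  conditions:", paste(levels(meta$condition), collapse = ", "), "\n")
  cat("  timepoints:", length(x$timepoint_map),
      sprintf("(%s)", paste(names(x$timepoint_map), collapse = ", ")), "\n")
  cat("  subjects:  ", length(unique(meta$subject_id)), "\n")
  invisible(x)
}

#' Read a time-course experiment from TSV files
#'
#' Reads the canonical on-disk representation: a tab-separated
#' feature-by-sample count table (first column feature id, header row of
#' sample ids) and a tab-separated metadata table with columns `sample_id`,
#' `subject_id`, `condition`, `timepoint`.  Sample column order of the
#' count table is preserved.  Any sample present in only one of the two
#' files is an error.
#'
#' @param counts_path path to the count TSV.
#' @param metadata_path path to the metadata TSV.
#' @return A validated [TimeCourseExperiment()].
#' @export
read_experiment <- function(counts_path, metadata_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("count table must have a feature-id column and >=1 sample column",
         call. = FALSE)
  }
  feature_ids <- as.character(tab[[1L]])
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- feature_ids
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  TimeCourseExperiment(counts, meta)
}

#' Write a time-course experiment to TSV files
#'
#' Inverse of [read_experiment()]; the round trip is value-identical for
#' integral counts.
#'
#' @param exp a [TimeCourseExperiment()].
#' @param counts_path,metadata_path output paths.
#' @return `exp`, invisibly.
#' @export
write_experiment <- function(exp, counts_path, metadata_path) {
  stopifnot(inherits(exp, "TimeCourseExperiment"))
  write_count_table(exp$counts, counts_path)
  meta <- exp$sample_meta
  out <- data.frame(sample_id = meta$sample_id,
                    subject_id = meta$subject_id,
                    condition = as.character(meta$condition),
                    timepoint = meta$timepoint_label,
                    stringsAsFactors = FALSE)
  utils::write.table(out, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(exp)
}

# shared TSV writer for raw and normalized tables (features x samples)
write_count_table <- function(mat, path, digits = NULL) {
  vals <- mat
  if (!is.null(digits)) vals <- round(vals, digits = digits)
  out <- data.frame(feature_id = rownames(mat),
                    as.data.frame(vals, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group samples by condition and time point
#'
#' Partitions the samples into condition-by-timepoint groups, the unit on
#' which intra-time normalization operates and between which bridge
#' normalization chains.
#'
#' @param exp a [TimeCourseExperiment()].
#' @return A named list of character vectors of sample ids, one element per
#'   non-empty (condition, timepoint) group, ordered by timepoint within
#'   condition.  Names have the form `"<condition>@t<index>"`; the
#'   attribute `"groups"` holds a data.frame with columns `name`,
#'   `condition`, `timepoint`.
#' @export
group_samples <- function(exp) {
  stopifnot(inherits(exp, "TimeCourseExperiment"))
  meta <- exp$sample_meta
  keys <- expand.grid(timepoint = sort(unique(meta$timepoint)),
                      condition = levels(meta$condition),
                      stringsAsFactors = FALSE)
  keys <- keys[, c("condition", "timepoint")]
  groups <- list()
  info <- list()
  for (r in seq_len(nrow(keys))) {
    sel <- meta$condition == keys$condition[r] &
      meta$timepoint == keys$timepoint[r]
    if (!any(sel)) next
    nm <- sprintf("%s@t%d", keys$condition[r], keys$timepoint[r])
    groups[[nm]] <- meta$sample_id[sel]
    info[[nm]] <- data.frame(name = nm, condition = keys$condition[r],
                             timepoint = keys$timepoint[r],
                             stringsAsFactors = FALSE)
  }
  attr(groups, "groups") <- do.call(rbind, c(info, list(make.row.names = FALSE)))
  groups
}
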