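#' Root-mean-squared log-intensity distance between two chips
#'
#' `sqrt(mean((log2 a - log2 b)^2))` over retained features.  Features
#' named in `exclude` (quality-control probes and probes with no
#' probeset assignment, when a layout is available) are omitted.
#' Non-positive intensities are replaced by the chip's smallest positive
#' value before the log transform.
#'
#' @param a,b Numeric vectors of linear intensities, same length and
#'   feature order.
#' @param exclude Integer indices or (if the vectors are named) feature
#'   IDs to omit.
#' @param log_base Base of the log transform (default 2).
#' @return The distance, in log units.
#' @examples
#' pairwise_rmsd(c(1, 2, 4), c(2, 4, 8))  # doubling = 1 everywhere
#' @export
pairwise_rmsd <- function(a, b, exclude = integer(), log_base = 2) {
  if (length(a) != length(b)) stop("chips must have the same length")
  keep <- rep(TRUE, length(a))
  if (length(exclude) > 0) {
    if (is.character(exclude)) {
      if (is.null(names(a))) stop("named exclusions require named vectors")
      keep[names(a) %in% exclude] <- FALSE
    } else {
      keep[exclude] <- FALSE
    }
  }
  if (!any(keep)) stop("no features retained for distance computation")
  la <- log(pseudo_positive(a)[keep], base = log_base)
  lb <- log(pseudo_positive(b)[keep], base = log_base)
  sqrt(mean((la - lb)^2))
}

# feature IDs to drop from distance computation: QC probes plus probes
# with no probeset assignment
rmsd_exclusions <- function(layout, feature_ids) {
  if (is.null(layout)) return(character())
  ps <- layout_probeset_of(layout, feature_ids)
  unique(c(layout$qc_probes, feature_ids[is.na(ps)]))
}

#' Select the median reference chip
#'
#' Computes all-vs-all root-mean-squared distances between the raw log2
#' intensity vectors of every pair of samples and returns the sample
#' with the smallest mean distance to all others.  That chip, being of
#' median brightness and minimal relative curvature, serves as the
#' common reference for pair-wise normalization.  Probeset
#' summarization can optionally be applied first, which shrinks the
#' vectors from probes to probesets.
#'
#' Ties are broken by the lexicographically smallest sample ID (with a
#' message).  Chips are streamed in pairs, so peak memory is one pair
#' of columns plus the samples-by-samples distance table.
#'
#' @param matrix A linear-scale [expression_matrix()] with >= 2 samples.
#' @param layout Optional [chip_layout()]; when given, quality-control
#'   probes and unassigned probes are excluded from the distances.
#' @param summarize_first Summarize probesets (Tukey biweight) before
#'   computing distances; requires `layout`.
#' @param config An [iron_config()] (used for the log base).
#' @return A list of class `median_chip` with elements `sample_id`,
#'   `mean_rmsd` (named vector) and `rmsd` (full symmetric matrix).
#' @export
find_median_chip <- function(matrix, layout = NULL, summarize_first = FALSE,
                             config = iron_config()) {
  assert_scale(matrix, "linear")
  config <- as_iron_config(config)
  if (ncol(matrix) < 2) stop("median chip selection needs at least 2 samples")
  if (summarize_first) {
    if (is.null(layout)) stop("summarize_first requires a layout")
    matrix <- summarize_probesets(matrix, layout)
    exclude <- character()
  } else {
    exclude <- rmsd_exclusions(layout, rownames(matrix))
  }
  ids <- colnames(matrix)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- unclass(matrix)[, i]
      b <- unclass(matrix)[, j]
      names(a) <- names(b) <- rownames(matrix)
      d[i, j] <- d[j, i] <- pairwise_rmsd(a, b, exclude = exclude,
                                          log_base = config$log_base)
    }
  }
  mean_rmsd <- rowSums(d) / (n - 1)
  best <- min(mean_rmsd)
  cands <- ids[mean_rmsd <= best]
  if (length(cands) > 1) {
    message("median chip tie between ", paste(sort(cands), collapse = ", "),
            "; choosing ", sort(cands)[1])
  }
  structure(list(sample_id = sort(cands)[1],
                 mean_rmsd = mean_rmsd,
                 rmsd = d),
            class = "median_chip")
}

#' @export
print.median_chip <- function(x, ...) {
  cat("Median reference chip:", x$sample_id, "\n")
  cat("Mean RMSD to the other chips (log2 units):\n")
  print(round(sort(x$mean_rmsd), 4))
  invisible(x)
}
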