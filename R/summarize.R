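#' One-step Tukey biweight
#'
#' Robust weighted average of log2 probe intensities that down-weights
#' values far from the median.  With `M` the median and `S` the median
#' absolute deviation from `M`, each value's standardized distance is
#' `u = (v - M) / (c*S + epsilon)`; weights are `(1 - u^2)^2` inside
#' `|u| < 1` and zero outside, and the result is the weighted mean.
#' One step only, no iteration.  When all values coincide (`S = 0`) the
#' epsilon guard keeps the weights finite and the result is the common
#' value.
#'
#' @param values Numeric vector (log2 intensities), length >= 1, all
#'   finite.
#' @param c Tuning constant (default 5).
#' @param epsilon Guard constant (default 0.0001).
#' @return The biweight location estimate.
#' @examples
#' tukey_biweight(c(1, 2, 3, 4, 100))  # outlier receives zero weight
#' @export
tukey_biweight <- function(values, c = 5, epsilon = 0.0001) {
  if (length(values) == 0) stop("cannot summarize an empty probeset")
  if (any(!is.finite(values))) stop("biweight input must be finite")
  stopifnot(c > 0, epsilon > 0)
  if (length(values) == 1) return(values)
  M <- stats::median(values)
  S <- stats::median(abs(values - M))
  u <- (values - M) / (c * S + epsilon)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(M)
  sum(w * values) / sum(w)
}

#' Summarize probes into probeset expression values
#'
#' For every probeset and every sample, the member probes' linear
#' intensities are log2-transformed, condensed with the one-step
#' [tukey_biweight()], and reported back on the linear scale
#' (`2^biweight`).  Masked probes are excluded from membership; a
#' probeset left with no usable probes is dropped with a warning.
#' Samples are summarized independently, so a probeset's value never
#' depends on which other samples are present.
#'
#' @param matrix A linear-scale [expression_matrix()] of probe
#'   intensities.
#' @param layout A [chip_layout()] assigning probes to probesets.
#' @param c,epsilon Biweight constants, see [tukey_biweight()].
#' @param log2_output Report log2 values instead of linear (default
#'   FALSE).
#' @return An [expression_matrix()] with one row per probeset.
#' @export
summarize_probesets <- function(matrix, layout, c = 5, epsilon = 0.0001,
                                log2_output = FALSE) {
  assert_scale(matrix, "linear")
  if (is.null(layout)) stop("summarization requires a layout")
  ids <- rownames(matrix)
  ps <- layout_probeset_of(layout, ids)
  usable <- !is.na(ps) & !(ids %in% layout$masked)
  dropped_sets <- setdiff(unique(ps[!is.na(ps)]), unique(ps[usable]))
  if (length(dropped_sets) > 0) {
    warning("probeset(s) with no unmasked probes dropped: ",
            paste(utils::head(dropped_sets, 5), collapse = ", "))
  }
  if (!any(usable)) stop("no probes available for summarization")
  groups <- split(which(usable), ps[usable])
  vals <- apply(unclass(matrix), 2L, pseudo_positive)
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(matrix))
  dimnames(vals) <- dimnames(matrix)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(vals),
                dimnames = list(names(groups), colnames(vals)))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    block <- log2(vals[rows, , drop = FALSE])
    out[g, ] <- apply(block, 2L, tukey_biweight, c = c, epsilon = epsilon)
  }
  if (log2_output) {
    expression_matrix(out, scale = "log2")
  } else {
    expression_matrix(2^out, scale = "linear")
  }
}
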