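#' Construct an expression matrix
#'
#' A features-by-samples grid of intensities with a scale tag recording
#' whether values are linear fluorescence units or log2 units.  Linear
#' values must be non-negative and finite; feature and sample
#' identifiers must be unique.
#'
#' @param values Numeric matrix, features in rows, samples in columns,
#'   with rownames (feature IDs) and colnames (sample IDs).
#' @param scale Either `"linear"` or `"log2"`.
#' @return A matrix of class `expr_matrix` carrying a `scale` attribute.
#' @examples
#' m <- expression_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("p", 1:3), c("a", "b"))))
#' exm_scale(m)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must carry feature (row) and sample (column) names")
  }
  validate_ids(rownames(values), "feature")
  validate_ids(colnames(values), "sample")
  if (any(!is.finite(values))) {
    stop("expression matrix contains non-finite values")
  }
  if (scale == "linear" && any(values < 0)) {
    stop("linear-scale intensities must be non-negative")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

validate_ids <- function(ids, what) {
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("empty or missing ", what, " identifier")
  }
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicated ", what, " identifier(s): ",
         paste(utils::head(dups, 5), collapse = ", "))
  }
  invisible(ids)
}

#' Scale tag of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return `"linear"` or `"log2"`.
#' @export
exm_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "linear" else sc
}

assert_scale <- function(x, expected) {
  if (!identical(exm_scale(x), expected)) {
    stop("expected a ", expected, "-scale matrix but got ", exm_scale(x))
  }
  invisible(x)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x), exm_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "scale") <- attr(x, "scale")
    class(out) <- class(x)
  }
  out
}

#' Read a tab-delimited intensity matrix
#'
#' The first row holds sample IDs, the first column feature IDs, the
#' body is numeric.  UTF-8, Unix or Windows line endings.
#'
#' @param path Path to the file.
#' @param expect Declared scale of the stored values (`"linear"` or
#'   `"log2"`); linear input is checked for negative values.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, expect = c("linear", "log2")) {
  expect <- match.arg(expect)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("matrix file needs a header row and at least one feature row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  sample_ids <- header[-1]
  if (length(sample_ids) == 0) stop("matrix file has no sample columns")
  ncols <- length(header)
  widths <- vapply(fields[-1], length, 1L)
  if (any(widths != ncols)) {
    i <- which(widths != ncols)[1]
    stop("ragged row at line ", i + 1L, ": expected ", ncols,
         " fields, got ", widths[i])
  }
  feature_ids <- vapply(fields[-1], `[[`, "", 1L)
  body <- vapply(fields[-1], function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }, numeric(ncols - 1L))
  # vapply returns samples x features when ncols-1 > 1; orient features x samples
  values <- if (is.matrix(body)) t(body) else matrix(body, ncol = ncols - 1L)
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing value at feature '", feature_ids[idx[1]],
         "', sample '", sample_ids[idx[2]], "'")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  expression_matrix(values, scale = expect)
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_matrix()]: `read_matrix(write_matrix(m))` recovers
#' `m` to the stated precision.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @param precision Significant digits used for serialization
#'   (default 10).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(matrix, path, precision = 10L) {
  if (!inherits(matrix, "expr_matrix")) {
    matrix <- expression_matrix(matrix)
  }
  if (ncol(matrix) == 0) stop("cannot write a matrix with no samples")
  if (nrow(matrix) == 0) stop("cannot write a matrix with no features")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(matrix)), collapse = "\t"), con)
  body <- formatC(unclass(matrix), digits = as.integer(precision),
                  format = "g", width = 1)
  lines <- paste(rownames(matrix),
                 apply(body, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

# Replace non-positive entries by the smallest positive value of the
# vector so the log transform is defined everywhere on the chip.
pseudo_positive <- function(v) {
  pos <- v > 0
  if (!any(pos)) stop("chip has no positive intensities")
  if (all(pos)) return(v)
  v[!pos] <- min(v[pos])
  v
}
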