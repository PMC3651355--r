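#' Candidate training-set selection
#'
#' Picks the features eligible to train the normalization curve.
#' Excluded are: probes with no probeset assignment, masked probes
#' (both only when a layout is supplied), every feature whose intensity
#' equals the chip minimum on either chip, every feature whose
#' intensity equals the chip maximum on either chip, and features
#' saturated (above `saturation_threshold`) on either chip.  Saturation
#' is judged on the raw intensities when `raw_sample`/`raw_reference`
#' are given (e.g. after background subtraction), otherwise on the
#' supplied vectors.
#'
#' @param sample,reference Aligned numeric vectors of linear
#'   intensities.
#' @param layout Optional [chip_layout()]; requires named vectors.
#' @param config An [iron_config()].
#' @param raw_sample,raw_reference Optional pre-correction intensities
#'   used for the saturation test.
#' @return Integer vector of candidate indices.
#' @export
build_training_set <- function(sample, reference, layout = NULL,
                               config = iron_config(),
                               raw_sample = NULL, raw_reference = NULL) {
  config <- as_iron_config(config)
  if (length(sample) != length(reference)) stop("vectors must be aligned")
  keep <- rep(TRUE, length(sample))
  if (!is.null(layout)) {
    ids <- names(sample)
    if (is.null(ids)) stop("layout-based exclusion requires named vectors")
    ps <- layout_probeset_of(layout, ids)
    keep[is.na(ps)] <- FALSE           # not part of any probeset
    keep[ids %in% layout$masked] <- FALSE
  }
  for (v in list(sample, reference)) {
    keep[v == min(v)] <- FALSE         # all features tied at the chip minimum
    keep[v == max(v)] <- FALSE         # ... and at the chip maximum
  }
  rs <- if (is.null(raw_sample)) sample else raw_sample
  rr <- if (is.null(raw_reference)) reference else raw_reference
  keep[rs > config$saturation_threshold] <- FALSE
  keep[rr > config$saturation_threshold] <- FALSE
  idx <- which(keep)
  if (length(idx) < config$min_training_size) {
    stop("only ", length(idx), " candidate training features remain (minimum ",
         config$min_training_size, ")")
  }
  idx
}

#' Iterative rank-order pruning
#'
#' Identifies a rank-invariant feature set.  At each iteration both
#' vectors are ranked within the current set (average ranks on ties)
#' and each feature's rank difference is expressed as a percentage of
#' the current set size.  If the maximum percentage difference is at or
#' below `convergence_pct` the loop stops; otherwise every feature
#' above (max - `prune_decrement_pct`) is removed and the set is
#' re-ranked.  The gradually decreasing cutoff is what makes the
#' training set robust to large one-sided blocks of differentially
#' expressed features.
#'
#' @param x,y Aligned numeric vectors in log scale (reference and
#'   sample).
#' @param config An [iron_config()].
#' @return An object of class `iron_training`: list with `indices`
#'   (positions within the input vectors), `x`, `y` (surviving values),
#'   `iteration_sizes` (set size after each pruning pass, starting with
#'   the initial size), `converged`, and `max_pct_delta` (final maximum
#'   rank difference, percent).
#' @export
iterative_rank_prune <- function(x, y, config = iron_config()) {
  config <- as_iron_config(config)
  stopifnot(length(x) == length(y))
  n0 <- length(x)
  if (n0 < config$min_training_size) {
    stop("training set smaller than min_training_size before pruning")
  }
  idx <- seq_len(n0)
  sizes <- integer(0)
  converged <- FALSE
  max_pct <- NA_real_
  repeat {
    n <- length(idx)
    rx <- rank(x[idx], ties.method = "average")
    ry <- rank(y[idx], ties.method = "average")
    pct <- abs(rx - ry) / n * 100
    max_pct <- max(pct)
    if (max_pct <= config$convergence_pct) {
      converged <- TRUE
      break
    }
    cutoff <- max_pct - config$prune_decrement_pct
    keep <- pct <= cutoff
    idx <- idx[keep]
    sizes <- c(sizes, length(idx))
    if (length(idx) < config$min_training_size) {
      stop(errorCondition(
        paste0("training set shrank below min_training_size (",
               length(idx), " < ", config$min_training_size, ")"),
        iteration_sizes = c(n0, sizes),
        class = "iron_prune_error"))
    }
  }
  structure(list(indices = idx,
                 x = x[idx], y = y[idx],
                 iteration_sizes = c(n0, sizes),
                 converged = converged,
                 max_pct_delta = max_pct),
            class = "iron_training")
}

# Sums of x over windows [i, i+w-1], i = 1..n-w+1.  Small problems use
# exact per-window summation; large ones use prefix sums, whose error
# is bounded by machine epsilon times the running total (adequate once
# windows hold thousands of points).
window_sums <- function(x, w) {
  n <- length(x)
  nw <- n - w + 1L
  if (as.double(nw) * w <= 5e6) {
    out <- numeric(nw)
    for (i in seq_len(nw)) out[i] <- sum(x[i:(i + w - 1L)])
    return(out)
  }
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# mean over, for each point j, the window statistics of all windows
# containing j; stat has one entry per window start
point_window_means <- function(stat, n, w) {
  nw <- n - w + 1L
  cs <- c(0, cumsum(stat))
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(seq_len(n), nw)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Density weights for curve fitting
#'
#' Sparsely populated regions of the average-intensity axis,
#' particularly at high intensity, must be up-weighted or the fit is
#' dominated by the dense bulk of the scatterplot.  A short sliding
#' window (fraction `window_frac_sigma` of the training set) moves over
#' the sorted `log(X*Y)` values; each point's `sigma_avg` is the mean
#' standard deviation of all windows containing it, and its weight is
#' `sigma_avg ^ weight_exponent`.
#'
#' @param a Ascending numeric vector of `log(X*Y)` values.
#' @param config An [iron_config()].
#' @return Weight vector, all positive for non-constant input.
#' @export
density_weights <- function(a, config = iron_config()) {
  config <- as_iron_config(config)
  n <- length(a)
  if (is.unsorted(a)) stop("`a` must be sorted ascending")
  if (n < 2 || max(a) == min(a)) {
    if (max(a) == min(a)) warning("constant intensities: uniform density weights")
    return(rep(1, n))
  }
  w <- max(2L, round(config$window_frac_sigma * n))
  w <- min(w, n)
  ac <- a - mean(a)                       # center for numerical stability
  s1 <- window_sums(ac, w)
  s2 <- window_sums(ac^2, w)
  var_w <- pmax(0, (s2 - s1^2 / w) / (w - 1))
  sd_w <- sqrt(var_w)
  sigma_avg <- point_window_means(sd_w, n, w)
  weights <- sigma_avg^config$weight_exponent
  if (any(weights == 0)) {
    pos <- weights[weights > 0]
    weights[weights == 0] <- if (length(pos) > 0) min(pos) else 1
  }
  weights
}

#' Sliding-window weighted least-squares trend fit
#'
#' Fits the intensity-dependent log-ratio trend.  With training points
#' sorted by `A = log(X*Y)`, a window of fraction `window_frac_fit` of
#' the set slides one point at a time; within each window a weighted
#' least-squares line of `M = log(X/Y)` on `A` is fitted.  Each point's
#' fitted value is obtained by averaging the slopes and the offsets of
#' every window containing it and evaluating the averaged line at the
#' point's `A`.  Windows with zero weight or no `A`-variance fall back
#' to the weighted mean of `M` (slope 0).
#'
#' @param x,y Aligned numeric log-scale vectors (reference, sample)
#'   sorted ascending by `x + y`.
#' @param weights Positive weights from [density_weights()].
#' @param config An [iron_config()].
#' @return Numeric vector of fitted `log(X/Y)` values, one per point.
#' @export
fit_correction <- function(x, y, weights, config = iron_config()) {
  config <- as_iron_config(config)
  n <- length(x)
  stopifnot(length(y) == n, length(weights) == n)
  a <- x + y
  m <- x - y
  if (is.unsorted(a)) stop("points must be sorted ascending by x + y")
  w <- max(3L, round(config$window_frac_fit * n))
  w <- min(w, n)
  # center to keep the window prefix sums small
  abar <- mean(a); mbar <- mean(m)
  ac <- a - abar; mc <- m - mbar
  sw   <- window_sums(weights, w)
  swa  <- window_sums(weights * ac, w)
  swm  <- window_sums(weights * mc, w)
  swaa <- window_sums(weights * ac * ac, w)
  swam <- window_sums(weights * ac * mc, w)
  denom <- sw * swaa - swa^2
  slope <- numeric(length(sw))
  icpt <- numeric(length(sw))
  ok <- sw > 0 & denom > .Machine$double.eps * pmax(sw * swaa, 1)
  slope[ok] <- (sw[ok] * swam[ok] - swa[ok] * swm[ok]) / denom[ok]
  icpt[ok] <- (swm[ok] - slope[ok] * swa[ok]) / sw[ok]
  # degenerate window: weighted mean of M, slope 0
  deg <- !ok
  if (any(deg)) {
    icpt[deg] <- ifelse(sw[deg] > 0, swm[deg] / sw[deg], 0)
  }
  slope_bar <- point_window_means(slope, n, w)
  icpt_bar <- point_window_means(icpt, n, w)
  slope_bar * ac + icpt_bar + mbar
}

#' Build the normalization fit curve
#'
#' Projects each training point onto the fitted trend along the ratio
#' axis: with `d = fitted - (x - y)`, the projected coordinates are
#' `x_proj = x + d/2`, `y_proj = y - d/2`, so average intensity
#' (`x + y`) is preserved and `x_proj - y_proj` equals the fitted
#' log-ratio, stored as the point's correction.  Points projecting onto
#' the same `y_proj` are merged by averaging their corrections.  The
#' means of the first and last `extrapolation_points` corrections are
#' precomputed for out-of-range queries.
#'
#' @param x,y Aligned log-scale training vectors (reference, sample).
#' @param fitted Fitted log-ratios from [fit_correction()].
#' @param config An [iron_config()].
#' @return An object of class `iron_curve`: data frame with columns
#'   `y_proj`, `x_proj`, `correction`, sorted by `y_proj`, plus
#'   attributes `head_correction` and `tail_correction`.
#' @export
build_fit_curve <- function(x, y, fitted, config = iron_config()) {
  config <- as_iron_config(config)
  stopifnot(length(x) == length(y), length(fitted) == length(x))
  d <- fitted - (x - y)
  y_proj <- y - d / 2
  corr <- fitted
  # merge exact duplicates in y_proj by averaging corrections
  o <- order(y_proj)
  y_proj <- y_proj[o]; corr <- corr[o]
  if (anyDuplicated(y_proj)) {
    grp <- match(y_proj, y_proj)
    corr <- as.numeric(tapply(corr, grp, mean))
    y_proj <- y_proj[!duplicated(grp)]
  }
  k <- min(config$extrapolation_points, length(y_proj))
  curve <- data.frame(y_proj = y_proj,
                      x_proj = y_proj + corr,
                      correction = corr)
  structure(curve,
            head_correction = mean(corr[seq_len(k)]),
            tail_correction = mean(corr[seq.int(length(corr) - k + 1, length(corr))]),
            class = c("iron_curve", "data.frame"))
}

#' Apply a fit curve to a chip
#'
#' Every feature's log intensity receives the correction interpolated
#' linearly over the curve's `y_proj` grid; queries below or above the
#' curve range receive the precomputed head or tail mean correction.
#' The corrected log intensity is exponentiated back to linear scale.
#'
#' @param sample Numeric vector of linear intensities (the whole chip,
#'   including features excluded from training).
#' @param curve An `iron_curve` from [build_fit_curve()] with >= 2
#'   points.
#' @param config An [iron_config()].
#' @return Normalized linear intensity vector.
#' @export
apply_fit_curve <- function(sample, curve, config = iron_config()) {
  config <- as_iron_config(config)
  if (!inherits(curve, "iron_curve")) stop("`curve` must be an iron_curve")
  if (nrow(curve) < 2) stop("fit curve needs at least 2 points")
  ylog <- log(pseudo_positive(sample), base = config$log_base)
  corr <- stats::approx(curve$y_proj, curve$correction, xout = ylog,
                        method = "linear", rule = 1, ties = "ordered")$y
  corr[ylog < curve$y_proj[1]] <- attr(curve, "head_correction")
  corr[ylog > curve$y_proj[nrow(curve)]] <- attr(curve, "tail_correction")
  out <- config$log_base^(ylog + corr)
  names(out) <- names(sample)
  out
}

#' Pair-wise iterative rank-order normalization
#'
#' Normalizes one sample chip against a reference chip.  The stages
#' are: candidate selection ([build_training_set()]), log transform,
#' iterative rank-order pruning ([iterative_rank_prune()]), density
#' weighting ([density_weights()]), sliding-window weighted
#' least-squares trend fitting ([fit_correction()]), curve construction
#' ([build_fit_curve()]) and application to every feature
#' ([apply_fit_curve()]).  The reference is never modified, and the
#' result depends only on the two vectors and the configuration, so a
#' dataset can be extended chip by chip without altering earlier
#' results.
#'
#' @param sample,reference Aligned numeric vectors of linear
#'   intensities (optionally named).
#' @param layout Optional [chip_layout()].
#' @param config An [iron_config()].
#' @param raw_sample,raw_reference Optional pre-correction intensities
#'   for the saturation test (see [build_training_set()]).
#' @return An object of class `iron_fit` with components `normalized`
#'   (linear intensities), `curve`, `training`, `sample`, `reference`,
#'   `config` and `report` (training trajectory and correction
#'   summary).  Methods: `print`, `summary`, `plot`, `predict`,
#'   `residuals`, `coef`, `fitted`.
#' @examples
#' set.seed(1)
#' ref <- rlnorm(2000, log(500), 1.5)
#' fit <- iron_fit(2 * ref, ref)
#' summary(fit)
#' @export
iron_fit <- function(sample, reference, layout = NULL,
                     config = iron_config(),
                     raw_sample = NULL, raw_reference = NULL) {
  config <- as_iron_config(config)
  if (length(sample) != length(reference)) stop("vectors must be aligned")
  stages <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  cand <- stages("training-set selection",
                 build_training_set(sample, reference, layout, config,
                                    raw_sample, raw_reference))
  xlog <- log(pseudo_positive(reference), base = config$log_base)
  ylog <- log(pseudo_positive(sample), base = config$log_base)
  training <- stages("rank pruning",
                     iterative_rank_prune(xlog[cand], ylog[cand], config))
  xs <- training$x; ys <- training$y
  o <- order(xs + ys)
  xs <- xs[o]; ys <- ys[o]
  wts <- stages("density weighting", density_weights(xs + ys, config))
  fitted_m <- stages("trend fitting", fit_correction(xs, ys, wts, config))
  curve <- stages("curve construction",
                  build_fit_curve(xs, ys, fitted_m, config))
  normalized <- stages("curve application",
                       apply_fit_curve(sample, curve, config))
  training$candidate_indices <- cand
  training$indices <- cand[training$indices]
  report <- list(
    n_candidates = length(cand),
    iteration_sizes = training$iteration_sizes,
    converged = training$converged,
    max_pct_delta = training$max_pct_delta,
    correction_summary = stats::quantile(curve$correction,
                                         c(0, 0.5, 1), names = FALSE)
  )
  structure(list(normalized = normalized,
                 curve = curve,
                 training = training,
                 fitted_log_ratio = fitted_m,
                 training_x = xs, training_y = ys, training_weights = wts,
                 sample = sample, reference = reference,
                 config = config, report = report,
                 call = match.call()),
            class = "iron_fit")
}

#' @rdname iron_fit
#' @param ... Passed on to [iron_fit()].
#' @export
normalize_pair <- function(sample, reference, ...) {
  iron_fit(sample, reference, ...)
}

#' @export
print.iron_fit <- function(x, ...) {
  r <- x$report
  cat("Pair-wise rank-order normalization fit\n")
  cat(sprintf("  features: %d, training candidates: %d, final training set: %d\n",
              length(x$sample), r$n_candidates, length(x$training$indices)))
  cat(sprintf("  pruning iterations: %d (converged: %s, final max rank delta %.3f%%)\n",
              length(r$iteration_sizes) - 1L, r$converged, r$max_pct_delta))
  cat(sprintf("  correction (log%g): min %.4f, median %.4f, max %.4f\n",
              x$config$log_base, r$correction_summary[1],
              r$correction_summary[2], r$correction_summary[3]))
  invisible(x)
}

#' @export
summary.iron_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(report = object$report,
              n_curve_points = nrow(object$curve),
              residual_summary = summary(res),
              trajectory = object$report$iteration_sizes)
  class(out) <- "summary.iron_fit"
  out
}

#' @export
print.summary.iron_fit <- function(x, ...) {
  cat("Pair-wise normalization summary\n")
  cat("  training-set trajectory:", paste(x$trajectory, collapse = " -> "), "\n")
  cat("  fit curve points:", x$n_curve_points, "\n")
  cat("  training residuals (observed - fitted log-ratio):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.iron_fit <- function(object, ...) {
  as.data.frame(object$curve)
}

#' @export
fitted.iron_fit <- function(object, ...) {
  object$fitted_log_ratio
}

#' @export
residuals.iron_fit <- function(object, ...) {
  (object$training_x - object$training_y) - object$fitted_log_ratio
}

#' Apply a fitted normalization to new intensities
#'
#' @param object An `iron_fit`.
#' @param newdata Optional vector of linear intensities; defaults to
#'   the fitted sample chip.
#' @param ... Unused.
#' @return Normalized linear intensities.
#' @export
predict.iron_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$normalized)
  apply_fit_curve(newdata, object$curve, object$config)
}

#' MA-plot of a pair-wise normalization fit
#'
#' Plots observed training points in average-intensity vs log-ratio
#' coordinates with the fitted correction curve overlaid.
#'
#' @param x An `iron_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.iron_fit <- function(x, ...) {
  a <- x$training_x + x$training_y
  m <- x$training_x - x$training_y
  graphics::plot(a, m, pch = ".", col = "grey40",
                 xlab = sprintf("A = log%g(X*Y)", x$config$log_base),
                 ylab = sprintf("M = log%g(X/Y)", x$config$log_base), ...)
  graphics::lines(a, x$fitted_log_ratio, col = "red", lwd = 2)
  graphics::abline(h = 0, col = "blue", lty = 2)
  invisible(x)
}
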