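#' Pipeline configuration
#'
#' Collects every tunable parameter of the normalization pipeline with
#' its default.  All log-space computation uses `log_base` (default 2);
#' correction factors are ratios and therefore base-independent.
#'
#' @param convergence_pct Rank-difference convergence threshold, in
#'   percent of the current training-set size.  Pruning stops once the
#'   largest rank difference is at or below this value.  Default 1.
#' @param prune_decrement_pct Per-iteration cutoff decrement, percent.
#'   Each pruning pass removes every point whose rank difference exceeds
#'   (current maximum - `prune_decrement_pct`).  Default 0.5.
#' @param window_frac_fit Sliding-window size for line fitting, as a
#'   fraction of the training set.  Default 0.10.
#' @param window_frac_sigma Sliding-window size for density weighting,
#'   as a fraction of the training set.  Default 0.01.
#' @param weight_exponent Exponent applied to the per-point average
#'   window standard deviation to form fitting weights.  Default 4.
#' @param saturation_threshold Linear intensity above which a feature is
#'   considered saturated and excluded from training.  Default 64000
#'   (16-bit scanners).
#' @param extrapolation_points Number of terminal fit points averaged to
#'   form the constant correction used outside the training range.
#'   Default 10.
#' @param min_training_size Minimum number of training points; below
#'   this the fit aborts rather than produce an unstable curve.
#'   Default 100.
#' @param do_background Run background subtraction in [iron_run()].
#' @param do_probeset_norm Run the second, probeset-level normalization
#'   pass in [iron_run()].
#' @param log_base Base for all log-space computation.  Default 2.
#' @param rng_seed Optional integer seed, reserved for stochastic
#'   components (the normalization itself is deterministic).
#'
#' @return An object of class `iron_config` (a validated list).
#' @examples
#' cfg <- iron_config(convergence_pct = 2)
#' cfg$convergence_pct
#' @export
iron_config <- function(convergence_pct = 1.0,
                        prune_decrement_pct = 0.5,
                        window_frac_fit = 0.10,
                        window_frac_sigma = 0.01,
                        weight_exponent = 4,
                        saturation_threshold = 64000,
                        extrapolation_points = 10,
                        min_training_size = 100,
                        do_background = TRUE,
                        do_probeset_norm = TRUE,
                        log_base = 2,
                        rng_seed = NULL) {
  cfg <- list(
    convergence_pct = as.numeric(convergence_pct),
    prune_decrement_pct = as.numeric(prune_decrement_pct),
    window_frac_fit = as.numeric(window_frac_fit),
    window_frac_sigma = as.numeric(window_frac_sigma),
    weight_exponent = as.numeric(weight_exponent),
    saturation_threshold = as.numeric(saturation_threshold),
    extrapolation_points = as.integer(extrapolation_points),
    min_training_size = as.integer(min_training_size),
    do_background = isTRUE(do_background),
    do_probeset_norm = isTRUE(do_probeset_norm),
    log_base = as.numeric(log_base),
    rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
  )
  validate_iron_config(cfg)
  class(cfg) <- "iron_config"
  cfg
}

validate_iron_config <- function(cfg) {
  stopifnot(
    cfg$convergence_pct > 0, cfg$convergence_pct < 100,
    cfg$prune_decrement_pct > 0,
    cfg$window_frac_sigma > 0,
    cfg$window_frac_sigma <= cfg$window_frac_fit,
    cfg$window_frac_fit < 1,
    cfg$weight_exponent >= 0,
    cfg$extrapolation_points >= 1L,
    cfg$min_training_size >= 3L,
    cfg$saturation_threshold > 0,
    cfg$log_base > 1
  )
  invisible(cfg)
}

#' @export
print.iron_config <- function(x, ...) {
  cat("Normalization pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

as_iron_config <- function(config) {
  if (is.null(config)) return(iron_config())
  if (inherits(config, "iron_config")) return(config)
  if (is.list(config)) return(do.call(iron_config, config))
  stop("`config` must be an iron_config object or a named list")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with
#' `#` are ignored.  Keys must match [iron_config()] argument names.
#'
#' @param path Path to the configuration file.
#' @return An `iron_config` object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(iron_config())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(iron_config))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (keys[i] %in% c("do_background", "do_probeset_norm")) {
      toupper(v) %in% c("TRUE", "T", "1", "YES")
    } else {
      as.numeric(v)
    }
  })
  names(args) <- keys
  do.call(iron_config, args)
}
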