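#' Run the full normalization pipeline
#'
#' Stage order: (1) reference selection by [find_median_chip()] when
#' `reference = "auto"`; (2) per-chip background subtraction
#' (`do_background`); (3) probe-level pair-wise normalization of every
#' sample against the reference; (4) probeset summarization when a
#' layout is given; (5) a second pair-wise normalization pass at the
#' probeset level against the reference's own summarized vector
#' (`do_probeset_norm`).  The reference chip passes through the
#' normalization stages unchanged (it is background-subtracted and
#' summarized, never curve-adjusted).  Every sample is processed as a
#' pure function of its own raw column, the reference and the
#' configuration, so results are independent of which other samples are
#' in the run.
#'
#' The saturation test for training-set selection always uses the raw
#' (pre-background-subtraction) intensities.
#'
#' @param matrix A linear-scale [expression_matrix()] with >= 2
#'   samples.
#' @param layout Optional [chip_layout()]; without it, summarization
#'   and the probeset-level pass are skipped.
#' @param config An [iron_config()].
#' @param reference A sample ID, or `"auto"` to select the median chip.
#' @return An object of class `iron_run` with components `expression`
#'   (final probeset- or probe-level matrix), `probe_matrix`
#'   (probe-level normalized matrix), `reference` (sample ID),
#'   `reference_selection` (the `median_chip` object, when auto),
#'   `report` (per-sample records), `bg_params`, and `config`.
#' @examples
#' sim <- simulate_chip_set(sim_spec(n_probes = 600, n_probesets = 200,
#'   probes_per_set = 3, n_chips = 3, seed = 1))
#' run <- iron_run(sim$matrix, sim$layout,
#'   config = iron_config(do_background = FALSE, min_training_size = 50))
#' run
#' @export
iron_run <- function(matrix, layout = NULL, config = iron_config(),
                     reference = "auto") {
  assert_scale(matrix, "linear")
  config <- as_iron_config(config)
  if (ncol(matrix) < 2) stop("pipeline needs at least 2 samples")
  t0 <- proc.time()[["elapsed"]]

  ref_sel <- NULL
  if (identical(reference, "auto")) {
    ref_sel <- find_median_chip(matrix, layout, config = config)
    reference <- ref_sel$sample_id
  }
  if (!reference %in% colnames(matrix)) {
    stop("reference sample '", reference, "' not found in matrix")
  }

  raw <- unclass(matrix)
  bg <- NULL
  if (config$do_background) {
    bg <- background_subtract(matrix)
    work <- unclass(bg$matrix)
  } else {
    work <- raw
  }

  ref_vec <- work[, reference]
  raw_ref <- raw[, reference]
  names(ref_vec) <- names(raw_ref) <- rownames(matrix)

  probe_out <- work
  report <- vector("list", ncol(matrix))
  names(report) <- colnames(matrix)
  for (j in seq_len(ncol(matrix))) {
    sid <- colnames(matrix)[j]
    if (sid == reference) {
      report[[j]] <- list(sample_id = sid, reference = TRUE)
      next
    }
    smp <- work[, j]
    names(smp) <- rownames(matrix)
    fit <- tryCatch(
      iron_fit(smp, ref_vec, layout, config,
               raw_sample = raw[, j], raw_reference = raw_ref),
      error = function(e) {
        stop("probe-level normalization failed for sample '", sid, "': ",
             conditionMessage(e), call. = FALSE)
      })
    probe_out[, j] <- fit$normalized
    report[[j]] <- c(list(sample_id = sid, reference = FALSE), fit$report)
  }
  probe_mat <- expression_matrix(probe_out, scale = "linear")

  expr <- probe_mat
  if (!is.null(layout)) {
    expr <- summarize_probesets(probe_mat, layout)
    if (config$do_probeset_norm) {
      ps_ref <- unclass(expr)[, reference]
      names(ps_ref) <- rownames(expr)
      ps_out <- unclass(expr)
      for (j in seq_len(ncol(expr))) {
        sid <- colnames(expr)[j]
        if (sid == reference) next
        smp <- ps_out[, j]
        names(smp) <- rownames(expr)
        fit <- tryCatch(
          iron_fit(smp, ps_ref, layout = NULL, config),
          error = function(e) {
            stop("probeset-level normalization failed for sample '", sid,
                 "': ", conditionMessage(e), call. = FALSE)
          })
        ps_out[, j] <- fit$normalized
        report[[sid]]$probeset_pass <- fit$report
      }
      expr <- expression_matrix(ps_out, scale = "linear")
    }
  }

  structure(list(expression = expr,
                 probe_matrix = probe_mat,
                 reference = reference,
                 reference_selection = ref_sel,
                 report = report,
                 bg_params = if (is.null(bg)) NULL else bg$params,
                 config = config,
                 elapsed = proc.time()[["elapsed"]] - t0,
                 call = match.call()),
            class = "iron_run")
}

#' @export
print.iron_run <- function(x, ...) {
  cat("Iterative rank-order normalization run\n")
  cat(sprintf("  %d features x %d samples; reference: %s\n",
              nrow(x$expression), ncol(x$expression), x$reference))
  cat(sprintf("  background subtraction: %s; probeset pass: %s\n",
              x$config$do_background,
              !is.null(x$report[[1]]$probeset_pass) ||
                x$config$do_probeset_norm))
  for (r in x$report) {
    if (isTRUE(r$reference)) {
      cat(sprintf("  %-12s reference (identity)\n", r$sample_id))
    } else {
      cat(sprintf(
        "  %-12s training %d -> %d, %d iteration(s), correction median %.3f\n",
        r$sample_id, r$iteration_sizes[1],
        r$iteration_sizes[length(r$iteration_sizes)],
        length(r$iteration_sizes) - 1L, r$correction_summary[2]))
    }
  }
  cat(sprintf("  elapsed: %.2f s\n", x$elapsed))
  invisible(x)
}

#' @export
summary.iron_run <- function(object, ...) {
  print(object, ...)
}

fingerprint <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(object, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Store a normalization reference for incremental use
#'
#' Captures everything needed to normalize future chips exactly as they
#' would have been normalized inside the original run: the processed
#' (background-subtracted) reference vector, the raw reference vector
#' (for the saturation test), the summarized probeset reference, the
#' layout, and the configuration, together with a fingerprint that
#' guards against mismatched configurations.
#'
#' @param run An [iron_run()] result.
#' @param raw_matrix The raw matrix the run was made from.
#' @return An object of class `iron_reference`.
#' @export
iron_reference <- function(run, raw_matrix) {
  stopifnot(inherits(run, "iron_run"))
  assert_scale(raw_matrix, "linear")
  ref <- run$reference
  raw_ref <- unclass(raw_matrix)[, ref]
  names(raw_ref) <- rownames(raw_matrix)
  proc_ref <- if (run$config$do_background) {
    p <- run$bg_params[[ref]]
    correct_chip(raw_ref, p)
  } else raw_ref
  names(proc_ref) <- rownames(raw_matrix)
  ps_ref <- NULL
  if (!is.null(run$expression) &&
      !identical(rownames(run$expression), rownames(raw_matrix))) {
    ps_ref <- unclass(run$expression)[, ref]
    names(ps_ref) <- rownames(run$expression)
  }
  obj <- list(sample_id = ref,
              feature_ids = rownames(raw_matrix),
              raw_reference = raw_ref,
              reference = proc_ref,
              probeset_reference = ps_ref,
              config = run$config)
  obj$fingerprint <- fingerprint(obj[c("feature_ids", "raw_reference",
                                       "config")])
  class(obj) <- "iron_reference"
  obj
}

#' @export
print.iron_reference <- function(x, ...) {
  cat("Stored normalization reference\n")
  cat("  sample:", x$sample_id, "(", length(x$feature_ids), "features )\n")
  cat("  probeset reference:",
      if (is.null(x$probeset_reference)) "none"
      else paste(length(x$probeset_reference), "probesets"), "\n")
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Normalize one new chip against a stored reference
#'
#' Produces output bit-identical to what the same chip would receive
#' inside [iron_run()] with the same reference and configuration; no
#' previously produced output is touched.  The chip must share the
#' reference's feature order exactly (no silent reordering).
#'
#' @param new_chip Named numeric vector of raw linear intensities.
#' @param ref A stored [iron_reference()].
#' @param layout Optional [chip_layout()], as used in the original run.
#' @param expected_fingerprint Optional fingerprint to verify `ref`
#'   against (e.g. recorded when the reference was first stored).
#' @return A list with `probe` (normalized probe vector), `probeset`
#'   (normalized probeset vector, when the reference carries one) and
#'   `report`.
#' @export
normalize_incremental <- function(new_chip, ref, layout = NULL,
                                  expected_fingerprint = NULL) {
  stopifnot(inherits(ref, "iron_reference"))
  if (!is.null(expected_fingerprint) &&
      !identical(expected_fingerprint, ref$fingerprint)) {
    stop("reference fingerprint mismatch: expected ", expected_fingerprint,
         " but reference has ", ref$fingerprint)
  }
  ids <- names(new_chip)
  if (is.null(ids)) stop("new chip must be a named vector")
  if (!identical(ids, ref$feature_ids)) {
    bad <- which(ids != ref$feature_ids)[1]
    if (length(ids) != length(ref$feature_ids)) {
      stop("new chip has ", length(ids), " features, reference has ",
           length(ref$feature_ids))
    }
    stop("feature order mismatch at position ", bad, ": '", ids[bad],
         "' vs '", ref$feature_ids[bad], "'")
  }
  config <- ref$config
  work <- new_chip
  if (config$do_background) {
    p <- estimate_bg_params(pseudo_positive(new_chip))
    work <- correct_chip(new_chip, p)
    names(work) <- ids
  }
  fit <- iron_fit(work, ref$reference, layout, config,
                  raw_sample = new_chip, raw_reference = ref$raw_reference)
  out <- list(probe = fit$normalized, report = fit$report)
  if (!is.null(ref$probeset_reference) && !is.null(layout)) {
    m <- expression_matrix(
      matrix(fit$normalized, ncol = 1,
             dimnames = list(ids, "new_chip")))
    ps <- summarize_probesets(m, layout)
    ps_vec <- unclass(ps)[, 1]
    names(ps_vec) <- rownames(ps)
    if (!identical(names(ps_vec), names(ref$probeset_reference))) {
      common <- names(ref$probeset_reference)
      ps_vec <- ps_vec[common]
    }
    if (config$do_probeset_norm) {
      fit2 <- iron_fit(ps_vec, ref$probeset_reference, layout = NULL, config)
      out$probeset <- fit2$normalized
      out$report$probeset_pass <- fit2$report
    } else {
      out$probeset <- ps_vec
    }
  }
  out
}

#' Global median scaling (comparison method)
#'
#' Scales a sample by the single factor that equalizes its median log
#' ratio to the reference.  This is the naive comparator: it can fix a
#' constant gain but neither nonlinear response differences nor the
#' bias induced by asymmetric differential expression.
#'
#' @param sample,reference Aligned linear intensity vectors.
#' @param log_base Log base (default 2).
#' @return Scaled sample vector.
#' @export
normalize_global_median <- function(sample, reference, log_base = 2) {
  ls <- log(pseudo_positive(sample), base = log_base)
  lr <- log(pseudo_positive(reference), base = log_base)
  shift <- stats::median(lr - ls)
  out <- sample * log_base^shift
  names(out) <- names(sample)
  out
}
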