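#' Construct a chip layout
#'
#' Maps probes to probesets and records per-probe mask / quality-control
#' flags.  Probes with no probeset assignment (`NA` or empty) are kept
#' as "unassigned": they are excluded from training sets and from
#' probeset summarization but still normalized.
#'
#' @param probe_id Character vector of probe identifiers (unique).
#' @param probeset_id Character vector, same length; `NA` or `""` marks
#'   an unassigned probe.
#' @param masked Character vector of masked probe IDs.
#' @param qc_probes Character vector of quality-control probe IDs.
#' @return An object of class `chip_layout`.
#' @examples
#' chip_layout(c("p1", "p2", "p3"), c("ps1", "ps1", NA), masked = "p2")
#' @export
chip_layout <- function(probe_id, probeset_id,
                        masked = character(), qc_probes = character()) {
  probe_id <- as.character(probe_id)
  probeset_id <- as.character(probeset_id)
  stopifnot(length(probe_id) == length(probeset_id))
  validate_ids(probe_id, "probe")
  probeset_id[!is.na(probeset_id) & !nzchar(probeset_id)] <- NA_character_
  masked <- unique(as.character(masked))
  qc_probes <- unique(as.character(qc_probes))
  unknown_m <- setdiff(masked, probe_id)
  unknown_q <- setdiff(qc_probes, probe_id)
  if (length(unknown_m) > 0 || length(unknown_q) > 0) {
    warning("flagged probe ID(s) not present in layout: ",
            paste(utils::head(c(unknown_m, unknown_q), 5), collapse = ", "))
  }
  structure(
    list(probe_id = probe_id,
         probeset_id = probeset_id,
         masked = masked,
         qc_probes = qc_probes),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  n_assigned <- sum(!is.na(x$probeset_id))
  cat(sprintf(
    "Chip layout: %d probes, %d probesets, %d unassigned, %d masked, %d QC\n",
    length(x$probe_id),
    length(unique(x$probeset_id[!is.na(x$probeset_id)])),
    length(x$probe_id) - n_assigned,
    length(x$masked), length(x$qc_probes)))
  invisible(x)
}

#' Read a probe layout file
#'
#' Tab-delimited with header `probe_id`, `probeset_id` and an optional
#' `flags` column whose comma-separated tokens may include `mask` and
#' `qc`.  A probe listed twice with conflicting probesets is an error;
#' duplicate consistent rows are collapsed.
#'
#' @param path Path to the layout file.
#' @return A [chip_layout()].
#' @export
read_layout <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          blank.lines.skip = TRUE)
  if (!all(c("probe_id", "probeset_id") %in% names(df))) {
    stop("layout file must have columns probe_id and probeset_id")
  }
  if (nrow(df) == 0) {
    warning("layout file contains no probes")
    return(chip_layout(character(), character()))
  }
  df$probeset_id[!nzchar(df$probeset_id)] <- NA_character_
  if (anyDuplicated(df$probe_id)) {
    sets <- split(df$probeset_id, df$probe_id)
    conflict <- names(sets)[vapply(sets, function(s)
      length(unique(s)) > 1L, logical(1))]
    if (length(conflict) > 0) {
      stop("probe(s) assigned to more than one probeset: ",
           paste(utils::head(conflict, 5), collapse = ", "))
    }
    df <- df[!duplicated(df$probe_id), , drop = FALSE]
  }
  flags <- if ("flags" %in% names(df)) df$flags else rep("", nrow(df))
  toks <- strsplit(tolower(flags), "[,; ]+")
  has <- function(tok) vapply(toks, function(t) tok %in% t, logical(1))
  chip_layout(df$probe_id, df$probeset_id,
              masked = df$probe_id[has("mask")],
              qc_probes = df$probe_id[has("qc")])
}

# probeset assignment for a vector of feature IDs; NA = unassigned
layout_probeset_of <- function(layout, feature_ids) {
  idx <- match(feature_ids, layout$probe_id)
  out <- layout$probeset_id[idx]
  out[is.na(idx)] <- NA_character_
  out
}
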