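#' Differential-expression configuration
#'
#' @param log2_threshold Fold-change cutoff on the log2 scale; calls use
#'   the strict inequality `|mean log2| > threshold`.
#' @param min_peptides Minimum evidence (distinct quantified spectra, the
#'   smaller count across replicate sets) for a protein to be callable.
#' @param require_both_sets Require QC-passing quantification in both
#'   replicate sets.
#' @return List of class `de_config`.
#' @export
de_config <- function(log2_threshold = 0.6, min_peptides = 2L,
                      require_both_sets = TRUE) {
  stopifnot(log2_threshold > 0, min_peptides >= 1L)
  structure(list(
    log2_threshold = log2_threshold,
    min_peptides = as.integer(min_peptides),
    require_both_sets = isTRUE(require_both_sets)
  ), class = "de_config")
}

#' Intersect two replicate quantification sets
#'
#' Keeps the proteins quantified with a QC pass and defined contrasts in
#' both independent MS replicate sets; each contrast becomes the
#' arithmetic mean of the two sets' log2 values and the evidence count the
#' smaller of the two sets' spectrum counts.
#'
#' @param quant_set1,quant_set2 `ProteinQuant` tables from
#'   [quantify_proteins()].
#' @return `data.frame`: `accession`, `mean_log2_ir_vs_sham`,
#'   `mean_log2_tale_vs_ir`, `n_spectra_min`.
#' @export
intersect_sets <- function(quant_set1, quant_set2) {
  usable <- function(q) {
    q[q$qc_pass & !is.na(q$log2_ir_vs_sham) & !is.na(q$log2_tale_vs_ir),
      c("accession", "n_spectra", "log2_ir_vs_sham", "log2_tale_vs_ir"),
      drop = FALSE]
  }
  a <- usable(quant_set1)
  b <- usable(quant_set2)
  common <- intersect(a$accession, b$accession)
  if (length(common) == 0L) {
    warning("no proteins common to both replicate sets", call. = FALSE)
  }
  ia <- match(common, a$accession)
  ib <- match(common, b$accession)
  out <- data.frame(
    accession = common,
    mean_log2_ir_vs_sham = (a$log2_ir_vs_sham[ia] + b$log2_ir_vs_sham[ib]) / 2,
    mean_log2_tale_vs_ir = (a$log2_tale_vs_ir[ia] + b$log2_tale_vs_ir[ib]) / 2,
    n_spectra_min = pmin(a$n_spectra[ia], b$n_spectra[ib]),
    stringsAsFactors = FALSE
  )
  out[order(out$accession), , drop = FALSE]
}

.threshold_call <- function(x, threshold) {
  ifelse(x > threshold, "up", ifelse(x < -threshold, "down", "null"))
}

#' Call IR-related proteins
#'
#' A protein is called up when its averaged IR-vs-sham log2 ratio exceeds
#' `+threshold` (strict), down below `-threshold`, and null otherwise;
#' proteins with fewer than `min_peptides` spectra are never called.
#'
#' @param common Output of [intersect_sets()].
#' @param config A [de_config()].
#' @return `common` with a `class_ir` column.
#' @export
call_ir_related <- function(common, config = de_config()) {
  common$class_ir <- .threshold_call(common$mean_log2_ir_vs_sham,
                                     config$log2_threshold)
  common$class_ir[common$n_spectra_min < config$min_peptides] <- "null"
  common
}

#' Call TALE-affected proteins among the IR-related set
#'
#' The TALE-vs-IR contrast is evaluated only for proteins already called
#' IR-related (up or down), by the same strict fold-change rule; all other
#' proteins are marked `not_evaluated`.
#'
#' @param calls Output of [call_ir_related()].
#' @param config A [de_config()].
#' @return `calls` with a `class_tale` column.
#' @export
call_tale_affected <- function(calls, config = de_config()) {
  calls$class_tale <- ifelse(
    calls$class_ir == "null", "not_evaluated",
    .threshold_call(calls$mean_log2_tale_vs_ir, config$log2_threshold))
  calls
}

#' Summarize differential-expression counts
#'
#' @param calls Output of [call_tale_affected()].
#' @return List of counts: common proteins, IR up/down/total, TALE
#'   up/down/total.
#' @export
summarize_counts <- function(calls) {
  n <- function(x, v) sum(x == v)
  ir_up <- n(calls$class_ir, "up"); ir_down <- n(calls$class_ir, "down")
  tale_up <- if ("class_tale" %in% names(calls))
    n(calls$class_tale, "up") else 0L
  tale_down <- if ("class_tale" %in% names(calls))
    n(calls$class_tale, "down") else 0L
  list(
    n_common = nrow(calls),
    ir_up = ir_up, ir_down = ir_down, ir_total = ir_up + ir_down,
    tale_up = tale_up, tale_down = tale_down,
    tale_total = tale_up + tale_down
  )
}
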