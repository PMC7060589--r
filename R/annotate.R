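#' Read a protein annotation table
#'
#' Expects a TSV with columns `accession`, `ontology`
#' (`molecular_function`, `biological_process` or `cellular_component`)
#' and `term`; a protein may map to several terms per ontology or to none.
#'
#' @param path TSV file path.
#' @return Annotation `data.frame`.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("accession", "ontology", "term") %in% names(ann)))
  ann
}

#' Category-percentage summary of a protein list
#'
#' Tabulates the annotation terms hit by a protein list within one
#' ontology.  Percentages are shares of classified hits (a protein
#' mapping to k terms contributes k hits), not of proteins, so they sum
#' to 100 over the listed terms; proteins with no annotation in the
#' ontology are counted separately in attribute `n_unannotated`.
#'
#' @param accessions Character vector of protein accessions (e.g. an up-
#'   or down-regulated list).
#' @param annotations Annotation `data.frame` from [read_annotations()].
#' @param ontology One of `"molecular_function"`, `"biological_process"`,
#'   `"cellular_component"`.
#' @return `data.frame` of `term`, `count`, `percent`, sorted by
#'   descending count.
#' @export
summarize_categories <- function(accessions, annotations, ontology) {
  stopifnot(ontology %in% c("molecular_function", "biological_process",
                            "cellular_component"))
  accessions <- unique(accessions)
  hits <- annotations[annotations$ontology == ontology &
                        annotations$accession %in% accessions, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- data.frame(term = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_unannotated") <- length(accessions)
    return(out)
  }
  tab <- table(hits$term)
  out <- data.frame(
    term = names(tab), count = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$count, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- sum(!accessions %in% hits$accession)
  out
}

# md5 of a config list through its serialized JSON (for the run manifest)
.config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-to-calls pipeline
#'
#' Simulates a proteome with ground truth, generates the paired CID/HCD
#' scan streams for each replicate set, merges reporter ions into the CID
#' scans, searches them against the target+decoy space, filters by
#' decoy-estimated FDR with the two-peptide rule, quantifies proteins with
#' duplicate-label QC, intersects the replicate sets, calls IR-related and
#' TALE-affected proteins, and (optionally) summarizes annotation
#' categories for the up/down lists.  A manifest records the
#' configuration hash, seed, package version and stage-by-stage record
#' counts.
#'
#' @param sim_config A [simulation_config()].
#' @param search_cfg A [search_config()].
#' @param quant_cfg A [quant_config()].
#' @param de_cfg A [de_config()].
#' @param design A [channel_design()].
#' @param annotations Optional annotation `data.frame`.
#' @param out_dir Optional directory; when given, the proteome FASTA,
#'   per-set MGF files, ground truth, quantification tables, the DE table
#'   and the JSON manifest are written there.
#' @return List: `proteins`, `truth`, `quant` (per set), `common`,
#'   `calls`, `counts`, `recovery` (confusion counts vs truth),
#'   `annotation_summaries` (if requested), `manifest`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         search_cfg = search_config(),
                         quant_cfg = quant_config(),
                         de_cfg = de_config(),
                         design = channel_design(),
                         annotations = NULL,
                         out_dir = NULL) {
  stopifnot(sim_config$n_sets >= 2L)
  proteins <- generate_proteome(sim_config)
  truth <- assign_ground_truth(proteins, sim_config)
  sets <- simulate_spectra(proteins, truth, sim_config, design)
  space <- build_search_space(proteins, search_cfg)

  quant <- vector("list", length(sets))
  stage_counts <- list()
  for (s in seq_along(sets)) {
    merged <- merge_scan_stream(sets[[s]], quant_cfg)
    psms <- search_spectra(merged, space, search_cfg)
    acc <- filter_by_fdr(psms, search_cfg)
    with_rep <- attach_reporters(acc$psms, merged)
    quant[[s]] <- quantify_proteins(with_rep, design, quant_cfg)
    stage_counts[[s]] <- list(
      spectra = length(sets[[s]]), merged_scans = length(merged),
      psms = nrow(psms), accepted_psms = nrow(acc$psms),
      accepted_proteins = nrow(acc$proteins),
      quantified_proteins = sum(quant[[s]]$qc_pass)
    )
  }
  common <- intersect_sets(quant[[1]], quant[[2]])
  calls <- call_tale_affected(call_ir_related(common, de_cfg), de_cfg)
  counts <- summarize_counts(calls)
  recovery <- recovery_stats(calls, truth)

  ann_sum <- NULL
  if (!is.null(annotations)) {
    up <- calls$accession[calls$class_ir == "up"]
    down <- calls$accession[calls$class_ir == "down"]
    onts <- c("molecular_function", "biological_process",
              "cellular_component")
    ann_sum <- lapply(
      setNames(onts, onts),
      function(ont) list(
        up = summarize_categories(up, annotations, ont),
        down = summarize_categories(down, annotations, ont)
      ))
  }

  manifest <- list(
    package_version = as.character(packageVersion("tmtquant")),
    seed = sim_config$seed,
    config_hash = .config_hash(list(sim = unclass(sim_config),
                                    search = unclass(search_cfg),
                                    quant = unclass(quant_cfg),
                                    de = unclass(de_cfg))),
    stage_counts = stage_counts,
    de_counts = counts
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta_proteins(proteins, file.path(out_dir, "proteome.fasta"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.tsv"))
    for (s in seq_along(sets)) {
      write_mgf(sets[[s]], file.path(out_dir, sprintf("set%d.mgf", s)))
      write.table(quant[[s]], file.path(out_dir, sprintf("quant_set%d.tsv", s)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(calls, file.path(out_dir, "de_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(proteins = proteins, truth = truth, quant = quant, common = common,
       calls = calls, counts = counts, recovery = recovery,
       annotation_summaries = ann_sum, manifest = manifest)
}

#' Recovery of ground-truth labels by the DE calls
#'
#' Confusion counts of the IR and TALE classifications against the
#' simulation ground truth, over the proteins present in the call table;
#' truth proteins absent from the table count as missed.
#'
#' @param calls Output of [call_tale_affected()].
#' @param truth Ground truth from [assign_ground_truth()].
#' @return List with per-contrast true/false positive and negative counts
#'   plus `sensitivity` and `fdp` for the IR contrast.
#' @export
recovery_stats <- function(calls, truth) {
  m <- match(truth$accession, calls$accession)
  called_ir <- ifelse(is.na(m), "null", calls$class_ir[m])
  true_ir <- truth$true_label_ir
  tp <- sum(true_ir != "null" & called_ir == true_ir)
  fp <- sum(true_ir == "null" & called_ir != "null") +
    sum(true_ir != "null" & called_ir != "null" & called_ir != true_ir)
  fn <- sum(true_ir != "null" & called_ir != true_ir)
  tn <- sum(true_ir == "null" & called_ir == "null")
  n_called <- sum(called_ir != "null")
  list(
    ir_tp = tp, ir_fp = fp, ir_fn = fn, ir_tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fdp = if (n_called > 0) fp / n_called else 0
  )
}
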