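#' Six-plex channel design
#'
#' The duplicate-label layout: each biological sample is labeled with two
#' different TMT reagents, giving two channels per group (sham 126/129,
#' IR 127/130, TALE 128/131).
#'
#' @return `data.frame` with columns `channel`, `group`, `replicate`.
#' @export
channel_design <- function() {
  data.frame(
    channel = c("126", "127", "128", "129", "130", "131"),
    group = c("sham", "IR", "TALE", "sham", "IR", "TALE"),
    replicate = c(1L, 1L, 1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Quantification configuration
#'
#' @param reporter_window_ppm Half-width of the reporter extraction window
#'   around each canonical reporter m/z, in ppm.
#' @param duplicate_variation_max Maximum tolerated duplicate-label
#'   variation per group; proteins above it are excluded.
#' @param reporter_mz Named vector of the six reporter m/z values.
#' @return List of class `quant_config`.
#' @export
quant_config <- function(reporter_window_ppm = 20,
                         duplicate_variation_max = 0.30,
                         reporter_mz = TMT6_REPORTER_MZ) {
  stopifnot(reporter_window_ppm > 0,
            duplicate_variation_max > 0, duplicate_variation_max < 1,
            length(reporter_mz) == 6L)
  structure(list(
    reporter_window_ppm = reporter_window_ppm,
    duplicate_variation_max = duplicate_variation_max,
    reporter_mz = reporter_mz
  ), class = "quant_config")
}

#' Pair CID scans with their HCD partners
#'
#' An HCD scan pairs with the nearest preceding CID scan that has the same
#' precursor m/z (within 1e-4 Th) with no other CID scan in between, the
#' acquisition order of data-dependent CID-HCD dual scans.  A CID scan
#' claimed by an earlier HCD scan is not re-paired (the first pairing wins,
#' with a warning).
#'
#' @param spectra List of [spectrum()] objects ordered by scan number.
#' @return List with `pairs` (`data.frame` of `cid_scan`, `hcd_scan`) and
#'   `unpaired` (integer scan numbers with no partner).
#' @export
pair_cid_hcd <- function(spectra) {
  ord <- order(vapply(spectra, `[[`, integer(1), "scan_number"))
  spectra <- spectra[ord]
  last_cid <- NULL
  last_cid_claimed <- FALSE
  pairs <- list()
  unpaired <- integer()
  for (s in spectra) {
    if (s$mode == "CID") {
      if (!is.null(last_cid) && !last_cid_claimed)
        unpaired <- c(unpaired, last_cid$scan_number)
      last_cid <- s
      last_cid_claimed <- FALSE
    } else {
      if (!is.null(last_cid) &&
          abs(s$precursor_mz - last_cid$precursor_mz) <= 1e-4) {
        if (last_cid_claimed) {
          warning("CID scan ", last_cid$scan_number,
                  " claimed by more than one HCD scan; keeping the first",
                  call. = FALSE)
          unpaired <- c(unpaired, s$scan_number)
        } else {
          pairs[[length(pairs) + 1L]] <- data.frame(
            cid_scan = last_cid$scan_number, hcd_scan = s$scan_number)
          last_cid_claimed <- TRUE
        }
      } else {
        unpaired <- c(unpaired, s$scan_number)
      }
    }
  }
  if (!is.null(last_cid) && !last_cid_claimed)
    unpaired <- c(unpaired, last_cid$scan_number)
  list(
    pairs = if (length(pairs) > 0L) do.call(rbind, pairs) else
      data.frame(cid_scan = integer(), hcd_scan = integer()),
    unpaired = unpaired
  )
}

#' Extract reporter intensities from an HCD scan
#'
#' For each of the six channels, takes the most intense peak within the
#' ppm window around the canonical reporter m/z (ties broken by smallest
#' absolute ppm error); channels with no in-window peak are `NA`.
#'
#' @param hcd An HCD [spectrum()].
#' @param config A [quant_config()].
#' @return Named numeric vector of six intensities (`NA` = missing).
#' @export
extract_reporters <- function(hcd, config = quant_config()) {
  stopifnot(hcd$mode == "HCD")
  tol <- config$reporter_window_ppm * 1e-6
  out <- setNames(rep(NA_real_, length(config$reporter_mz)),
                  names(config$reporter_mz))
  for (ch in names(config$reporter_mz)) {
    r <- config$reporter_mz[[ch]]
    in_win <- which(abs(hcd$mz - r) <= r * tol)
    if (length(in_win) == 0L) next
    best <- in_win[order(-hcd$intensity[in_win], abs(hcd$mz[in_win] - r))][1L]
    out[ch] <- hcd$intensity[best]
  }
  out
}

#' Insert reporter ions into the paired CID scan
#'
#' Reproduces the merged-scan construction: the CID peak list is unioned
#' with the found reporter peaks placed at their canonical m/z, leaving
#' every CID peak untouched, and the reporter vector is attached.
#'
#' @param cid The CID [spectrum()] of a pair.
#' @param reporters Output of [extract_reporters()] for the paired HCD scan.
#' @param config A [quant_config()].
#' @return The CID spectrum with reporter peaks inserted (sorted by m/z)
#'   and a `reporter_intensities` field.
#' @export
merge_into_cid <- function(cid, reporters, config = quant_config()) {
  found <- !is.na(reporters)
  mz <- c(cid$mz, unname(config$reporter_mz[names(reporters)[found]]))
  int <- c(cid$intensity, unname(reporters[found]))
  merged <- spectrum(cid$scan_number, "CID", cid$precursor_mz,
                     cid$precursor_charge, mz, int)
  merged$reporter_intensities <- reporters
  class(merged) <- c("merged_spectrum", "spectrum")
  merged
}

#' Pair, extract and merge a whole scan stream
#'
#' Convenience wrapper applying [pair_cid_hcd()], [extract_reporters()] and
#' [merge_into_cid()] to a full run.
#'
#' @param spectra List of [spectrum()] objects.
#' @param config A [quant_config()].
#' @return List of merged spectra (one per CID/HCD pair), with the pairing
#'   table as attribute `pairs`.
#' @export
merge_scan_stream <- function(spectra, config = quant_config()) {
  pr <- pair_cid_hcd(spectra)
  by_scan <- setNames(spectra,
                      vapply(spectra, `[[`, integer(1), "scan_number"))
  merged <- lapply(seq_len(nrow(pr$pairs)), function(i) {
    cid <- by_scan[[as.character(pr$pairs$cid_scan[i])]]
    hcd <- by_scan[[as.character(pr$pairs$hcd_scan[i])]]
    merge_into_cid(cid, extract_reporters(hcd, config), config)
  })
  structure(merged, pairs = pr$pairs, unpaired = pr$unpaired)
}

# duplicate-label variation: |a - b| / mean(a, b); NA when both are zero
.dup_variation <- function(a, b) {
  m <- (a + b) / 2
  ifelse(m > 0, abs(a - b) / m, NA_real_)
}

#' Aggregate accepted PSMs to protein-level channel means
#'
#' Channel mean = arithmetic mean of the reporter intensity over all
#' contributing spectra of the protein subgroup.  A PSM missing any of the
#' six reporters is excluded from every channel so the channel means stay
#' comparable; spectra matching shared peptides contribute to every parent
#' protein.  Proteins with no quantifiable spectrum are dropped (reported
#' in attribute `dropped`).
#'
#' @param psms Accepted-PSM `data.frame` with columns `scan`, `accessions`
#'   (`;`-joined) and reporter columns `ch126`..`ch131`.
#' @param design A [channel_design()].
#' @return `ProteinQuant` `data.frame`: `accession`, `n_spectra`, the six
#'   channel means, the three group means and per-group duplicate
#'   variation.
#' @export
aggregate_protein <- function(psms, design = channel_design()) {
  ch_cols <- paste0("ch", design$channel)
  stopifnot(all(ch_cols %in% names(psms)))
  complete <- stats::complete.cases(psms[, ch_cols])
  dropped_psms <- psms[!complete, , drop = FALSE]
  psms <- psms[complete, , drop = FALSE]
  if (nrow(psms) == 0L) {
    out <- data.frame(accession = character(), n_spectra = integer())
    attr(out, "dropped") <- unique(unlist(strsplit(
      dropped_psms$accessions, ";", fixed = TRUE)))
    return(out)
  }
  # expand multi-parent PSMs: one row per (PSM, accession)
  acc_list <- strsplit(psms$accessions, ";", fixed = TRUE)
  idx <- rep.int(seq_len(nrow(psms)), lengths(acc_list))
  acc <- unlist(acc_list)
  split_idx <- split(idx, acc)
  rows <- lapply(names(split_idx), function(a) {
    sub <- psms[unique(split_idx[[a]]), , drop = FALSE]
    means <- colMeans(sub[, ch_cols, drop = FALSE])
    cbind(data.frame(accession = a, n_spectra = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  pq <- do.call(rbind, rows)
  for (g in unique(design$group)) {
    chs <- paste0("ch", design$channel[design$group == g])
    pq[[paste0("mean_", g)]] <- rowMeans(pq[, chs])
    pq[[paste0("variation_", g)]] <- .dup_variation(pq[[chs[1]]], pq[[chs[2]]])
  }
  attr(pq, "dropped") <- setdiff(
    unique(unlist(strsplit(dropped_psms$accessions, ";", fixed = TRUE))),
    pq$accession)
  pq
}

#' Duplicate-label quality control
#'
#' A protein is excluded when, for any group, the variation between its two
#' duplicate channels `|a - b| / ((a + b)/2)` exceeds the threshold
#' (default 30%).  A group with both duplicate intensities zero has
#' undefined variation and is excluded with a reason.
#'
#' @param pq Output of [aggregate_protein()].
#' @param config A [quant_config()].
#' @param design A [channel_design()].
#' @return `pq` with logical column `qc_pass` and character `qc_reason`.
#' @export
duplicate_qc <- function(pq, config = quant_config(),
                         design = channel_design()) {
  groups <- unique(design$group)
  var_cols <- paste0("variation_", groups)
  if (nrow(pq) == 0L) {
    pq$qc_pass <- logical(); pq$qc_reason <- character(); return(pq)
  }
  vmat <- as.matrix(pq[, var_cols])
  undefined <- apply(vmat, 1L, function(v) any(is.na(v)))
  over <- apply(vmat, 1L, function(v) any(!is.na(v) & v > config$duplicate_variation_max))
  pq$qc_pass <- !undefined & !over
  pq$qc_reason <- ifelse(undefined, "undefined duplicate variation",
                         ifelse(over, sprintf("duplicate variation > %.0f%%",
                                              100 * config$duplicate_variation_max),
                                ""))
  pq
}

#' Log2 group-ratio contrasts
#'
#' Adds `log2_ir_vs_sham = log2(IR/sham)` and `log2_tale_vs_ir =
#' log2(TALE/IR)` computed from the group means; defined only for
#' QC-passing proteins with positive denominators (`NA` otherwise, with
#' the reason recorded).
#'
#' @param pq Output of [duplicate_qc()].
#' @return `pq` with the two log2 contrast columns.
#' @export
compute_ratios <- function(pq) {
  if (nrow(pq) == 0L) {
    pq$log2_ir_vs_sham <- numeric(); pq$log2_tale_vs_ir <- numeric()
    return(pq)
  }
  ok_ir <- pq$qc_pass & pq$mean_sham > 0 & pq$mean_IR > 0
  ok_tale <- pq$qc_pass & pq$mean_IR > 0 & pq$mean_TALE > 0
  pq$log2_ir_vs_sham <- ifelse(ok_ir, log2(pq$mean_IR / pq$mean_sham), NA_real_)
  pq$log2_tale_vs_ir <- ifelse(ok_tale, log2(pq$mean_TALE / pq$mean_IR), NA_real_)
  bad <- pq$qc_pass & (is.na(pq$log2_ir_vs_sham) | is.na(pq$log2_tale_vs_ir))
  pq$qc_reason[bad] <- "zero group mean; ratio undefined"
  pq
}

#' Protein quantification from accepted PSMs
#'
#' Runs aggregation, duplicate QC and ratio computation in sequence.
#'
#' @inheritParams aggregate_protein
#' @param config A [quant_config()].
#' @return `ProteinQuant` `data.frame` with QC flags and log2 contrasts.
#' @export
quantify_proteins <- function(psms, design = channel_design(),
                              config = quant_config()) {
  compute_ratios(duplicate_qc(aggregate_protein(psms, design), config, design))
}

#' Attach reporter intensities to accepted PSMs
#'
#' Joins the reporter vectors carried by merged spectra onto a PSM table
#' by scan number, producing the `ch126`..`ch131` columns consumed by
#' [aggregate_protein()].
#'
#' @param psms Accepted-PSM `data.frame` with a `scan` column.
#' @param merged List of merged spectra from [merge_scan_stream()].
#' @return `psms` with six reporter intensity columns appended.
#' @export
attach_reporters <- function(psms, merged) {
  scans <- vapply(merged, `[[`, integer(1), "scan_number")
  rep_mat <- do.call(rbind, lapply(merged, `[[`, "reporter_intensities"))
  hit <- match(psms$scan, scans)
  out <- psms
  for (ch in colnames(rep_mat)) {
    out[[paste0("ch", ch)]] <- rep_mat[hit, ch]
  }
  out
}
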