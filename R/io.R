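#' Construct a fragmentation spectrum
#'
#' @param scan_number Integer scan number, unique within a run.
#' @param mode `"CID"` or `"HCD"`.
#' @param precursor_mz Precursor m/z (Th).
#' @param precursor_charge Integer charge state.
#' @param mz,intensity Parallel numeric peak vectors; stored sorted by m/z.
#' @return List of class `spectrum`.
#' @export
spectrum <- function(scan_number, mode, precursor_mz, precursor_charge,
                     mz, intensity) {
  stopifnot(mode %in% c("CID", "HCD"), length(mz) == length(intensity),
            all(intensity >= 0))
  o <- order(mz)
  structure(list(
    scan_number = as.integer(scan_number), mode = mode,
    precursor_mz = precursor_mz, precursor_charge = as.integer(precursor_charge),
    mz = mz[o], intensity = intensity[o]
  ), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<%s scan %d> precursor %.5f (%d+), %d peaks\n",
              x$mode, x$scan_number, x$precursor_mz, x$precursor_charge,
              length(x$mz)))
  invisible(x)
}

#' Write spectra to a Mascot generic format (MGF) file
#'
#' One `BEGIN IONS` block per spectrum; the TITLE line encodes the scan
#' number and fragmentation mode as `scan=N mode=CID|HCD`.  Numeric fields
#' are printed with fixed formatting so identical inputs give identical
#' bytes.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- vapply(spectra, function(s) {
    peaks <- if (length(s$mz) > 0L)
      paste(sprintf("%.5f %.4f", s$mz, s$intensity), collapse = "\n")
    else ""
    paste0(
      "BEGIN IONS\n",
      sprintf("TITLE=scan=%d mode=%s\n", s$scan_number, s$mode),
      sprintf("PEPMASS=%.5f\n", s$precursor_mz),
      sprintf("CHARGE=%d+\n", s$precursor_charge),
      peaks, if (nzchar(peaks)) "\n" else "",
      "END IONS"
    )
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with TITLE, PEPMASS and CHARGE
#' headers and peak lines of `m/z intensity`.  Scan number and mode are
#' recovered from `scan=` / `mode=` tokens in the TITLE when present,
#' otherwise scans are numbered in file order with mode `"CID"`.
#'
#' @param path MGF file path.
#' @return List of [spectrum()] objects in file order.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE) & !grepl("^[0-9]", block)
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pepmass <- as.numeric(strsplit(
      sub("^PEPMASS=", "", grep("^PEPMASS=", block, value = TRUE)[1]), " ")[[1]][1])
    charge_line <- grep("^CHARGE=", block, value = TRUE)
    charge <- if (length(charge_line) > 0L)
      as.integer(sub("\\+$", "", sub("^CHARGE=", "", charge_line[1]))) else NA_integer_
    scan <- if (grepl("scan=\\d+", title))
      as.integer(sub(".*scan=(\\d+).*", "\\1", title)) else i
    mode <- if (grepl("mode=(CID|HCD)", title))
      sub(".*mode=(CID|HCD).*", "\\1", title) else "CID"
    peaks <- block[!hdr & nzchar(block)]
    if (length(peaks) > 0L) {
      mat <- do.call(rbind, strsplit(trimws(peaks), "[ \t]+"))
      mz <- as.numeric(mat[, 1]); int <- as.numeric(mat[, 2])
    } else {
      mz <- numeric(); int <- numeric()
    }
    spectrum(scan, mode, pepmass, charge, mz, int)
  })
}

#' Write proteins to FASTA
#'
#' @param proteins `ProteinRecord` `data.frame`.
#' @param path Output path; sequences wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta_proteins <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                           paste(proteins$accession,
                                                 proteins$description)))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read proteins from FASTA
#'
#' Accessions prefixed `REV_` are flagged as decoys.
#'
#' @param path FASTA file path.
#' @return `ProteinRecord` `data.frame` (`accession`, `description`,
#'   `sequence`, `is_decoy`).
#' @export
read_fasta_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  nm <- names(seqs)
  acc <- sub("[ \t].*$", "", nm)
  desc <- ifelse(grepl("[ \t]", nm), sub("^[^ \t]+[ \t]+", "", nm), "")
  data.frame(
    accession = acc, description = desc,
    sequence = as.character(seqs),
    is_decoy = startsWith(acc, "REV_"),
    stringsAsFactors = FALSE
  )
}
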