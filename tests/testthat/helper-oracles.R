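# Independent brute-force oracles and small fixture builders used across
# the test files.

# O(n^2) digest oracle: a substring [i, j] is a tryptic peptide with m
# missed cleavages iff its N-terminal boundary is the protein start or a
# cleavage site, its C-terminal boundary is the protein end or a cleavage
# site, and it spans exactly m internal cleavage sites.  Cleavage sites
# are positions after K/R not followed by P.
brute_force_digest <- function(sequence, max_missed_cleavages) {
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(res)
  is_site <- function(i) {
    i >= 1L && i < n && res[i] %in% c("K", "R") && res[i + 1L] != "P"
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!(i == 1L || is_site(i - 1L))) next
      if (!(j == n || is_site(j))) next
      internal <- if (j > i) sum(vapply((i):(j - 1L), is_site, logical(1))) else 0L
      if (internal <= max_missed_cleavages) {
        out[[length(out) + 1L]] <- data.frame(
          peptide = substr(sequence, i, j), start = i, end = j,
          missed_cleavages = internal, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

random_protein <- function(len) {
  aa <- c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
          "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Spectrum carrying exactly the b/y ladder of a peptide (unit intensity).
ladder_spectrum <- function(peptide, scan = 1L, charge = 2L, ...) {
  ladder <- fragment_ladder(peptide, ...)
  spectrum(scan, "CID", precursor_mz(peptide_mass(peptide, ...), charge),
           charge, ladder, rep(1, length(ladder)))
}

# Minimal PSM table for aggregation tests: one row per scan with explicit
# reporter intensities (a named list of six-vectors keyed 126..131).
psm_table <- function(accessions, intensities) {
  stopifnot(length(accessions) == length(intensities))
  rows <- lapply(seq_along(accessions), function(i) {
    v <- intensities[[i]]
    df <- data.frame(scan = i, accessions = accessions[i],
                     stringsAsFactors = FALSE)
    for (k in seq_along(v)) df[[paste0("ch", names(v)[k])]] <- v[[k]]
    df
  })
  do.call(rbind, rows)
}

# Quant table row in the shape intersect_sets() expects.
quant_row <- function(accession, log2_ir, log2_tale, n_spectra = 5L,
                      qc_pass = TRUE) {
  data.frame(accession = accession, n_spectra = n_spectra,
             qc_pass = qc_pass,
             log2_ir_vs_sham = log2_ir, log2_tale_vs_ir = log2_tale,
             stringsAsFactors = FALSE)
}
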