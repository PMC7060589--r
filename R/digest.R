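#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminal to lysine and arginine, except
#' when the following residue is proline, and enumerates every peptide
#' with up to `max_missed_cleavages` internal uncut sites.
#'
#' @param sequence Protein sequence (uppercase one-letter codes).
#' @param max_missed_cleavages Maximum internal K/R sites left uncut
#'   (0 to 3 is the usual range).
#' @return `data.frame` with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`; one row per (sequence, position) pair.
#' @examples
#' digest_protein("ACKDEFRGH", max_missed_cleavages = 1)
#' @export
digest_protein <- function(sequence, max_missed_cleavages = 3L) {
  res <- .check_sequence(sequence)
  n <- length(res)
  stopifnot(max_missed_cleavages >= 0L)
  # internal cleavage: after position i when res[i] is K/R, i < n,
  # and res[i+1] is not P
  kr <- which(res %in% c("K", "R"))
  sites <- kr[kr < n & res[pmin(kr + 1L, n)] != "P"]
  bounds <- c(0L, sites, n)
  nseg <- length(bounds) - 1L
  out <- vector("list", max_missed_cleavages + 1L)
  for (mc in 0:max_missed_cleavages) {
    k <- nseg - mc
    if (k < 1L) break
    i <- seq_len(k)
    start <- bounds[i] + 1L
    end <- bounds[i + mc + 1L]
    out[[mc + 1L]] <- data.frame(
      peptide = substring(sequence, start, end),
      start = start, end = end, missed_cleavages = mc,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Reversed-sequence decoy proteins
#'
#' Builds decoy entries by reversing each target sequence and prefixing the
#' accession with `REV_`, for target-decoy FDR estimation.
#'
#' @param proteins `data.frame` with columns `accession`, `description`,
#'   `sequence`, `is_decoy`; all rows must be targets.
#' @return `data.frame` of the same shape flagged as decoys.
#' @export
reverse_decoy <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  if (!is.null(proteins$is_decoy) && any(proteins$is_decoy)) {
    stop("input already contains decoy proteins", call. = FALSE)
  }
  rev_one <- function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }
  data.frame(
    accession = paste0("REV_", proteins$accession),
    description = if (is.null(proteins$description)) "" else
      paste("decoy of", proteins$accession),
    sequence = vapply(proteins$sequence, rev_one, character(1),
                      USE.NAMES = FALSE),
    is_decoy = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Search configuration
#'
#' Tolerances and filters of the identification stage: 25 ppm precursor
#' and 600 ppm fragment windows, trypsin with up to three missed
#' cleavages, decoy-estimated FDR below 0.01 and at least two distinct
#' spectra per reported protein.
#'
#' @param precursor_tol_ppm Precursor mass window, ppm.
#' @param fragment_tol_ppm Fragment ion window, ppm.
#' @param max_missed_cleavages Trypsin missed-cleavage cap.
#' @param fdr_threshold Decoy-estimated FDR cutoff (strict `<`).
#' @param min_peptides_per_protein Minimum distinct accepted spectra for a
#'   protein identification.
#' @param charges Precursor charge states considered.
#' @param max_oxidation Cap on variable methionine oxidations per peptide.
#' @return List of class `search_config`.
#' @export
search_config <- function(precursor_tol_ppm = 25, fragment_tol_ppm = 600,
                          max_missed_cleavages = 3L, fdr_threshold = 0.01,
                          min_peptides_per_protein = 2L, charges = c(2L, 3L),
                          max_oxidation = 2L) {
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            fdr_threshold > 0, fdr_threshold < 1,
            min_peptides_per_protein >= 1L, all(charges >= 1L))
  structure(list(
    precursor_tol_ppm = precursor_tol_ppm,
    fragment_tol_ppm = fragment_tol_ppm,
    max_missed_cleavages = as.integer(max_missed_cleavages),
    fdr_threshold = fdr_threshold,
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    charges = as.integer(charges),
    max_oxidation = as.integer(max_oxidation)
  ), class = "search_config")
}

# All oxidation-site subsets of the M positions of a peptide, capped.
.ox_states <- function(sequence, max_oxidation) {
  m_pos <- which(strsplit(sequence, "", fixed = TRUE)[[1L]] == "M")
  states <- list(integer())
  if (length(m_pos) == 0L || max_oxidation == 0L) return(states)
  for (k in seq_len(min(length(m_pos), max_oxidation))) {
    combos <- if (length(m_pos) == 1L) list(m_pos) else
      utils::combn(m_pos, k, simplify = FALSE)
    states <- c(states, combos)
  }
  states
}

#' Build the target+decoy peptide search space
#'
#' Digests targets and reversed decoys, applies the static TMT (N-terminus
#' and K) and carbamidomethyl (C) modifications, enumerates variable
#' methionine-oxidation states, and computes modified monoisotopic masses.
#' Peptides shared between proteins are collapsed to one candidate
#' carrying every parent accession.
#'
#' @param proteins Target `ProteinRecord` `data.frame` (see
#'   [generate_proteome()] or [read_fasta_proteins()]).
#' @param config A [search_config()].
#' @param append_decoys Append reversed decoys before digesting.
#' @return `data.frame` of peptide candidates: `peptide`, `ox_sites`
#'   (comma-joined positions, `""` for none), `mono_mass`,
#'   `missed_cleavages`, `accessions` (`;`-joined), `from_decoy`.
#' @export
build_search_space <- function(proteins, config = search_config(),
                               append_decoys = TRUE) {
  stopifnot(is.data.frame(proteins), nrow(proteins) > 0L)
  all_prot <- proteins
  if (append_decoys) all_prot <- rbind(
    proteins[, c("accession", "description", "sequence", "is_decoy")],
    reverse_decoy(proteins)
  )
  per_prot <- lapply(seq_len(nrow(all_prot)), function(i) {
    d <- digest_protein(all_prot$sequence[i], config$max_missed_cleavages)
    d$accession <- all_prot$accession[i]
    d$from_decoy <- all_prot$is_decoy[i]
    d
  })
  pep <- do.call(rbind, per_prot)
  # collapse shared peptides: one candidate per sequence, all parents kept
  key <- pep$peptide
  acc <- vapply(split(pep$accession, key), function(a)
    paste(sort(unique(a)), collapse = ";"), character(1))
  dec <- vapply(split(pep$from_decoy, key), all, logical(1))
  mc <- vapply(split(pep$missed_cleavages, key), min, integer(1))
  uniq <- names(acc)
  base_mass <- vapply(uniq, peptide_mass, numeric(1), USE.NAMES = FALSE)
  ox_states <- lapply(uniq, .ox_states, max_oxidation = config$max_oxidation)
  n_states <- lengths(ox_states)
  idx <- rep.int(seq_along(uniq), n_states)
  ox_flat <- unlist(ox_states, recursive = FALSE)
  data.frame(
    peptide = uniq[idx],
    ox_sites = vapply(ox_flat, paste, character(1), collapse = ","),
    mono_mass = base_mass[idx] +
      lengths(ox_flat) * MET_OXIDATION_DELTA,
    missed_cleavages = mc[idx],
    accessions = unname(acc[idx]),
    from_decoy = unname(dec[idx]),
    stringsAsFactors = FALSE
  )
}
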