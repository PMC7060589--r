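#' Precursor-window candidate matching
#'
#' Returns the candidates whose theoretical m/z at the spectrum's charge is
#' within the ppm tolerance of the observed precursor; ppm error is
#' `1e6 * (obs - theo) / theo`.
#'
#' @param observed_mz Observed precursor m/z (Th).
#' @param charge Observed precursor charge; an error if missing/NA.
#' @param candidates Search-space `data.frame` from [build_search_space()].
#' @param config A [search_config()].
#' @return Subset of `candidates` with an extra `ppm_error` column.
#' @export
match_precursor <- function(observed_mz, charge, candidates,
                            config = search_config()) {
  if (is.na(charge)) stop("spectrum has no precursor charge", call. = FALSE)
  if (nrow(candidates) == 0L) {
    candidates$ppm_error <- numeric()
    return(candidates)
  }
  theo <- precursor_mz(candidates$mono_mass, charge)
  ppm <- 1e6 * (observed_mz - theo) / theo
  keep <- abs(ppm) <= config$precursor_tol_ppm
  out <- candidates[keep, , drop = FALSE]
  out$ppm_error <- ppm[keep]
  out
}

#' Matched-ion-fraction PSM score
#'
#' Fraction of the peptide's theoretical singly charged b/y ions that are
#' matched by an observed peak within the fragment ppm tolerance, with
#' each observed peak allowed to match at most one theoretical ion
#' (greedy, ascending m/z).  A peptide of length 1 has no internal
#' fragments and scores 0 with a warning.
#'
#' @param peaks_mz Observed fragment m/z values (any order).
#' @param theoretical_mz Theoretical b/y ladder (from [fragment_ladder()]).
#' @param fragment_tol_ppm Fragment window, ppm.
#' @return Score in `[0, 1]`.
#' @export
score_psm <- function(peaks_mz, theoretical_mz, fragment_tol_ppm = 600) {
  if (length(theoretical_mz) == 0L) {
    warning("peptide has no internal fragments; score 0", call. = FALSE)
    return(0)
  }
  if (length(peaks_mz) == 0L) return(0)
  obs <- sort(peaks_mz)
  theo <- sort(theoretical_mz)
  tol <- fragment_tol_ppm * 1e-6
  used <- logical(length(obs))
  matched <- 0L
  ptr <- 1L
  for (t in theo) {
    lo <- t * (1 - tol); hi <- t * (1 + tol)
    while (ptr <= length(obs) && obs[ptr] < lo) ptr <- ptr + 1L
    k <- ptr
    while (k <= length(obs) && obs[k] <= hi) {
      if (!used[k]) {
        used[k] <- TRUE
        matched <- matched + 1L
        break
      }
      k <- k + 1L
    }
  }
  matched / length(theo)
}

#' Assign spectra to peptides
#'
#' For every CID (or merged) spectrum, matches candidates in the precursor
#' window and keeps the best-scoring peptide (ties broken by smaller
#' absolute precursor error).  Spectra with no candidate or a zero score
#' are not reported.
#'
#' @param spectra List of [spectrum()] objects; only `mode == "CID"` scans
#'   are searched.
#' @param candidates Search space from [build_search_space()].
#' @param config A [search_config()].
#' @return PSM `data.frame`: `scan`, `peptide`, `ox_sites`, `accessions`,
#'   `score`, `ppm_error`, `from_decoy`.
#' @export
search_spectra <- function(spectra, candidates, config = search_config()) {
  cand <- candidates[order(candidates$mono_mass), , drop = FALSE]
  ladder_cache <- new.env(parent = emptyenv())
  get_ladder <- function(pep, ox) {
    key <- paste0(pep, "|", ox)
    if (!is.null(ladder_cache[[key]])) return(ladder_cache[[key]])
    sites <- if (nzchar(ox)) as.integer(strsplit(ox, ",")[[1]]) else integer()
    l <- fragment_ladder(pep, ox_sites = sites)
    ladder_cache[[key]] <- l
    l
  }
  rows <- vector("list", length(spectra))
  n <- 0L
  for (s in spectra) {
    if (s$mode != "CID") next
    if (is.na(s$precursor_charge) ||
        !(s$precursor_charge %in% config$charges)) next
    # binary-search the sorted mass vector for the precursor window
    neutral <- (s$precursor_mz - PROTON_MASS) * s$precursor_charge
    tol <- config$precursor_tol_ppm * 1e-6
    lo <- findInterval(neutral * (1 - tol) - 1e-9, cand$mono_mass) + 1L
    hi <- findInterval(neutral * (1 + tol) + 1e-9, cand$mono_mass)
    if (hi < lo) next
    sub <- match_precursor(s$precursor_mz, s$precursor_charge,
                           cand[lo:hi, , drop = FALSE], config)
    if (nrow(sub) == 0L) next
    scores <- vapply(seq_len(nrow(sub)), function(i) {
      ladder <- get_ladder(sub$peptide[i], sub$ox_sites[i])
      if (length(ladder) == 0L) return(0)  # no internal fragments
      score_psm(s$mz, ladder, config$fragment_tol_ppm)
    }, numeric(1))
    best <- order(-scores, abs(sub$ppm_error))[1L]
    if (scores[best] <= 0) next
    n <- n + 1L
    rows[[n]] <- data.frame(
      scan = s$scan_number, peptide = sub$peptide[best],
      ox_sites = sub$ox_sites[best], accessions = sub$accessions[best],
      score = scores[best], ppm_error = sub$ppm_error[best],
      from_decoy = sub$from_decoy[best], stringsAsFactors = FALSE
    )
  }
  if (n == 0L) {
    return(data.frame(scan = integer(), peptide = character(),
                      ox_sites = character(), accessions = character(),
                      score = numeric(), ppm_error = numeric(),
                      from_decoy = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Target-decoy FDR filtering with a two-peptide protein rule
#'
#' Sweeps PSM scores from high to low and keeps the largest accepted set
#' whose decoy-estimated FDR `(# decoy PSMs) / (# target PSMs)` stays
#' below the threshold.  Proteins then require at least
#' `min_peptides_per_protein` distinct accepted spectra; decoys are used
#' for the estimate but removed from the report.  Proteins whose accepted
#' peptide sets are identical are collapsed to one representative
#' accession (alphabetically first), carrying the group members.
#'
#' @param psms PSM `data.frame` from [search_spectra()].
#' @param config A [search_config()].
#' @return List: `psms` (accepted target PSMs), `proteins` (`data.frame`
#'   of `accession`, `n_spectra`, `group_members`), `score_cutoff`,
#'   `fdr_estimate`.
#' @export
filter_by_fdr <- function(psms, config = search_config()) {
  empty <- list(
    psms = psms[0, , drop = FALSE],
    proteins = data.frame(accession = character(), n_spectra = integer(),
                          group_members = character()),
    score_cutoff = NA_real_, fdr_estimate = NA_real_
  )
  if (nrow(psms) == 0L) return(empty)
  o <- order(-psms$score)
  sorted <- psms[o, , drop = FALSE]
  cum_decoy <- cumsum(sorted$from_decoy)
  cum_target <- cumsum(!sorted$from_decoy)
  fdr <- ifelse(cum_target > 0, cum_decoy / cum_target, Inf)
  # only cut at the last index of each tied score so the accepted set is
  # exactly {score >= cutoff}
  last_of_score <- rev(!duplicated(rev(sorted$score)))
  ok <- which(last_of_score & fdr < config$fdr_threshold)
  if (length(ok) == 0L) return(empty)
  k <- max(ok)
  accepted <- sorted[seq_len(k), , drop = FALSE]
  cutoff <- sorted$score[k]
  fdr_est <- fdr[k]
  targets <- accepted[!accepted$from_decoy, , drop = FALSE]
  if (nrow(targets) == 0L) {
    empty$score_cutoff <- cutoff; empty$fdr_estimate <- fdr_est
    return(empty)
  }
  # protein evidence: distinct accepted spectra per accession
  acc_list <- strsplit(targets$accessions, ";", fixed = TRUE)
  idx <- rep.int(seq_len(nrow(targets)), lengths(acc_list))
  acc <- unlist(acc_list)
  acc <- acc[!startsWith(acc, "REV_")]
  idx <- idx[!startsWith(unlist(acc_list), "REV_")]
  scans_by_acc <- lapply(split(targets$scan[idx], acc), unique)
  peps_by_acc <- lapply(split(targets$peptide[idx], acc), function(p)
    paste(sort(unique(p)), collapse = "|"))
  n_spectra <- lengths(scans_by_acc)
  keep <- n_spectra >= config$min_peptides_per_protein
  accs <- names(scans_by_acc)[keep]
  pepsets <- unlist(peps_by_acc[keep])
  # collapse identical peptide sets to one representative accession
  groups <- split(accs, pepsets)
  reps <- vapply(groups, function(g) sort(g)[1], character(1))
  members <- vapply(groups, function(g) paste(sort(g), collapse = ";"),
                    character(1))
  prot <- data.frame(
    accession = unname(reps),
    n_spectra = unname(n_spectra[keep][match(reps, accs)]),
    group_members = unname(members),
    stringsAsFactors = FALSE
  )
  prot <- prot[order(prot$accession), , drop = FALSE]
  rownames(prot) <- NULL
  # keep target PSMs that support at least one accepted protein group and
  # rewrite their parent lists to the accepted representatives, so decoy
  # or below-evidence parents never reach quantification
  member_to_rep <- setNames(
    rep(prot$accession, lengths(strsplit(prot$group_members, ";", fixed = TRUE))),
    unlist(strsplit(prot$group_members, ";", fixed = TRUE)))
  new_acc <- vapply(strsplit(targets$accessions, ";", fixed = TRUE),
                    function(a) {
                      reps <- unique(stats::na.omit(member_to_rep[a]))
                      paste(sort(reps), collapse = ";")
                    }, character(1))
  targets$accessions <- new_acc
  list(
    psms = targets[nzchar(new_acc), , drop = FALSE],
    proteins = prot,
    score_cutoff = cutoff,
    fdr_estimate = fdr_est
  )
}
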