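# Run an expression with a fixed RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Study conditions for the synthetic three-group, six-channel TMT
#' experiment: two duplicate labels per group (sham 126/129, IR 127/130,
#' TALE 128/131), two independent MS replicate sets, multiplicative
#' log-normal intensity noise, and a configurable fraction of proteins
#' carrying true group effects.
#'
#' @param n_proteins Number of target proteins to simulate.
#' @param frac_de_ir Fraction of proteins with a true IR-vs-sham effect.
#' @param frac_de_tale Fraction of the IR-affected proteins that
#'   additionally carry a TALE-vs-IR effect.
#' @param effect_log2 Magnitude of true effects on the log2 scale.
#' @param noise_sigma Standard deviation (natural log) of the
#'   multiplicative log-normal noise applied to every reporter intensity.
#' @param duplicate_sigma Extra log-normal spread between the two
#'   duplicate channels of the same sample.
#' @param n_sets Number of independent MS replicate sets.
#' @param seed Integer seed fixing every downstream draw.
#' @param qc_failure_frac Fraction of proteins injected with one duplicate
#'   channel scaled so its duplicate variation exceeds 30%.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 100L, frac_de_ir = 0.2,
                              frac_de_tale = 0.5, effect_log2 = 1.0,
                              noise_sigma = 0.1, duplicate_sigma = 0.05,
                              n_sets = 2L, seed = 1L, qc_failure_frac = 0) {
  stopifnot(n_proteins >= 1L,
            frac_de_ir >= 0, frac_de_ir <= 1,
            frac_de_tale >= 0, frac_de_tale <= 1,
            qc_failure_frac >= 0, qc_failure_frac <= 1,
            noise_sigma >= 0, duplicate_sigma >= 0, n_sets >= 1L)
  structure(list(
    n_proteins = as.integer(n_proteins), frac_de_ir = frac_de_ir,
    frac_de_tale = frac_de_tale, effect_log2 = effect_log2,
    noise_sigma = noise_sigma, duplicate_sigma = duplicate_sigma,
    n_sets = as.integer(n_sets), seed = as.integer(seed),
    qc_failure_frac = qc_failure_frac
  ), class = "simulation_config")
}

# Quantifiable peptides of one protein: fully cleaved tryptic peptides of
# at least 6 residues whose TMT/carbamidomethyl-modified mass falls in
# [600, 4000] Da (shorter peptides carry too few fragments to identify).
.quant_peptides <- function(sequence) {
  d <- digest_protein(sequence, max_missed_cleavages = 0L)
  mass <- vapply(d$peptide, peptide_mass, numeric(1), USE.NAMES = FALSE)
  d$mono_mass <- mass
  d[mass >= 600 & mass <= 4000 & nchar(d$peptide) >= 6L, , drop = FALSE]
}

#' Generate a synthetic proteome
#'
#' Draws random protein sequences over the 20 standard amino acids with
#' lengths between 50 and 500.  Each sequence is rejection-sampled until it
#' has at least three tryptic cleavage sites, at least four fully cleaved
#' peptides, and at least three quantifiable peptides (length >= 6,
#' modified mass in the simulated precursor range), so every protein can
#' satisfy the two-peptide evidence rule downstream with a spectrum to
#' spare.
#'
#' @param config A [simulation_config()].
#' @return `ProteinRecord` `data.frame` with `n_proteins` target rows.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_proteins < 1L) stop("n_proteins must be >= 1", call. = FALSE)
  aa <- names(AA_MONO)
  with_seed(config$seed, {
    seqs <- character(config$n_proteins)
    for (i in seq_len(config$n_proteins)) {
      repeat {
        len <- sample(50:500, 1L)
        s <- paste(sample(aa, len, replace = TRUE), collapse = "")
        d0 <- digest_protein(s, 0L)
        if (nrow(d0) >= 4L && nrow(.quant_peptides(s)) >= 3L) break
      }
      seqs[i] <- s
    }
    data.frame(
      accession = sprintf("SYN%04d", seq_len(config$n_proteins)),
      description = "synthetic protein",
      sequence = seqs, is_decoy = FALSE,
      stringsAsFactors = FALSE
    )
  })
}

#' Assign ground-truth abundance effects
#'
#' Gives `round(frac_de_ir * n)` proteins an IR-vs-sham multiplier of
#' `2^(+-effect_log2)` (half up, half down, ties to up); among those,
#' `round(frac_de_tale * n_ir)` additionally receive a TALE-vs-IR effect.
#' All remaining multipliers are 1, so null proteins have equal abundance
#' in every group.
#'
#' @param proteins `ProteinRecord` `data.frame` of targets.
#' @param config A [simulation_config()].
#' @return `data.frame` with `accession`, linear `mult_sham`, `mult_ir`,
#'   `mult_tale`, and labels `true_label_ir`, `true_label_tale` in
#'   `{"up","down","null"}`.
#' @export
assign_ground_truth <- function(proteins, config) {
  n <- nrow(proteins)
  n_ir <- round(config$frac_de_ir * n)
  with_seed(config$seed + 1L, {
    ir_idx <- if (n_ir > 0L) sample(n, n_ir) else integer()
    n_up <- ceiling(n_ir / 2)
    up_idx <- ir_idx[seq_len(n_up)]
    down_idx <- setdiff(ir_idx, up_idx)
    mult_ir <- rep(1, n)
    mult_ir[up_idx] <- 2^config$effect_log2
    mult_ir[down_idx] <- 2^(-config$effect_log2)
    n_tale <- round(config$frac_de_tale * n_ir)
    tale_idx <- if (n_tale > 0L) sample(ir_idx, n_tale) else integer()
    n_tale_up <- ceiling(n_tale / 2)
    tale_up <- tale_idx[seq_len(n_tale_up)]
    tale_down <- setdiff(tale_idx, tale_up)
    tale_factor <- rep(1, n)
    tale_factor[tale_up] <- 2^config$effect_log2
    tale_factor[tale_down] <- 2^(-config$effect_log2)
    lab <- function(f) ifelse(f > 1, "up", ifelse(f < 1, "down", "null"))
    data.frame(
      accession = proteins$accession,
      mult_sham = 1,
      mult_ir = mult_ir,
      mult_tale = mult_ir * tale_factor,
      true_label_ir = lab(mult_ir),
      true_label_tale = lab(tale_factor),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate paired CID/HCD spectra
#'
#' For every quantifiable peptide of every protein, emits a CID scan
#' carrying the peptide's singly charged b/y fragment ladder (unit
#' intensities, no reporter region) immediately followed by an HCD scan
#' with the same precursor m/z carrying the six TMT reporter peaks.
#' Reporter intensity is `base * group multiplier * duplicate factor *
#' lognormal(0, noise_sigma)`; the peptide base intensity is drawn
#' log-uniform in `[1e4, 1e6]`, the duplicate factor is a per-protein,
#' per-channel log-normal draw with spread `duplicate_sigma`, and each
#' replicate set re-draws the noise from a set-specific sub-seed while
#' sharing the same truth.  `qc_failure_frac` of the proteins get one
#' duplicate channel scaled by 1.5 in every set, which forces that group's
#' duplicate variation above 30%.
#'
#' @param proteins Target proteome.
#' @param truth Ground truth from [assign_ground_truth()].
#' @param config A [simulation_config()].
#' @param design A [channel_design()].
#' @return List with one element per replicate set, each a list of
#'   [spectrum()] objects (alternating CID/HCD), plus attributes
#'   `peptide_truth` (scan-to-peptide map) and `qc_failure` (accessions).
#' @export
simulate_spectra <- function(proteins, truth, config,
                             design = channel_design()) {
  stopifnot(nrow(proteins) > 0L)
  truth <- truth[match(proteins$accession, truth$accession), ]
  channels <- design$channel
  group_of <- setNames(design$group, design$channel)
  mult <- cbind(sham = truth$mult_sham, IR = truth$mult_ir,
                TALE = truth$mult_tale)

  # structural draws shared by both sets: peptide tables, base intensities,
  # charges, duplicate factors' channel choice for injected QC failures
  structural <- with_seed(config$seed + 2L, {
    peps <- lapply(proteins$sequence, .quant_peptides)
    n_pep <- vapply(peps, nrow, integer(1))
    base <- lapply(n_pep, function(k) 10^runif(k, 4, 6))
    charge <- lapply(n_pep, function(k) sample(c(2L, 3L), k, replace = TRUE))
    n_fail <- round(config$qc_failure_frac * nrow(proteins))
    fail_idx <- if (n_fail > 0L) sample(nrow(proteins), n_fail) else integer()
    fail_channel <- if (n_fail > 0L)
      sample(channels, n_fail, replace = TRUE) else character()
    list(peps = peps, base = base, charge = charge,
         fail_idx = fail_idx, fail_channel = fail_channel)
  })

  sets <- vector("list", config$n_sets)
  for (s in seq_len(config$n_sets)) {
    sets[[s]] <- with_seed(config$seed + 100L + s, {
      scans <- list()
      scan_map <- list()
      scan_no <- 0L
      for (i in seq_len(nrow(proteins))) {
        pe <- structural$peps[[i]]
        if (nrow(pe) == 0L) next
        # per-protein per-channel duplicate factor, redrawn per set
        dup <- exp(rnorm(length(channels), 0, config$duplicate_sigma))
        names(dup) <- channels
        fail_pos <- match(i, structural$fail_idx)
        if (!is.na(fail_pos)) {
          ch <- structural$fail_channel[fail_pos]
          dup[ch] <- dup[ch] * 1.5
        }
        for (j in seq_len(nrow(pe))) {
          pep <- pe$peptide[j]
          z <- structural$charge[[i]][j]
          mz <- precursor_mz(pe$mono_mass[j], z)
          ladder <- fragment_ladder(pep)
          scan_no <- scan_no + 1L
          cid <- spectrum(scan_no, "CID", mz, z, ladder,
                          rep(1, length(ladder)))
          rep_int <- structural$base[[i]][j] *
            mult[i, group_of[channels]] * dup[channels] *
            exp(rnorm(length(channels), 0, config$noise_sigma))
          scan_no <- scan_no + 1L
          hcd <- spectrum(scan_no, "HCD", mz, z,
                          unname(TMT6_REPORTER_MZ[channels]),
                          unname(rep_int))
          scans[[length(scans) + 1L]] <- cid
          scans[[length(scans) + 1L]] <- hcd
          scan_map[[length(scan_map) + 1L]] <- data.frame(
            cid_scan = cid$scan_number, hcd_scan = hcd$scan_number,
            accession = proteins$accession[i], peptide = pep,
            stringsAsFactors = FALSE
          )
        }
      }
      structure(scans, peptide_truth = do.call(rbind, scan_map))
    })
  }
  structure(sets,
            peptide_truth = attr(sets[[1]], "peptide_truth"),
            qc_failure = proteins$accession[structural$fail_idx])
}

#' Write ground truth to TSV
#'
#' @param truth Ground-truth `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
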