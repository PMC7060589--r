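test_that("proteome generation is seeded and bounded", {
  cfg <- simulation_config(n_proteins = 5, seed = 7)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta_proteins(p1, f1); write_fasta_proteins(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # lengths within [50, 500], at least four fully cleaved peptides each
  len <- nchar(p1$sequence)
  expect_true(all(len >= 50 & len <= 500))
  for (s in p1$sequence) {
    expect_gte(nrow(digest_protein(s, 0L)), 4)
  }
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
})

test_that("ground truth effects match the configured design", {
  cfg <- simulation_config(n_proteins = 100, frac_de_ir = 0.2,
                           frac_de_tale = 0.5, effect_log2 = 1, seed = 3)
  prot <- generate_proteome(cfg)
  truth <- assign_ground_truth(prot, cfg)
  expect_identical(sum(truth$mult_ir == 2), 10L)
  expect_identical(sum(truth$mult_ir == 0.5), 10L)
  expect_identical(sum(truth$true_label_ir == "null"), 80L)
  # TALE effects only among IR-affected proteins
  tale_affected <- truth$true_label_tale != "null"
  expect_identical(sum(tale_affected), 10L)
  expect_true(all(truth$true_label_ir[tale_affected] != "null"))
  # labels recomputed from multipliers equal stored labels
  relab_ir <- ifelse(truth$mult_ir > truth$mult_sham, "up",
                     ifelse(truth$mult_ir < truth$mult_sham, "down", "null"))
  expect_identical(relab_ir, truth$true_label_ir)
  relab_tale <- ifelse(truth$mult_tale > truth$mult_ir, "up",
                       ifelse(truth$mult_tale < truth$mult_ir, "down", "null"))
  expect_identical(relab_tale, truth$true_label_tale)
  # frac_de_ir = 0 gives all-null truth
  cfg0 <- simulation_config(n_proteins = 10, frac_de_ir = 0, seed = 3)
  t0 <- assign_ground_truth(generate_proteome(cfg0), cfg0)
  expect_true(all(t0$true_label_ir == "null"))
  expect_true(all(t0$mult_ir == 1 & t0$mult_tale == 1))
})

test_that("simulated scan streams have the paired CID/HCD structure", {
  cfg <- simulation_config(n_proteins = 4, frac_de_ir = 0.5, noise_sigma = 0,
                           duplicate_sigma = 0, seed = 11)
  prot <- generate_proteome(cfg)
  truth <- assign_ground_truth(prot, cfg)
  sets <- simulate_spectra(prot, truth, cfg)
  expect_length(sets, 2)
  scans <- sets[[1]]
  modes <- vapply(scans, `[[`, character(1), "mode")
  expect_true(all(modes == rep(c("CID", "HCD"), length(scans) / 2)))
  # every HCD precursor equals the preceding CID precursor
  for (i in seq(2, length(scans), by = 2)) {
    expect_identical(scans[[i]]$precursor_mz, scans[[i - 1]]$precursor_mz)
  }
  # CID scans carry no peaks in the reporter region; HCD carry exactly six
  for (i in seq_along(scans)) {
    if (scans[[i]]$mode == "CID") {
      expect_false(any(scans[[i]]$mz < 132 & scans[[i]]$mz > 125.5))
    } else {
      expect_identical(sort(scans[[i]]$mz), sort(unname(TMT6_REPORTER_MZ)))
    }
  }
  # precursor m/z consistent with the peptide's modified mass at charge 2/3
  pt <- attr(sets, "peptide_truth")
  by_scan <- setNames(scans, vapply(scans, `[[`, integer(1), "scan_number"))
  for (j in seq_len(nrow(pt))) {
    s <- by_scan[[as.character(pt$cid_scan[j])]]
    expect_true(s$precursor_charge %in% c(2L, 3L))
    expect_equal(s$precursor_mz,
                 precursor_mz(peptide_mass(pt$peptide[j]), s$precursor_charge),
                 tolerance = 1e-9)
  }
})

test_that("zero-noise reporter intensities reflect the multipliers exactly", {
  cfg <- simulation_config(n_proteins = 6, frac_de_ir = 0.5, effect_log2 = 1,
                           noise_sigma = 0, duplicate_sigma = 0, seed = 19)
  prot <- generate_proteome(cfg)
  truth <- assign_ground_truth(prot, cfg)
  sets <- simulate_spectra(prot, truth, cfg)
  pt <- attr(sets, "peptide_truth")
  scans <- sets[[1]]
  by_scan <- setNames(scans, vapply(scans, `[[`, integer(1), "scan_number"))
  for (j in seq_len(nrow(pt))) {
    hcd <- by_scan[[as.character(pt$hcd_scan[j])]]
    v <- extract_reporters(hcd)
    tr <- truth[truth$accession == pt$accession[j], ]
    # channels 127/130 = IR multiplier x channels 126/129 (sham)
    expect_equal(v[["127"]] / v[["126"]], tr$mult_ir, tolerance = 1e-9)
    expect_equal(v[["130"]] / v[["129"]], tr$mult_ir, tolerance = 1e-9)
    expect_equal(v[["128"]] / v[["127"]], tr$mult_tale / tr$mult_ir,
                 tolerance = 1e-9)
    # null proteins: all six equal
    if (tr$true_label_ir == "null") {
      expect_equal(max(v) / min(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("injected QC failures are the only proteins above 30% variation", {
  cfg <- simulation_config(n_proteins = 10, frac_de_ir = 0, noise_sigma = 0,
                           duplicate_sigma = 0, qc_failure_frac = 0.3,
                           seed = 23)
  prot <- generate_proteome(cfg)
  truth <- assign_ground_truth(prot, cfg)
  sets <- simulate_spectra(prot, truth, cfg)
  injected <- attr(sets, "qc_failure")
  expect_length(injected, 3)
  merged <- merge_scan_stream(sets[[1]])
  pt <- attr(sets, "peptide_truth")
  psms <- data.frame(scan = pt$cid_scan, accessions = pt$accession,
                     stringsAsFactors = FALSE)
  pq <- duplicate_qc(aggregate_protein(attach_reporters(psms, merged)))
  expect_setequal(pq$accession[!pq$qc_pass], injected)
})

test_that("MGF round-trip preserves the scan stream", {
  cfg <- simulation_config(n_proteins = 2, seed = 5)
  prot <- generate_proteome(cfg)
  truth <- assign_ground_truth(prot, cfg)
  sets <- simulate_spectra(prot, truth, cfg)
  path <- tempfile(fileext = ".mgf")
  write_mgf(sets[[1]], path)
  back <- read_mgf(path)
  expect_length(back, length(sets[[1]]))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$scan_number, sets[[1]][[i]]$scan_number)
    expect_identical(back[[i]]$mode, sets[[1]][[i]]$mode)
    expect_identical(back[[i]]$precursor_charge,
                     sets[[1]][[i]]$precursor_charge)
    expect_equal(back[[i]]$mz, sets[[1]][[i]]$mz, tolerance = 1e-4)
    expect_equal(back[[i]]$intensity, sets[[1]][[i]]$intensity,
                 tolerance = 1e-3)
  }
  # same seed, same bytes
  path2 <- tempfile(fileext = ".mgf")
  write_mgf(simulate_spectra(prot, truth, cfg)[[1]], path2)
  expect_identical(readLines(path), readLines(path2))
})
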