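hcd_with_peaks <- function(mz, intensity, scan = 2L) {
  spectrum(scan, "HCD", 500.25, 2L, mz, intensity)
}

test_that("CID/HCD pairing follows the preceding-scan rule", {
  cid <- function(scan, mz) spectrum(scan, "CID", mz, 2L, numeric(), numeric())
  hcd <- function(scan, mz) spectrum(scan, "HCD", mz, 2L, numeric(), numeric())
  # matching precursor pairs
  p <- pair_cid_hcd(list(cid(1, 500.25), hcd(2, 500.25)))
  expect_identical(p$pairs$cid_scan, 1L)
  expect_identical(p$pairs$hcd_scan, 2L)
  # mismatched precursor leaves both unpaired
  p2 <- pair_cid_hcd(list(cid(1, 500.25), hcd(2, 501.25)))
  expect_identical(nrow(p2$pairs), 0L)
  expect_setequal(p2$unpaired, c(1L, 2L))
  # interleaved pairs never cross
  p3 <- pair_cid_hcd(list(cid(1, 500.25), hcd(2, 500.25),
                          cid(3, 600.5), hcd(4, 600.5)))
  expect_identical(p3$pairs$cid_scan, c(1L, 3L))
  expect_identical(p3$pairs$hcd_scan, c(2L, 4L))
  expect_length(p3$unpaired, 0)
  # a second HCD claiming the same CID warns and is reported unpaired
  expect_warning(
    p4 <- pair_cid_hcd(list(cid(1, 500.25), hcd(2, 500.25), hcd(3, 500.25))),
    "more than one")
  expect_identical(p4$pairs$hcd_scan, 2L)
  expect_identical(p4$unpaired, 3L)
})

test_that("reporter extraction respects the 20 ppm window", {
  r126 <- TMT6_REPORTER_MZ[["126"]]
  # exact hit
  v <- extract_reporters(hcd_with_peaks(r126, 1000))
  expect_equal(v[["126"]], 1000)
  expect_true(all(is.na(v[c("127", "128", "129", "130", "131")])))
  # +25 ppm is outside, +15 ppm inside
  expect_true(is.na(extract_reporters(
    hcd_with_peaks(r126 * (1 + 25e-6), 1000))[["126"]]))
  expect_equal(extract_reporters(
    hcd_with_peaks(r126 * (1 + 15e-6), 1000))[["126"]], 1000)
  # two in-window peaks: the more intense one wins
  v2 <- extract_reporters(hcd_with_peaks(
    c(r126 * (1 - 10e-6), r126 * (1 + 10e-6)), c(300, 700)))
  expect_equal(v2[["126"]], 700)
  # brute-force check of the max-intensity rule over random peak sets
  set.seed(9)
  for (i in 1:10) {
    mz <- r126 * (1 + runif(5, -30e-6, 30e-6))
    int <- runif(5, 10, 1000)
    inside <- abs(mz - r126) <= r126 * 20e-6
    want <- if (any(inside)) max(int[inside]) else NA_real_
    expect_equal(extract_reporters(hcd_with_peaks(mz, int))[["126"]], want)
  }
})

test_that("merging inserts found reporters and preserves CID peaks", {
  cid <- spectrum(1L, "CID", 500.25, 2L, c(300.1, 400.2, 700.7), c(1, 2, 3))
  reporters <- setNames(c(100, 200, NA, 150, 120, NA), names(TMT6_REPORTER_MZ))
  merged <- merge_into_cid(cid, reporters)
  expect_length(merged$mz, 3 + 4)
  expect_true(all(c(300.1, 400.2, 700.7) %in% merged$mz))
  expect_false(is.unsorted(merged$mz))
  expect_identical(merged$reporter_intensities, reporters)
  # no reporters found: merged peaks equal the CID peaks
  none <- setNames(rep(NA_real_, 6), names(TMT6_REPORTER_MZ))
  expect_identical(merge_into_cid(cid, none)$mz, cid$mz)
})

test_that("protein aggregation averages channels and drops partial PSMs", {
  six <- function(x) setNames(x, c("126", "127", "128", "129", "130", "131"))
  psms <- psm_table(
    c("P1", "P1", "P2"),
    list(six(c(100, 200, 150, 100, 200, 150)),
         six(c(300, 400, 350, 300, 400, 350)),
         six(c(100, NA, 100, 100, 100, 100))))
  pq <- aggregate_protein(psms)
  p1 <- pq[pq$accession == "P1", ]
  expect_identical(p1$n_spectra, 2L)
  expect_equal(p1$ch126, 200)
  expect_equal(p1$ch127, 300)
  # group mean = mean of the two duplicate channels
  expect_equal(p1$mean_sham, (p1$ch126 + p1$ch129) / 2)
  expect_equal(p1$mean_IR, (p1$ch127 + p1$ch130) / 2)
  expect_equal(p1$mean_TALE, (p1$ch128 + p1$ch131) / 2)
  # P2's only PSM misses a channel: protein dropped, reason recorded
  expect_false("P2" %in% pq$accession)
  expect_true("P2" %in% attr(pq, "dropped"))
  # shared-peptide PSMs contribute to every parent
  shared <- psm_table("P1;P3", list(six(rep(100, 6))))
  pq2 <- aggregate_protein(shared)
  expect_setequal(pq2$accession, c("P1", "P3"))
})

test_that("duplicate QC excludes above 30% variation", {
  mk <- function(a, b) {
    six <- setNames(c(a, 100, 100, b, 100, 100),
                    c("126", "127", "128", "129", "130", "131"))
    duplicate_qc(aggregate_protein(psm_table("P", list(six))))
  }
  # |a-b|/mean: 0 retained, 40/120 = 0.333 excluded, 30/115 = 0.261 kept
  expect_true(mk(100, 100)$qc_pass)
  expect_false(mk(100, 140)$qc_pass)
  expect_true(mk(100, 130)$qc_pass)
  # both duplicates zero: variation undefined, excluded with reason
  z <- mk(0, 0)
  expect_false(z$qc_pass)
  expect_match(z$qc_reason, "undefined")
})

test_that("QC monotonicity: a looser threshold never excludes more", {
  set.seed(77)
  six_names <- c("126", "127", "128", "129", "130", "131")
  psms <- psm_table(sprintf("P%02d", 1:40), lapply(1:40, function(i)
    setNames(10^runif(6, 2, 4), six_names)))
  pq <- aggregate_protein(psms)
  thresholds <- c(0.1, 0.2, 0.3, 0.5, 0.8)
  passes <- vapply(thresholds, function(t)
    sum(duplicate_qc(pq, quant_config(duplicate_variation_max = t))$qc_pass),
    numeric(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("log2 contrasts behave as log ratios", {
  six <- function(x) setNames(x, c("126", "127", "128", "129", "130", "131"))
  # IR = 2x sham, TALE = IR
  pq <- quantify_proteins(psm_table("P", list(six(c(100, 200, 200, 100, 200, 200)))))
  expect_equal(pq$log2_ir_vs_sham, 1)
  expect_equal(pq$log2_tale_vs_ir, 0)
  # all groups equal: both contrasts zero
  pq0 <- quantify_proteins(psm_table("P", list(six(rep(150, 6)))))
  expect_equal(pq0$log2_ir_vs_sham, 0)
  expect_equal(pq0$log2_tale_vs_ir, 0)
  # scale invariance: scaling every intensity leaves contrasts unchanged
  pq_scaled <- quantify_proteins(psm_table("P", list(six(
    1000 * c(100, 200, 200, 100, 200, 200)))))
  expect_equal(pq_scaled$log2_ir_vs_sham, pq$log2_ir_vs_sham)
  expect_equal(pq_scaled$log2_tale_vs_ir, pq$log2_tale_vs_ir)
  # zero denominator: ratio undefined, protein flagged
  pqz <- quantify_proteins(psm_table("P", list(six(c(0, 100, 100, 0, 100, 100)))))
  expect_false(pqz$qc_pass)
})
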