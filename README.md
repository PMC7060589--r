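# tmtquant

Quantitative proteomics pipeline for **isobaric TMT six-plex** experiments
acquired as paired **CID–HCD dual scans**, aimed at three-group designs
with duplicate labels per group (e.g. a sham / ischemia-reperfusion (IR) /
dietary-intervention (TALE) cardiac study: sham on channels 126+129, IR on
127+130, TALE on 128+131). It is written for proteomics analysts who want
the full chain — identification, reporter quantification, quality control,
differential calling — as inspectable, testable R functions rather than a
black-box vendor pipeline, plus a synthetic-spectra generator with known
ground truth to validate every stage.

## The method

For each precursor, the instrument acquires a CID scan (sequence b/y ions)
followed by an HCD scan of the same precursor (TMT reporter ions at m/z
126–131). The pipeline:

1. digests the FASTA database with trypsin (cleavage after K/R, not before
   P, ≤3 missed cleavages), appends reversed-sequence decoys, and applies
   static TMT (+229.1629 Da, N-terminus and K), carbamidomethyl-C
   (+57.02146 Da) and variable Met oxidation (+15.9949 Da);
2. matches spectra to candidates within ±25 ppm of the precursor and
   scores each PSM as the fraction of theoretical singly charged b/y ions
   matched within ±600 ppm;
3. keeps the largest PSM set with decoy-estimated FDR
   (#decoys / #targets) < 0.01 and requires ≥2 distinct spectra per
   reported protein;
4. extracts the six reporter intensities from each HCD scan in ±20 ppm
   windows and inserts them into the paired CID scan; averages reporter
   intensities over all spectra of a protein subgroup; excludes proteins
   whose duplicate labels disagree by more than 30%
   (|a−b| / pair mean > 0.30); reports log2 group ratios;
5. intersects two independent replicate sets, averages their contrasts,
   and calls a protein differential when |mean log2 ratio| > 0.6 (strict)
   with ≥2 spectra; the TALE-vs-IR contrast is evaluated only among
   IR-related proteins;
6. optionally summarizes up/down lists as category percentages from a
   user-supplied annotation table.

## Worked example

```r
library(tmtquant)

cfg <- simulation_config(n_proteins = 30, frac_de_ir = 0.2,
                         noise_sigma = 0, duplicate_sigma = 0, seed = 42)
res <- run_pipeline(cfg)
str(res$counts)
#> List of 7
#>  $ n_common  : int 30
#>  $ ir_up     : int 3
#>  $ ir_down   : int 3
#>  $ ir_total  : int 6
#>  $ tale_up   : int 2
#>  $ tale_down : int 1
#>  $ tale_total: int 3
str(res$recovery)
#> List of 6
#>  $ ir_tp      : int 6
#>  $ ir_fp      : int 0
#>  $ ir_fn      : int 0
#>  $ ir_tn      : int 24
#>  $ sensitivity: num 1
#>  $ fdp        : num 0
```

All 30 simulated proteins survive both replicate sets (`n_common`); at
zero noise the six injected two-fold changes (3 up, 3 down) are called
exactly, with no false IR calls (`fdp = 0`), and the three injected
TALE effects are recovered among them. `run_pipeline(cfg, out_dir = "run")`
additionally writes the proteome FASTA, per-set MGF files, quantification
tables, the DE table and a JSON run manifest.

Individual stages are exported for use on real files: `read_mgf()` /
`read_fasta_proteins()`, `build_search_space()`, `merge_scan_stream()`,
`search_spectra()`, `filter_by_fdr()`, `attach_reporters()`,
`quantify_proteins()`, `intersect_sets()`, `call_ir_related()`,
`call_tale_affected()`, `summarize_categories()`.

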