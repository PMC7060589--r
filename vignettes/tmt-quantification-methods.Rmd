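---
title: "Methods: TMT six-plex quantification with paired CID-HCD scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TMT six-plex quantification with paired CID-HCD scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtquant)
```

## The experiment this package models

`tmtquant` implements the analysis of a three-group isobaric labeling
experiment on an LTQ-Orbitrap-class instrument: three biological samples
(a sham-operated control, an ischemia-reperfusion (IR) perturbation, and
a dietary-intervention (TALE) arm) are each labeled with **two** different
TMT six-plex reagents — sham on channels 126 and 129, IR on 127 and 130,
TALE on 128 and 131 — mixed, and acquired as data-dependent **CID-HCD dual
scans**: a CID scan providing sequence (b/y) ions for identification,
immediately followed by an HCD scan of the same precursor providing the
low-mass reporter ions for quantification. Two such LC-MS/MS replicate
sets are acquired independently.

The pipeline stages are:

1. **Digest and search space** — tryptic digestion (cleavage after K/R,
   suppressed before P, up to 3 missed cleavages) of the target protein
   database plus its reversed-sequence decoys; static TMT (+229.1629 Da
   at the N-terminus and every lysine) and carbamidomethyl-cysteine
   (+57.02146 Da) modifications, variable methionine oxidation
   (+15.9949 Da).
2. **Identification** — candidates within ±25 ppm of the observed
   precursor m/z (charges 2–3) are scored by the fraction of their
   theoretical singly charged b/y ions matched within ±600 ppm, each
   observed peak matching at most one theoretical ion. The best candidate
   per spectrum is the PSM.
3. **FDR filtering** — a descending-score sweep keeps the largest PSM set
   whose decoy-estimated FDR (decoy/target counts) stays below 0.01;
   reported proteins need at least two distinct accepted spectra, and
   proteins with identical accepted peptide sets collapse to one
   representative accession.
4. **Quantification** — the six reporter intensities are extracted from
   each HCD scan as the most intense peak within ±20 ppm of the canonical
   reporter m/z and inserted into the paired CID scan; protein channel
   means average all spectra of the protein subgroup; a protein is
   excluded when any group's duplicate labels differ by more than 30%
   (variation = |a−b| / pair mean); group ratios are reported on the log2
   scale.
5. **Differential calling** — proteins quantified in both replicate sets
   have their contrasts averaged; a protein is IR-related when its mean
   log2(IR/sham) exceeds ±0.6 (strict inequality) with at least two
   spectra of evidence; the TALE-vs-IR contrast is evaluated by the same
   rule, but only among IR-related proteins.
6. **Annotation summary** — up- and down-regulated lists are tabulated
   against a user-supplied accession→ontology→term table; percentages are
   shares of classified hits (a protein contributing one hit per matched
   term), not of proteins.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `precursor_tol_ppm` | 25 | ppm | precursor match window |
| `fragment_tol_ppm` | 600 | ppm | b/y ion match window |
| `max_missed_cleavages` | 3 | — | tryptic enumeration depth |
| `fdr_threshold` | 0.01 | — | decoy-estimated FDR cutoff (strict `<`) |
| `min_peptides_per_protein` | 2 | spectra | protein identification evidence |
| `reporter_window_ppm` | 20 | ppm | reporter extraction half-window |
| `duplicate_variation_max` | 0.30 | — | duplicate-label exclusion threshold |
| `log2_threshold` | 0.6 | log2 | fold-change call cutoff (strict `>`) |

The TMT six-plex reporter m/z values (126.12773, 127.13108, 128.13443,
129.13779, 130.14114, 131.13818) are the reagent's published monoisotopic
values. At m/z 126.128 the ±20 ppm window is ±0.0025 Th, narrow enough
that adjacent channels (spaced ≈1 Th, except 130→131 at ≈0.997 Th) can
never bleed into each other's windows.

## What the synthetic generator emulates — and what it does not

`simulation_config()` encodes the study conditions: six channels with
duplicate labels per group, two independent replicate sets sharing one
ground truth, a configurable fraction of proteins with true effects of
magnitude `effect_log2` (default 1.0, i.e. two-fold), multiplicative
log-normal reporter noise (`noise_sigma`, natural-log scale, default
0.1), an extra per-protein, per-channel duplicate-label spread
(`duplicate_sigma`, default 0.05), and an optional fraction of proteins
injected with a 1.5× scaling of one duplicate channel, which forces that
group's variation to 40% — above the 30% exclusion rule.

Structural choices, made once:

* **Proteomes** are uniform-random sequences of length 50–500,
  rejection-sampled so each has ≥3 cleavage sites, ≥4 fully cleaved
  peptides, and ≥3 *quantifiable* peptides (length ≥6, TMT-modified mass
  in [600, 4000] Da). This guarantees the two-spectrum evidence rule is
  satisfiable for every protein and that quantification averages over at
  least three spectra.
* **Spectra**: one CID/HCD pair per quantifiable peptide; CID scans carry
  the singly charged b/y ladder at unit intensity, HCD scans carry
  exactly the six reporter peaks. Peptide base intensity is log-uniform
  in [1e4, 1e6] so protein averaging is exercised across a realistic
  dynamic range; precursor charge is drawn from {2, 3}.
* **Replicate sets** re-draw all noise from set-specific sub-seeds
  derived from the master seed; base intensities, charges and the truth
  are shared.
* `frac_de_tale` is interpreted as the fraction *of the IR-affected
  proteins* that also carry a TALE-vs-IR effect, since the TALE contrast
  is only ever evaluated within the IR-related set.

Not emulated: isotope envelopes and channel impurity bleed-through,
retention time, chimeric spectra, fractionation, semi-tryptic peptides,
real amino-acid composition biases, and intensity-dependent (shot-noise)
variance. Passing the recovery tests therefore demonstrates the
*pipeline logic* — pairing, extraction, FDR control, QC, averaging,
thresholding — not robustness to the full messiness of instrument data.

## Numerical and design choices

* **PSM scoring** uses a matched-ion-fraction score rather than a
  cross-correlation: on synthetic ladders the contract is identification
  correctness, and the fraction score is exactly 1 for the generating
  peptide and sharply lower for others, which the FDR sweep handles
  cleanly. Ties are broken by smaller absolute precursor error.
* **FDR formula**: decoys/targets over the accepted set, one global
  sweep, cut only at score-tie boundaries so the accepted set is exactly
  `{score ≥ cutoff}`. With zero decoys the estimate is 0 and everything
  is accepted; an all-decoy input yields an empty result rather than an
  error.
* **Missing reporter channels**: a PSM missing any of the six reporters
  is excluded from aggregation entirely, keeping the six channel means
  comparable across spectra.
* **Duplicate variation** is `|a − b| / ((a + b)/2)` on the two duplicate
  channel means; a 0/0 pair is undefined and excluded with a recorded
  reason. QC runs at the protein level, after aggregation.
* **Shared peptides** are credited to every parent protein (no parsimony);
  proteins with identical accepted peptide sets are collapsed to the
  alphabetically first accession with the group members recorded.
* **Oxidation states** are enumerated per methionine subset, capped at 2
  per peptide — the usual search-engine default, and sufficient here
  because the generator never emits oxidized peptides.
* **Boundary conventions** are strict everywhere the thresholds are
  stated as strict: FDR `< 0.01`, fold change `> ±0.6`; the tolerance
  windows (ppm, variation) are inclusive.

## Problem sizes used in validation

The packaged tests simulate 80–100 proteins per run (several hundred
peptide spectra per replicate set), 20 seeded replicates for the noisy
recovery and FDR-calibration properties, and 200 random sequences for the
digestion oracle comparison; these sizes give stable pooled estimates
(±1–2% on sensitivity) while keeping a full test run to a few minutes.
At zero noise the pipeline recovers the injected truth exactly; at
`noise_sigma = 0.1` pooled sensitivity stays above 0.95 with essentially
no false calls, the residual misses coming from proteins that a noisy
duplicate pair pushes over the 30% QC rule in one replicate set.

## Known limitations

* The matched-ion-fraction scorer is not a drop-in for a production
  search engine; it is designed for ladder-like spectra.
* No isotopic impurity correction or between-channel normalization is
  applied; contrasts are raw ratio averages, as in the modeled workflow.
* The annotation summarizer consumes a static annotation snapshot;
  category percentages depend entirely on that table's term granularity.
* FDR is controlled at the PSM level with a protein evidence rule, not at
  the protein level.
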