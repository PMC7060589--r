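# Standard monoisotopic residue masses (Da) for the 20 amino acids,
# monoisotopic water and the proton mass used for m/z arithmetic.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

WATER_MONO <- 18.010565
PROTON_MASS <- 1.00727646

# Modification deltas (monoisotopic, Da).  TMT six-plex adds the same
# +229.1629 tag to the peptide N-terminus and to every lysine side chain.
TMT6_DELTA <- 229.1629
CARBAMIDOMETHYL_DELTA <- 57.02146
MET_OXIDATION_DELTA <- 15.9949

#' Canonical TMT six-plex reporter ion m/z values
#'
#' Monoisotopic m/z of the six low-mass reporter fragments released by the
#' TMT six-plex label on HCD fragmentation, keyed by nominal channel label.
#'
#' @format Named numeric vector of length 6 (names `"126"`..`"131"`).
#' @export
TMT6_REPORTER_MZ <- c(
  "126" = 126.12773, "127" = 127.13108, "128" = 128.13443,
  "129" = 129.13779, "130" = 130.14114, "131" = 131.13818
)

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(AA_MONO))
  if (length(bad) > 0L) {
    stop("invalid residue(s) in sequence: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  res
}

#' Per-residue modified masses of a peptide
#'
#' Returns the monoisotopic mass of each residue with the static and
#' variable modifications applied in place: TMT on every lysine,
#' carbamidomethyl on every cysteine, oxidation on the given methionine
#' positions.  The N-terminal TMT tag is returned separately because it
#' belongs to the b-ion series, not to a residue.
#'
#' @param sequence Peptide sequence (uppercase one-letter codes).
#' @param tmt Apply the TMT six-plex static modification (N-terminus and K).
#' @param carbamidomethyl Apply static carbamidomethylation of cysteine.
#' @param ox_sites Integer positions of oxidized methionines (may be empty).
#' @return List with `residues` (numeric vector) and `nterm` (scalar delta).
#' @keywords internal
residue_masses <- function(sequence, tmt = TRUE, carbamidomethyl = TRUE,
                           ox_sites = integer()) {
  res <- .check_sequence(sequence)
  m <- unname(AA_MONO[res])
  if (tmt) m[res == "K"] <- m[res == "K"] + TMT6_DELTA
  if (carbamidomethyl) m[res == "C"] <- m[res == "C"] + CARBAMIDOMETHYL_DELTA
  if (length(ox_sites) > 0L) {
    ox_sites <- as.integer(ox_sites)
    if (any(ox_sites < 1L | ox_sites > length(res)) ||
        any(res[ox_sites] != "M")) {
      stop("oxidation site is not a methionine residue", call. = FALSE)
    }
    m[ox_sites] <- m[ox_sites] + MET_OXIDATION_DELTA
  }
  list(residues = m, nterm = if (tmt) TMT6_DELTA else 0)
}

#' Monoisotopic peptide mass
#'
#' Mass of a peptide as the sum of its (modified) residue masses plus one
#' water, the standard neutral monoisotopic mass.  Modifications are
#' additive: the TMT six-plex tag contributes +229.1629 Da at the
#' N-terminus and at every lysine, carbamidomethylation +57.02146 Da at
#' every cysteine, and oxidation +15.9949 Da per chosen methionine.
#'
#' @inheritParams residue_masses
#' @param n_oxidation Number of oxidized methionines (sites are
#'   interchangeable for the precursor mass); must not exceed the number
#'   of M residues.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G", tmt = FALSE, carbamidomethyl = FALSE)  # 75.03203
#' @export
peptide_mass <- function(sequence, tmt = TRUE, carbamidomethyl = TRUE,
                         n_oxidation = 0L) {
  res <- .check_sequence(sequence)
  n_m <- sum(res == "M")
  if (n_oxidation > n_m) {
    stop("n_oxidation exceeds the number of methionine residues", call. = FALSE)
  }
  rm <- residue_masses(sequence, tmt = tmt, carbamidomethyl = carbamidomethyl)
  sum(rm$residues) + rm$nterm + WATER_MONO + n_oxidation * MET_OXIDATION_DELTA
}

#' Precursor m/z from neutral mass and charge
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @export
precursor_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1L))
  (mass + charge * PROTON_MASS) / charge
}

#' Singly charged b/y fragment ladder
#'
#' Theoretical singly protonated b- and y-ion m/z values for a peptide with
#' its modifications.  Peptides of length 1 have no internal fragments and
#' yield an empty ladder.
#'
#' @inheritParams residue_masses
#' @return Numeric vector of fragment m/z values, ascending, with the b/y
#'   series interleaved by m/z.
#' @export
fragment_ladder <- function(sequence, tmt = TRUE, carbamidomethyl = TRUE,
                            ox_sites = integer()) {
  rm <- residue_masses(sequence, tmt = tmt, carbamidomethyl = carbamidomethyl,
                       ox_sites = ox_sites)
  n <- length(rm$residues)
  if (n < 2L) return(numeric())
  cs <- cumsum(rm$residues)
  b <- rm$nterm + cs[-n] + PROTON_MASS
  y <- (cs[n] - cs[-n]) + WATER_MONO + PROTON_MASS
  sort(c(b, y))
}
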