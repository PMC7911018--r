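# Amino-acid property tables used across the package.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter codes. `X` is tolerated in sequences (flagged on input)
#' but excluded from fingerprint classification and scored neutrally by the
#' solubility surrogate.
#'
#' @format Character vector of length 20.
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Chou-Fasman beta-sheet propensity (P_beta, 1 = indifferent)
BETA_PROPENSITY <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10, E = 0.37,
  G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74, M = 1.05, F = 1.38,
  P = 0.55, S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70)

# Side-chain pKa values (Henderson-Hasselbalch charge at a given pH)
SIDECHAIN_PKA <- list(
  acidic = c(D = 3.65, E = 4.25, C = 8.30, Y = 10.07),
  basic  = c(H = 6.00, K = 10.53, R = 12.48))

# Theoretical maximum per-residue SASA (Tien et al. 2013), Angstrom^2,
# used as the default reference for relative SASA on all-atom structures.
MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225,
  G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
  P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

# van der Waals radii by element, Angstrom
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
VDW_DEFAULT <- 1.70

# Default hydrophobic residue set for exposed-hydrophobic analysis
HYDROPHOBIC_SET <- c("V", "I", "L", "F", "M", "W", "Y")

#' Net side-chain charge at a given pH
#'
#' Henderson-Hasselbalch fractional charge of the side chain of each residue.
#' Backbone termini are ignored (the profile is per-residue).
#'
#' @param residues character vector of one-letter codes.
#' @param pH numeric scalar.
#' @return numeric vector of signed fractional charges.
#' @keywords internal
sidechain_charge <- function(residues, pH) {
  q <- numeric(length(residues))
  ac <- SIDECHAIN_PKA$acidic
  ba <- SIDECHAIN_PKA$basic
  is_ac <- residues %in% names(ac)
  is_ba <- residues %in% names(ba)
  q[is_ac] <- -1 / (1 + 10^(ac[residues[is_ac]] - pH))
  q[is_ba] <- 1 / (1 + 10^(pH - ba[residues[is_ba]]))
  q
}

# one-letter <-> three-letter residue code helpers (wrap bio3d tables,
# tolerant of unknown codes)
aa_three <- function(x) {
  out <- suppressWarnings(bio3d::aa123(x))
  out[is.na(out) | !nzchar(out)] <- "UNK"
  out
}

aa_one <- function(x) {
  out <- suppressWarnings(bio3d::aa321(x))
  out[is.na(out)] <- "X"
  out
}
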