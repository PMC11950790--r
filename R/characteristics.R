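# Expasy-compatible average masses of amino-acid residues (dehydrated, Da).
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.02

# Bjellqvist/Expasy pKa set; configurable via the `pka` argument of
# isoelectric_point(). Positive groups: N-terminus, K, R, H.
# Negative groups: C-terminus, D, E, C, Y.
PKA_DEFAULT <- c(
  Nterm = 7.50, Cterm = 3.55,
  D = 4.05, E = 4.45, H = 5.98, C = 9.00, Y = 10.00, K = 10.00, R = 12.00
)

#' Average mass of a free amino acid
#'
#' Returns the average molecular mass of the free amino acid (residue mass
#' plus one water, 18.02 Da), the figure usually printed in tables of
#' amino-acid masses (e.g. L = 131.17 Da, Q = 146.14 Da).
#'
#' @param code One-letter amino-acid code(s).
#' @return Numeric vector of masses in daltons.
#' @examples
#' residue_mass(c("F", "Y"))
#' @export
residue_mass <- function(code) {
  code <- toupper(code)
  bad <- which(!code %in% names(RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue code '%s'", code[bad[1]]))
  unname(RESIDUE_MASS[code] + WATER_MASS)
}

#' Molecular weight of a peptide
#'
#' Average molecular weight: sum of dehydrated residue masses plus one water
#' (18.02 Da), as computed by the Expasy Compute pI/Mw convention.
#'
#' @param sequence One-letter amino-acid sequence (character scalar).
#' @return Mass in daltons.
#' @examples
#' molecular_weight("GG")
#' @export
molecular_weight <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASS))
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d", aa[bad[1]], bad[1]))
  sum(RESIDUE_MASS[aa]) + WATER_MASS
}

# Net Henderson-Hasselbalch charge of a composition at a given pH.
net_charge <- function(counts, pH, pka = PKA_DEFAULT) {
  pos <- 1 / (1 + 10^(pH - pka["Nterm"]))
  for (r in c("K", "R", "H"))
    if (!is.na(counts[r]) && counts[r] > 0)
      pos <- pos + counts[r] / (1 + 10^(pH - pka[r]))
  neg <- 1 / (1 + 10^(pka["Cterm"] - pH))
  for (r in c("D", "E", "C", "Y"))
    if (!is.na(counts[r]) && counts[r] > 0)
      neg <- neg + counts[r] / (1 + 10^(pka[r] - pH))
  unname(pos - neg)
}

#' Isoelectric point of a peptide
#'
#' pH at which the net Henderson-Hasselbalch charge of the termini and the
#' ionizable side chains (D, E, H, C, Y, K, R) crosses zero. The charge is
#' strictly decreasing in pH, so the root is found by bisection on \[0, 14\].
#'
#' @param sequence One-letter amino-acid sequence.
#' @param pka Named pKa vector with entries `Nterm`, `Cterm`, `D`, `E`, `H`,
#'   `C`, `Y`, `K`, `R`. Defaults to the Bjellqvist/Expasy set.
#' @param tol Bisection tolerance in pH units (default 0.001).
#' @return pH of zero net charge.
#' @examples
#' isoelectric_point("KDEL")
#' @export
isoelectric_point <- function(sequence, pka = PKA_DEFAULT, tol = 0.001) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% AA1)
  if (length(bad))
    stop(sprintf("unknown residue code '%s' at position %d", aa[bad[1]], bad[1]))
  stopifnot(all(c("Nterm", "Cterm", "D", "E", "H", "C", "Y", "K", "R") %in%
                  names(pka)), all(pka > 0 & pka < 14))
  counts <- table(factor(aa, levels = AA1))
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
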