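# Residue (monomer) masses in daltons, i.e. the amino-acid mass minus one
# water. A peptide's chemical mass is the sum of its residue masses plus one
# water. Values follow the standard IUPAC 2021 atomic weights (average) and
# the usual monoisotopic element masses; embedded as versioned constants so
# results are reproducible offline.

.AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.MONOISOTOPIC_RESIDUE_MASS <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,  V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MASS <- c(average = 18.01528, monoisotopic = 18.0105646863)

#' Residue mass table
#'
#' The per-residue masses (amino-acid mass minus water) used by
#' [compute_peptide_mass()], for the 20 standard residues.
#'
#' @param mode `"average"` (chemical/average masses) or `"monoisotopic"`.
#' @return Named numeric vector of 20 residue masses in daltons.
#' @export
residue_mass_table <- function(mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  if (mode == "average") .AVERAGE_RESIDUE_MASS else .MONOISOTOPIC_RESIDUE_MASS
}

#' Peptide mass from sequence
#'
#' Computes the neutral peptide mass as the sum of residue masses plus one
#' water. Vectorised over `sequence`.
#'
#' @param sequence Character vector of peptide sequences (20 standard
#'   residues; case-insensitive).
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Numeric vector of masses in daltons.
#' @examples
#' compute_peptide_mass("GG")            # 132.12 Da (average)
#' compute_peptide_mass("IPP", "monoisotopic")
#' @export
compute_peptide_mass <- function(sequence, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  tab <- residue_mass_table(mode)
  if (length(sequence) == 0L) return(numeric(0))
  if (any(is.na(sequence)) || any(!nzchar(sequence)))
    stop_validation("compute_peptide_mass: empty or missing sequence")
  sequence <- toupper(sequence)
  vapply(strsplit(sequence, "", fixed = TRUE), function(res) {
    m <- tab[res]
    if (anyNA(m))
      stop_validation("compute_peptide_mass: non-standard residue '%s'",
                      res[which(is.na(m))[1L]])
    sum(m) + .WATER_MASS[[mode]]
  }, numeric(1))
}
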