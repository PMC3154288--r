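# Pinned physicochemical reference tables. Versions: average residue masses
# and elemental formulas follow the ExPASy ProtParam tables; pKa values are
# the EMBOSS set; hydropathy is Kyte-Doolittle. Changing any of these changes
# downstream feature values, so they are fixed here rather than configurable.

#' Standard amino acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. This order is
#' canonical throughout the package: it fixes schema order and therefore every
#' downstream tie-break.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Accepted ambiguity / nonstandard residue letters
#'
#' Counted only in the "other residue" attributes; excluded from molecular
#' weight, isoelectric point, elemental composition, dipeptides and
#' hydropathy/charge classes.
#'
#' @format Character vector.
#' @export
AA_OTHER <- c("B", "Z", "X", "U", "O", "J")

# Average residue masses (Da), i.e. amino acid minus one water.
RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)

WATER_MASS <- 18.01524

# Elemental formulas of chain residues (amino acid minus H2O), rows C,H,N,O,S.
RESIDUE_FORMULA <- matrix(
  c(
    # C  H   N  O  S
    3,  5,  1, 1, 0,   # A
    3,  5,  1, 1, 1,   # C
    4,  5,  1, 3, 0,   # D
    5,  7,  1, 3, 0,   # E
    9,  9,  1, 1, 0,   # F
    2,  3,  1, 1, 0,   # G
    6,  7,  3, 1, 0,   # H
    6, 11,  1, 1, 0,   # I
    6, 12,  2, 1, 0,   # K
    6, 11,  1, 1, 0,   # L
    5,  9,  1, 1, 1,   # M
    4,  6,  2, 2, 0,   # N
    5,  7,  1, 1, 0,   # P
    5,  8,  2, 2, 0,   # Q
    6, 12,  4, 1, 0,   # R
    3,  5,  1, 2, 0,   # S
    4,  7,  1, 2, 0,   # T
    5,  9,  1, 1, 0,   # V
    11, 10, 2, 1, 0,   # W
    9,  9,  1, 2, 0    # Y
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S"))
)

WATER_FORMULA <- c(C = 0, H = 2, N = 0, O = 1, S = 0)

# EMBOSS pKa set used for net charge and isoelectric point.
PKA_TABLE <- list(
  positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
  negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# Kyte-Doolittle hydropathy sign partitions the standard 20:
# hydrophobic = KD > 0, hydrophilic = KD < 0 (no residue has KD = 0).
KD_HYDROPHOBIC <- c("A", "C", "F", "I", "L", "M", "V")
KD_HYDROPHILIC <- c("R", "K", "N", "D", "Q", "E", "H", "P", "Y", "W",
                    "S", "T", "G")

CHARGE_POSITIVE <- c("R", "K", "H")
CHARGE_NEGATIVE <- c("D", "E")

# ExPASy molar extinction coefficients at 280 nm (1/(M cm)).
EPS280 <- c(Tyr = 1490, Trp = 5500, cystine = 125)

# Swiss-Prot average amino acid frequencies (release statistics), used as the
# background composition of the synthetic generator.
AA_BACKGROUND_FREQ <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
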