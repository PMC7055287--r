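# Canonical amino-acid alphabet, column order used by all score tables.
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (not monoisotopic) residue masses in Daltons, plus one water per
# chain; the convention used by the usual proteomics servers.
AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
WATER_MASS <- 18.01524

# Single declared pKa set (EMBOSS values) used for the isoelectric point.
PKA_SET <- list(
  nterm = 8.6,
  cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

# Closed subfamily vocabulary and the fixed priority order applied when a
# protein carries several recognized non-ANK domains.
SUBFAMILY_VOCAB <- c("ANK-U", "ANK-TM", "ANK-ZnF", "ANK-BTB", "ANK-ACBP",
                     "ANK-GPCR", "ANK-PK", "ANK-BPA", "ANK-IQ", "ANK-RF",
                     "ANK-TPR", "ANK-O")
SUBFAMILY_PRIORITY <- c("TM", "PK", "ZnF", "BTB", "ACBP", "GPCR", "BPA",
                        "IQ", "RF", "TPR")

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide degeneracy codes.
IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N")

# Default molecular clock: synonymous substitutions per site per year.
DEFAULT_CLOCK_LAMBDA <- 6.96e-9

`%||%` <- function(a, b) if (is.null(a)) b else a

chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# round-half-away-from-zero to 2 decimals on an exact integer ratio
# (numerator/denominator both integers); avoids float .5 edge cases.
round2_ratio <- function(num, den) {
  stopifnot(den > 0)
  scaled <- num * 10000            # percent * 100, as integers
  q <- scaled %/% den
  r <- scaled %% den
  (q + as.integer(2 * r >= den)) / 100
}
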