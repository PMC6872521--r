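# Constant tables for protein physicochemical features and peptide masses.
# All tables are restricted to the 20 canonical amino acids.

#' @keywords internal
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte & Doolittle (1982) hydropathy scale.
KD_HYDROPATHY <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3
)

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values.
# DIWV[x, y] is the weight of the dipeptide x-y (x first, y second).
DIWV <- local({
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(1, 20L, 20L, dimnames = list(aas, aas))
  set <- function(x, y, v) m[x, y] <<- v
  # rows in alphabetical order; only non-unit entries listed
  set("A", "C", 44.94); set("A", "D", -7.49); set("A", "H", -7.49)
  set("A", "P", 20.26); set("C", "D", 20.26); set("C", "H", 33.6)
  set("C", "L", 20.26); set("C", "M", 33.6); set("C", "P", 20.26)
  set("C", "Q", -6.54); set("C", "T", 33.6); set("C", "V", -6.54)
  set("C", "W", 24.68); set("D", "F", -6.54); set("D", "K", -7.49)
  set("D", "R", -6.54); set("D", "S", 20.26); set("D", "T", -14.03)
  set("E", "C", 44.94); set("E", "D", 20.26); set("E", "E", 33.6)
  set("E", "H", -6.54); set("E", "I", 20.26); set("E", "P", 20.26)
  set("E", "Q", 20.26); set("E", "S", 20.26); set("E", "W", -14.03)
  set("F", "D", 13.34); set("F", "K", -14.03); set("F", "P", 20.26)
  set("F", "Y", 33.601); set("G", "A", -7.49); set("G", "E", -6.54)
  set("G", "G", 13.34); set("G", "I", -7.49); set("G", "K", -7.49)
  set("G", "N", -7.49); set("G", "T", -7.49); set("G", "W", 13.34)
  set("G", "Y", -7.49); set("H", "F", -9.37); set("H", "G", -9.37)
  set("H", "I", 44.94); set("H", "K", 24.68); set("H", "N", 24.68)
  set("H", "P", -1.88); set("H", "T", -6.54); set("H", "W", -1.88)
  set("H", "Y", 44.94); set("I", "E", 44.94); set("I", "H", 13.34)
  set("I", "K", -7.49); set("I", "L", 20.26); set("I", "P", -1.88)
  set("I", "V", -7.49); set("K", "G", -7.49); set("K", "I", -7.49)
  set("K", "L", -7.49); set("K", "M", 33.6); set("K", "P", -6.54)
  set("K", "Q", 24.64); set("K", "R", 33.6); set("K", "V", -7.49)
  set("L", "K", -7.49); set("L", "P", 20.26); set("L", "Q", 33.6)
  set("L", "R", 20.26); set("L", "W", 24.68); set("M", "A", 13.34)
  set("M", "H", 58.28); set("M", "M", -1.88); set("M", "P", 44.94)
  set("M", "Q", -6.54); set("M", "R", -6.54); set("M", "S", 44.94)
  set("M", "T", -1.88); set("M", "Y", 24.68); set("N", "C", -1.88)
  set("N", "F", -14.03); set("N", "G", -14.03); set("N", "I", 44.94)
  set("N", "K", 24.68); set("N", "P", -1.88); set("N", "Q", -6.54)
  set("N", "T", -7.49); set("N", "W", -9.37); set("P", "A", 20.26)
  set("P", "C", -6.54); set("P", "D", -6.54); set("P", "E", 18.38)
  set("P", "F", 20.26); set("P", "M", -6.54); set("P", "P", 20.26)
  set("P", "Q", 20.26); set("P", "R", -6.54); set("P", "S", 20.26)
  set("P", "V", 20.26); set("P", "W", -1.88); set("Q", "C", -6.54)
  set("Q", "D", 20.26); set("Q", "E", 20.26); set("Q", "F", -6.54)
  set("Q", "P", 20.26); set("Q", "Q", 20.26); set("Q", "S", 44.94)
  set("Q", "V", -6.54); set("Q", "Y", -6.54); set("R", "G", -7.49)
  set("R", "H", 20.26); set("R", "N", 13.34); set("R", "P", 20.26)
  set("R", "Q", 20.26); set("R", "R", 58.28); set("R", "S", 44.94)
  set("R", "W", 58.28); set("R", "Y", -6.54); set("S", "C", 33.6)
  set("S", "E", 20.26); set("S", "P", 44.94); set("S", "Q", 20.26)
  set("S", "R", 20.26); set("S", "S", 20.26); set("T", "E", 20.26)
  set("T", "F", 13.34); set("T", "G", -7.49); set("T", "N", -14.03)
  set("T", "Q", -6.54); set("T", "W", -14.03); set("V", "D", -14.03)
  set("V", "G", -7.49); set("V", "K", -1.88); set("V", "P", 20.26)
  set("V", "T", -7.49); set("V", "Y", -6.54); set("W", "A", -14.03)
  set("W", "G", -9.37); set("W", "H", 24.68); set("W", "L", 13.34)
  set("W", "M", 24.68); set("W", "N", 13.34); set("W", "T", -14.03)
  set("W", "V", -7.49); set("Y", "A", 24.68); set("Y", "D", 24.68)
  set("Y", "E", -6.54); set("Y", "G", -7.49); set("Y", "H", 13.34)
  set("Y", "M", 44.94); set("Y", "P", 13.34); set("Y", "R", -15.91)
  set("Y", "T", -7.49); set("Y", "W", -9.37); set("Y", "Y", 13.34)
  m
})

# EMBOSS pKa set (as used by iep): ionisable side chains plus termini.
EMBOSS_PKA <- list(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)

# Monoisotopic residue masses (Da) and constants for m/z computation.
AA_MONO_MASS <- c(
  A =  71.037114, C = 103.009185, D = 115.026943, E = 129.042593,
  F = 147.068414, G =  57.021464, H = 137.058912, I = 113.084064,
  K = 128.094963, L = 113.084064, M = 131.040485, N = 114.042927,
  P =  97.052764, Q = 128.058578, R = 156.101111, S =  87.032028,
  T = 101.047678, V =  99.068414, W = 186.079313, Y = 163.063329
)
MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276
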