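# Physical constants and residue tables used throughout the package.
# Residue monoisotopic masses are fixed to 5 decimals so that computed
# peptide masses are bit-stable across platforms.

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_HYDROXYLATION <- 15.994915   # +O on proline (hydroxyproline)
MASS_DEAMIDATION <- 0.984016      # N/Q -> D/E: -NH +O
ISOTOPE_SPACING <- 1.00336        # mean nucleon spacing of peptide envelopes

# Monoisotopic residue (i.e. amino acid minus water) masses, Da.
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

# Residue elemental compositions (no water), rows C H N O S.
RESIDUE_COMPOSITION <- matrix(
  c(
    # C  H  N  O  S
    2, 3, 1, 1, 0,  # G
    3, 5, 1, 1, 0,  # A
    3, 5, 1, 2, 0,  # S
    5, 7, 1, 1, 0,  # P
    5, 9, 1, 1, 0,  # V
    4, 7, 1, 2, 0,  # T
    3, 5, 1, 1, 1,  # C
    6, 11, 1, 1, 0, # L
    6, 11, 1, 1, 0, # I
    4, 6, 2, 2, 0,  # N
    4, 5, 1, 3, 0,  # D
    5, 8, 2, 2, 0,  # Q
    6, 12, 2, 1, 0, # K
    5, 7, 1, 3, 0,  # E
    5, 9, 1, 1, 1,  # M
    6, 7, 3, 1, 0,  # H
    9, 9, 1, 1, 0,  # F
    6, 12, 4, 1, 0, # R
    9, 9, 1, 2, 0,  # Y
    11, 10, 2, 1, 0 # W
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N", "D", "Q", "K",
      "E", "M", "H", "F", "R", "Y", "W"),
    c("C", "H", "N", "O", "S")
  )
)

# Stable-isotope masses and terrestrial abundances per element.  The list
# position of each isotope is its nucleon offset from the lightest one
# (sulfur's offset-3 slot has zero abundance).
ISOTOPES <- list(
  C = list(mass = c(12.0000000, 13.0033548), abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.0078250, 2.0141018), abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740, 15.0001089), abundance = c(0.99636, 0.00364)),
  O = list(
    mass = c(15.9949146, 16.9991315, 17.9991604),
    abundance = c(0.99757, 0.00038, 0.00205)
  ),
  S = list(
    mass = c(31.9720707, 32.9714585, 33.9678668, 0, 35.9670809),
    abundance = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
)

# Averagine model residue: used to approximate the elemental composition of
# a peptide known only by mass (marker-database entries without sequence).
AVERAGINE <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
AVERAGINE_MASS <- 111.1254
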