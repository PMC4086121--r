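# Residue-level constants used across the package. All scales are taken from
# the primary literature; values are per-residue lookups keyed by the 20
# canonical one-letter codes.

# Canonical alphabet, alphabetical order. This order fixes the layout of the
# composition (20) and bigram (20 x 20) feature groups.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

BASIC_RESIDUES <- c("K", "R")

# Residue class memberships (documented in the feature catalog help page).
AA_CLASSES <- list(
  charged     = c("D", "E", "K", "R", "H"),
  polar       = c("C", "H", "N", "Q", "S", "T", "W", "Y"),
  hydrophobic = c("A", "C", "F", "I", "L", "M", "V"),  # Kyte-Doolittle > 0
  aromatic    = c("F", "H", "W", "Y"),
  tiny        = c("A", "C", "G", "S", "T"),
  small       = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
  basic       = c("H", "K", "R"),
  acidic      = c("D", "E"),
  aliphatic   = c("A", "I", "L", "V"),
  helix       = c("A", "E", "H", "K", "L", "M", "Q", "R"),   # Chou-Fasman formers
  sheet       = c("C", "F", "I", "T", "V", "W", "Y"),
  turn        = c("D", "G", "N", "P", "S")
)

# Kyte & Doolittle (1982) hydropathy.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Vihinen et al. (1994) normalized B-factor flexibility.
FLEXIBILITY <- c(
  A = 0.984, C = 0.906, D = 1.068, E = 1.094, F = 0.915, G = 1.031,
  H = 0.95, I = 0.927, K = 1.102, L = 0.935, M = 0.952, N = 1.048,
  P = 1.049, Q = 1.037, R = 1.008, S = 1.046, T = 0.997, V = 0.931,
  W = 0.904, Y = 0.929
)

# Average residue masses (Da), free amino acids; peptide-bond formation
# subtracts one water per bond.
AA_WEIGHT <- c(
  A = 89.0932, C = 121.158, D = 133.103, E = 147.129, F = 165.189,
  G = 75.0666, H = 155.155, I = 131.173, K = 146.188, L = 131.173,
  M = 149.211, N = 132.118, P = 115.13, Q = 146.144, R = 174.201,
  S = 105.093, T = 119.119, V = 117.146, W = 204.225, Y = 181.189
)
WATER_MASS <- 18.0153

# Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
# (DIWV); row = first residue of the bigram, column = second.
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(AA_ALPHABET, AA_ALPHABET))

# Side-chain and terminal pKa values (EMBOSS set) for charge/pI calculations.
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

# Molar extinction coefficients at 280 nm (Pace et al. 1995), reduced Cys.
EXTINCTION <- c(W = 5500, Y = 1490, C = 125)

# Average amino-acid frequencies of well-annotated protein databases
# (Swiss-Prot release statistics), renormalized to sum to one. Used as the
# default background composition of the synthetic generator.
BACKGROUND_COMPOSITION <- local({
  p <- c(
    A = 8.25, C = 1.37, D = 5.45, E = 6.75, F = 3.86, G = 7.07, H = 2.27,
    I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06, P = 4.70, Q = 3.93,
    R = 5.53, S = 6.56, T = 5.34, V = 6.87, W = 1.08, Y = 2.92
  )
  p / sum(p)
})

# Version string for the descriptor catalog; stored inside trained model
# bundles so that feature vectors and models can refuse to mix across
# incompatible catalog revisions.
FEATURE_CATALOG_VERSION <- "nppred-catalog-1.0"
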