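# Physicochemical constants used by the descriptor battery.
# All tables are indexed by the 20 standard amino-acid one-letter codes.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# boundary/other symbol completing the 21-letter alphabet of the
# windowed dipeptide block (21^2 = 441 ordered pairs)
AA_BOUNDARY <- "#"

# Kyte & Doolittle (1982) hydropathy
SCALE_HYDROPATHY <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9, M =  1.9, F =  2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Hopp & Woods (1981) hydrophilicity
SCALE_HYDROPHILICITY <- c(
  A = -0.5, R =  3.0, N =  0.2, D =  3.0, C = -1.0, Q =  0.2, E =  3.0,
  G =  0.0, H = -0.5, I = -1.8, L = -1.8, K =  3.0, M = -1.3, F = -2.5,
  P =  0.0, S =  0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5)

# side-chain mass (Da), as used in pseudo amino acid composition
SCALE_SIDECHAIN_MASS <- c(
  A =  15.0, R = 101.0, N =  58.0, D =  59.0, C =  47.0, Q =  72.0,
  E =  73.0, G =   1.0, H =  82.0, I =  57.0, L =  57.0, K =  73.0,
  M =  75.0, F =  91.0, P =  42.0, S =  31.0, T =  45.0, W = 130.0,
  Y = 107.0, V =  43.0)

# Grantham (1974) side-chain properties: composition c, polarity p, volume v
GRANTHAM_COMPOSITION <- c(
  A = 0.00, R = 0.65, N = 1.33, D = 1.38, C = 2.75, Q = 0.89, E = 0.92,
  G = 0.74, H = 0.58, I = 0.00, L = 0.00, K = 0.33, M = 0.00, F = 0.00,
  P = 0.39, S = 1.42, T = 0.71, W = 0.13, Y = 0.20, V = 0.00)
GRANTHAM_POLARITY <- c(
  A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5, Q = 10.5, E = 12.3,
  G =  9.0, H = 10.4, I =  5.2, L =  4.9, K = 11.3, M =  5.7, F =  5.2,
  P =  8.0, S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9)
GRANTHAM_VOLUME <- c(
  A =  31.0, R = 124.0, N =  56.0, D =  54.0, C =  55.0, Q =  85.0,
  E =  83.0, G =   3.0, H =  96.0, I = 111.0, L = 111.0, K = 119.0,
  M = 105.0, F = 132.0, P =  32.5, S =  32.0, T =  61.0, W = 170.0,
  Y = 136.0, V =  84.0)

#' @noRd
#' Grantham (1974) chemical distance matrix, rebuilt from the published
#' formula D_ij = rho * sqrt(alpha (c_i-c_j)^2 + beta (p_i-p_j)^2 +
#' gamma (v_i-v_j)^2), rho normalizing the mean off-diagonal distance to 100.
grantham_matrix <- function() {
  a <- 1.833; b <- 0.1018; g <- 0.000399
  cc <- GRANTHAM_COMPOSITION[AA_ALPHABET]
  pp <- GRANTHAM_POLARITY[AA_ALPHABET]
  vv <- GRANTHAM_VOLUME[AA_ALPHABET]
  d <- sqrt(a * outer(cc, cc, "-")^2 +
            b * outer(pp, pp, "-")^2 +
            g * outer(vv, vv, "-")^2)
  rho <- 100 / mean(d[upper.tri(d)])
  m <- rho * d
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

#' @noRd
#' Physicochemical residue distance: Euclidean distance over the three
#' standardized property scales that also drive pseudo amino acid
#' composition (hydropathy, hydrophilicity, side-chain mass).
physchem_distance_matrix <- function() {
  s <- vapply(list(SCALE_HYDROPATHY, SCALE_HYDROPHILICITY, SCALE_SIDECHAIN_MASS),
              function(x) {
                x <- x[AA_ALPHABET]
                (x - mean(x)) / stats::sd(x)
              }, numeric(20))
  m <- as.matrix(stats::dist(s))
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  m
}

# six physicochemical amino-acid groups used for group counts/frequencies
AA_SIX_GROUPS <- list(
  hydrophobic    = c("V", "I", "L", "F", "M", "W", "Y", "C"),
  negative       = c("D", "E"),
  positive       = c("R", "K", "H"),
  conformational = c("G", "P"),
  polar          = c("N", "Q", "S"),
  other          = c("A", "T"))

# CTD: seven classic properties, each a 3-class partition of the alphabet
# (Dubchak et al. groupings)
CTD_PROPERTIES <- list(
  hydrophobicity = list(
    g1 = c("R", "K", "E", "D", "Q", "N"),
    g2 = c("G", "A", "S", "T", "P", "H", "Y"),
    g3 = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    g1 = c("G", "A", "S", "T", "P", "D", "C"),
    g2 = c("N", "V", "E", "Q", "I", "L"),
    g3 = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    g1 = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    g2 = c("P", "A", "T", "G", "S"),
    g3 = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    g1 = c("G", "A", "S", "D", "T"),
    g2 = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    g3 = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    g1 = c("K", "R"),
    g2 = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F", "P", "S",
           "T", "W", "Y", "V"),
    g3 = c("D", "E")),
  secondary_structure = list(
    g1 = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    g2 = c("V", "I", "Y", "C", "W", "F", "T"),
    g3 = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    g1 = c("A", "L", "F", "C", "G", "I", "V", "W"),
    g2 = c("R", "K", "Q", "E", "N", "D"),
    g3 = c("M", "S", "P", "T", "H", "Y")))

# conjoint triad: seven classes of Shen et al. (2007)
CONJOINT_CLASSES <- list(
  c1 = c("A", "G", "V"),
  c2 = c("I", "L", "F", "P"),
  c3 = c("Y", "M", "T", "S"),
  c4 = c("H", "N", "Q", "W"),
  c5 = c("R", "K"),
  c6 = c("D", "E"),
  c7 = c("C"))

# average isotopic residue masses (Da) and water
RESIDUE_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
MASS_WATER <- 18.01524

# atoms per residue (free amino acid minus one water), rows C,H,N,O,S
RESIDUE_ATOMS <- rbind(
  C = c(A = 3, R = 6,  N = 4, D = 4, C = 3, E = 5, Q = 5,  G = 2, H = 6,
        I = 6, L = 6,  K = 6, M = 5, F = 9, P = 5, S = 3,  T = 4, V = 5,
        W = 11, Y = 9),
  H = c(A = 5, R = 12, N = 6, D = 5, C = 5, E = 7, Q = 8,  G = 3, H = 7,
        I = 11, L = 11, K = 12, M = 9, F = 9, P = 7, S = 5, T = 7, V = 9,
        W = 10, Y = 9),
  N = c(A = 1, R = 4,  N = 2, D = 1, C = 1, E = 1, Q = 2,  G = 1, H = 3,
        I = 1, L = 1,  K = 2, M = 1, F = 1, P = 1, S = 1,  T = 1, V = 1,
        W = 2, Y = 1),
  O = c(A = 1, R = 1,  N = 2, D = 3, C = 1, E = 3, Q = 2,  G = 1, H = 1,
        I = 1, L = 1,  K = 1, M = 1, F = 1, P = 1, S = 2,  T = 2, V = 1,
        W = 1, Y = 2),
  S = c(A = 0, R = 0,  N = 0, D = 0, C = 1, E = 0, Q = 0,  G = 0, H = 0,
        I = 0, L = 0,  K = 0, M = 1, F = 0, P = 0, S = 0,  T = 0, V = 0,
        W = 0, Y = 0))

# Bjellqvist/Expasy pKa values used for the isoelectric point and net charge.
# N-terminal pKa depends on the first residue; 7.5 elsewhere.
PKA_CTERM <- 3.55
PKA_NTERM_DEFAULT <- 7.5
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.70)
PKA_SIDECHAIN_NEG <- c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00)  # + C-terminus
PKA_SIDECHAIN_POS <- c(H = 5.98, K = 10.00, R = 12.00)           # + N-terminus

# N-end-rule half-lives (hours) by N-terminal residue; open intervals
# (">20 h", ">10 h") encoded at their lower bound, unknowns at the
# conservative ">10 h" bound.
HALF_LIFE <- rbind(
  mammalian = c(A = 4.4, R = 1.0,   N = 1.4,  D = 1.1,  C = 1.2, Q = 0.8,
                E = 1.0, G = 30.0,  H = 3.5,  I = 20.0, L = 5.5, K = 1.3,
                M = 30.0, F = 1.1,  P = 20.0, S = 1.9,  T = 7.2, W = 2.8,
                Y = 2.8, V = 100.0),
  yeast     = c(A = 20.0, R = 1/30, N = 0.05, D = 0.05, C = 20.0, Q = 1/6,
                E = 0.5,  G = 20.0, H = 1/6,  I = 0.5,  L = 0.05, K = 0.05,
                M = 20.0, F = 0.05, P = 20.0, S = 20.0, T = 20.0, W = 0.05,
                Y = 1/6,  V = 20.0),
  ecoli     = c(A = 10.0, R = 1/30, N = 10.0, D = 10.0, C = 10.0, Q = 10.0,
                E = 10.0, G = 10.0, H = 10.0, I = 10.0, L = 1/30, K = 1/30,
                M = 10.0, F = 1/30, P = 10.0, S = 10.0, T = 10.0, W = 1/30,
                Y = 1/30, V = 10.0))

# extinction coefficients at 280 nm (Gill & von Hippel / Pace)
EXT_TYR <- 1490
EXT_TRP <- 5500
EXT_CYSTINE <- 125

#' @noRd
#' default autocorrelation scale set (standardized at point of use)
default_scales <- function() {
  list(hydropathy     = SCALE_HYDROPATHY,
       hydrophilicity = SCALE_HYDROPHILICITY,
       sidechain_mass = SCALE_SIDECHAIN_MASS,
       polarity       = GRANTHAM_POLARITY,
       volume         = GRANTHAM_VOLUME)
}
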