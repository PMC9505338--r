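# Sequence-derived protein descriptors: composition families, CTD,
# autocorrelation, sequence-order/quasi-sequence-order, (amphiphilic) pseudo
# amino acid composition, conjoint triads, the windowed dipeptide block, the
# six-group block and the ProtParam-style physicochemical block.

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

check_seq <- function(seq, min_len = 1L, what = "descriptor") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, ": sequence must be a non-empty string")
  }
  if (nchar(seq) < min_len) {
    stop(what, ": sequence length ", nchar(seq), " below minimum ", min_len)
  }
  invisible(seq)
}

#' Descriptor configuration
#'
#' Bundles every tunable parameter of the descriptor battery. The defaults
#' are the established values of the descriptor literature: lag 30 for
#' autocorrelation and sequence-order families, lambda 30 and weight 0.05
#' for pseudo amino acid composition, weight 0.1 for quasi-sequence-order,
#' and a 21-residue window for the windowed dipeptide block.
#'
#' @param nlag_autocorr Maximum lag for the autocorrelation families.
#' @param nlag_socn_qso Maximum lag for sequence-order coupling numbers and
#'   quasi-sequence-order descriptors.
#' @param paac_lambda Number of sequence-correlation factors in PAAC/APAAC.
#' @param paac_weight Mixing weight of the correlation factors in PAAC/APAAC,
#'   in (0, 1).
#' @param qso_weight Mixing weight of the coupling terms in QSO.
#' @param window Window length (residues) for the windowed dipeptide block.
#' @param group_map Named list partitioning the 20 standard letters into the
#'   six physicochemical groups (hydrophobic, negative, positive,
#'   conformational, polar, other).
#' @param scales Named list of 20-value property scales for the
#'   autocorrelation families; standardized to mean 0, sd 1 before use.
#' @param enabled_families Character vector of descriptor family names; any
#'   subset of `descriptor_families()`.
#' @return An object of class `descriptor_config`.
#' @export
descriptor_config <- function(nlag_autocorr = 30L,
                              nlag_socn_qso = 30L,
                              paac_lambda = 30L,
                              paac_weight = 0.05,
                              qso_weight = 0.1,
                              window = 21L,
                              group_map = AA_SIX_GROUPS,
                              scales = default_scales(),
                              enabled_families = descriptor_families()) {
  stopifnot(nlag_autocorr >= 1L, nlag_socn_qso >= 1L, paac_lambda >= 1L,
            paac_weight > 0 && paac_weight < 1, qso_weight > 0,
            window >= 2L)
  got <- sort(unlist(group_map, use.names = FALSE))
  if (!identical(got, sort(AA_ALPHABET)) || length(group_map) != 6L) {
    stop("group_map must partition the 20 standard letters into 6 groups")
  }
  unknown <- setdiff(enabled_families, descriptor_families())
  if (length(unknown) > 0L) {
    stop("unknown descriptor famil(ies): ", paste(unknown, collapse = ", "))
  }
  structure(list(nlag_autocorr = as.integer(nlag_autocorr),
                 nlag_socn_qso = as.integer(nlag_socn_qso),
                 paac_lambda = as.integer(paac_lambda),
                 paac_weight = paac_weight,
                 qso_weight = qso_weight,
                 window = as.integer(window),
                 group_map = group_map,
                 scales = scales,
                 enabled_families = enabled_families),
            class = "descriptor_config")
}

#' All descriptor family names, in assembly order
#' @return Character vector of family names understood by [featurize()].
#' @export
descriptor_families <- function() {
  c("aac", "dpc", "ctd", "autocorr", "socn_qso", "paac", "apaac",
    "conjoint_triad", "aa_group", "windowed_dipeptide", "physchem")
}

#' Deterministic fingerprint of a descriptor configuration
#' @param config A `descriptor_config`.
#' @return A single string identifying the configuration.
#' @export
config_fingerprint <- function(config) {
  paste0("nlag", config$nlag_autocorr, ".", config$nlag_socn_qso,
         "_lambda", config$paac_lambda,
         "_w", config$paac_weight, ".", config$qso_weight,
         "_win", config$window,
         "_scales:", paste(names(config$scales), collapse = "+"),
         "_fam:", paste(config$enabled_families, collapse = "+"))
}

# standardize a 20-value scale to mean 0, sd 1 (sample sd over the 20 values)
standardize_scale <- function(scale) {
  x <- scale[AA_ALPHABET]
  if (anyNA(x)) stop("scale must cover all 20 standard residues")
  (x - mean(x)) / stats::sd(x)
}

#' Amino acid composition (20 values)
#'
#' @param seq Validated sequence string.
#' @return Named vector of the 20 residue frequencies; sums to 1.
#' @export
aa_composition <- function(seq) {
  check_seq(seq, 1L, "aa_composition")
  ch <- factor(seq_chars(seq), levels = AA_ALPHABET)
  out <- as.vector(table(ch)) / nchar(seq)
  names(out) <- AA_ALPHABET
  out
}

#' Dipeptide composition (400 values)
#'
#' Frequencies of the 400 ordered residue pairs among the L-1 adjacent pairs.
#'
#' @param seq Validated sequence string of length >= 2.
#' @return Named 400-vector summing to 1.
#' @export
dipeptide_composition <- function(seq) {
  check_seq(seq, 2L, "dipeptide_composition")
  ch <- seq_chars(seq)
  L <- length(ch)
  pairs <- paste0(ch[-L], ch[-1L])
  lev <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  out <- as.vector(table(factor(pairs, levels = lev))) / (L - 1L)
  names(out) <- lev
  out
}

# number of length-`window` windows of a padded sequence of length lp that
# contain both positions i and i+1 (single truncated window when lp < window)
.pair_window_weight <- function(i, lp, window) {
  if (lp <= window) return(rep(1, length(i)))
  n_starts <- lp - window + 1L
  pmin(i, n_starts) - pmax(1L, i + 2L - window) + 1
}

#' Windowed dipeptide counts (441 values)
#'
#' Counts of ordered symbol pairs over a 21-letter alphabet (the 20 standard
#' residues plus one boundary symbol `#` marking the sequence termini),
#' accumulated over all sliding windows of `window` residues (stride 1). The
#' sequence is padded with one boundary symbol at each end, so N- and
#' C-terminal context contributes the pairs involving `#`; a sequence shorter
#' than the window yields a single truncated window. Each adjacent pair is
#' counted once per window containing it, i.e. weighted by its window
#' multiplicity.
#'
#' @param seq Validated sequence string of length >= 2.
#' @param window Window length in residues (>= 2), default 21.
#' @return Named 441-vector of counts (first symbol then second symbol,
#'   boundary symbol last).
#' @export
windowed_dipeptide_counts <- function(seq, window = 21L) {
  check_seq(seq, 2L, "windowed_dipeptide_counts")
  if (window < 2L) stop("window must be >= 2")
  alphabet <- c(AA_ALPHABET, AA_BOUNDARY)
  ch <- c(AA_BOUNDARY, seq_chars(seq), AA_BOUNDARY)
  lp <- length(ch)
  i <- seq_len(lp - 1L)
  w <- .pair_window_weight(i, lp, as.integer(window))
  lev <- as.vector(t(outer(alphabet, alphabet, paste0)))
  pairs <- factor(paste0(ch[i], ch[i + 1L]), levels = lev)
  out <- as.vector(tapply(w, pairs, sum, default = 0))
  names(out) <- lev
  out
}

#' Six-group amino acid counts and frequencies (12 values)
#'
#' Residues are grouped into hydrophobic (V, I, L, F, M, W, Y, C), negatively
#' charged (D, E), positively charged (R, K, H), conformational (G, P), polar
#' (N, Q, S) and other (A, T); the block holds the six counts followed by the
#' six frequencies.
#'
#' @param seq Validated sequence string.
#' @param group_map Partition of the alphabet into six named groups.
#' @return Named 12-vector: `count_<group>` then `freq_<group>`.
#' @export
aa_group_features <- function(seq, group_map = AA_SIX_GROUPS) {
  check_seq(seq, 1L, "aa_group_features")
  ch <- seq_chars(seq)
  counts <- vapply(group_map, function(g) sum(ch %in% g), numeric(1))
  out <- c(counts, counts / length(ch))
  names(out) <- c(paste0("count_", names(group_map)),
                  paste0("freq_", names(group_map)))
  out
}

#' Composition/Transition/Distribution descriptors (147 values)
#'
#' Classic CTD over seven 3-class physicochemical partitions of the alphabet
#' (hydrophobicity, normalized van der Waals volume, polarity, polarizability,
#' charge, secondary structure, solvent accessibility). Per property:
#' 3 class fractions; 3 transition frequencies (unordered class pairs among
#' adjacent residues, divided by L-1); 15 distribution values — for each class
#' the positions of the first, 25%, 50%, 75% and last occurrence as fractions
#' of the sequence length (quantile index `max(1, round(q * n))`; an absent
#' class contributes zeros).
#'
#' @param seq Validated sequence string of length >= 2.
#' @return Named 147-vector (7 properties x 21 values).
#' @export
ctd_features <- function(seq) {
  check_seq(seq, 2L, "ctd_features")
  ch <- seq_chars(seq)
  L <- length(ch)
  out <- numeric(0)
  for (prop in names(CTD_PROPERTIES)) {
    groups <- CTD_PROPERTIES[[prop]]
    cls <- integer(L)
    for (k in 1:3) cls[ch %in% groups[[k]]] <- k
    comp <- vapply(1:3, function(k) sum(cls == k) / L, numeric(1))
    a <- cls[-L]; b <- cls[-1L]
    trans <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
               sum((a == 1 & b == 3) | (a == 3 & b == 1)),
               sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1L)
    distr <- numeric(15)
    for (k in 1:3) {
      pos <- which(cls == k)
      n <- length(pos)
      vals <- if (n == 0L) rep(0, 5) else {
        idx <- c(1L, pmax(1L, round(c(0.25, 0.5, 0.75) * n)), n)
        pos[idx] / L
      }
      distr[(k - 1L) * 5L + 1:5] <- vals
    }
    block <- c(comp, trans, distr)
    names(block) <- c(paste0(prop, ".comp.g", 1:3),
                      paste0(prop, ".trans.", c("g1g2", "g1g3", "g2g3")),
                      paste0(prop, ".distr.g", rep(1:3, each = 5), ".",
                             rep(c("first", "q25", "q50", "q75", "last"), 3)))
    out <- c(out, block)
  }
  out
}

#' Autocorrelation descriptors (normalized Moreau-Broto, Moran, Geary)
#'
#' Property scales are standardized to mean 0, sd 1 over the 20 residues
#' before use. With p the per-residue scale values, L the length and d the
#' lag: normalized Moreau-Broto is `sum(p_i p_{i+d}) / (L - d)`; Moran and
#' Geary follow their classical spatial-statistics forms with the sequence
#' mean and variance of p. A scale that is constant over the sequence leaves
#' Moran/Geary undefined (0/0); the value is set to 0 with a warning.
#'
#' @param seq Validated sequence string with length > `nlag`.
#' @param scales Named list of 20-value property scales.
#' @param nlag Maximum lag.
#' @param kind One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @return Named vector of length `nlag * length(scales)`.
#' @export
autocorrelation <- function(seq, scales = default_scales(), nlag = 30L,
                            kind = c("moreau_broto", "moran", "geary")) {
  kind <- match.arg(kind)
  check_seq(seq, 1L, "autocorrelation")
  L <- nchar(seq)
  if (L <= nlag) {
    stop("autocorrelation: sequence length ", L, " must exceed nlag ", nlag)
  }
  ch <- seq_chars(seq)
  out <- numeric(0)
  for (sc in names(scales)) {
    p <- standardize_scale(scales[[sc]])[ch]
    pbar <- mean(p)
    ss <- sum((p - pbar)^2)
    vals <- numeric(nlag)
    if (kind != "moreau_broto" && ss == 0) {
      warning("autocorrelation: zero-variance scale '", sc,
              "' over the sequence; ", kind, " set to 0")
    }
    for (d in seq_len(nlag)) {
      head_i <- 1:(L - d)
      if (kind == "moreau_broto") {
        vals[d] <- sum(p[head_i] * p[head_i + d]) / (L - d)
      } else if (kind == "moran") {
        vals[d] <- if (ss == 0) 0 else
          (sum((p[head_i] - pbar) * (p[head_i + d] - pbar)) / (L - d)) /
          (ss / L)
      } else {
        vals[d] <- if (ss == 0) 0 else
          (sum((p[head_i] - p[head_i + d])^2) / (2 * (L - d))) /
          (ss / (L - 1))
      }
    }
    names(vals) <- paste0(kind, ".", sc, ".lag", seq_len(nlag))
    out <- c(out, vals)
  }
  out
}

# residue-residue distance matrices for sequence-order descriptors
socn_distance_matrices <- function() {
  list(grantham = grantham_matrix(), physchem = physchem_distance_matrix())
}

#' Sequence-order coupling numbers and quasi-sequence-order descriptors
#'
#' Coupling numbers `tau_d = sum_i dist(R_i, R_{i+d})^2` for d = 1..nlag
#' under two residue distance matrices (Grantham chemical distance and a
#' physicochemical Euclidean distance over the standardized hydropathy,
#' hydrophilicity and side-chain-mass scales). The quasi-sequence-order block
#' for each matrix combines the 20 residue counts f and the nlag coupling
#' numbers: `qso_r = f_r / (L + w sum(tau))` for the 20 residues and
#' `qso_{20+d} = w tau_d / (L + w sum(tau))`, so each matrix's QSO block sums
#' to 1.
#'
#' @param seq Validated sequence string with length > `nlag`.
#' @param nlag Maximum lag.
#' @param weight Mixing weight w of the coupling terms (default 0.1).
#' @return Named vector: `2 * nlag` coupling numbers followed by
#'   `2 * (20 + nlag)` QSO values.
#' @export
sequence_order_features <- function(seq, nlag = 30L, weight = 0.1) {
  check_seq(seq, 1L, "sequence_order_features")
  L <- nchar(seq)
  if (L <= nlag) {
    stop("sequence_order_features: sequence length ", L,
         " must exceed nlag ", nlag)
  }
  ch <- seq_chars(seq)
  mats <- socn_distance_matrices()
  f <- as.vector(table(factor(ch, levels = AA_ALPHABET)))
  socn <- numeric(0)
  qso <- numeric(0)
  for (mn in names(mats)) {
    m <- mats[[mn]]
    tau <- vapply(seq_len(nlag), function(d) {
      i <- 1:(L - d)
      sum(m[cbind(ch[i], ch[i + d])]^2)
    }, numeric(1))
    names(tau) <- paste0("socn.", mn, ".lag", seq_len(nlag))
    socn <- c(socn, tau)
    denom <- L + weight * sum(tau)
    q <- c(f, weight * tau) / denom
    names(q) <- c(paste0("qso.", mn, ".", AA_ALPHABET),
                  paste0("qso.", mn, ".lag", seq_len(nlag)))
    qso <- c(qso, q)
  }
  c(socn, qso)
}

# classical PAAC normalization of a property scale: subtract the mean over
# the 20 residues, divide by the population sd over the 20 residues
paac_normalize <- function(scale) {
  x <- scale[AA_ALPHABET]
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
}

#' Pseudo amino acid composition (20 + lambda values)
#'
#' Chou's classical PAAC: composition augmented with lambda sequence
#' correlation factors `theta_d`, each the mean over positions of the
#' property-averaged squared difference of the normalized hydropathy,
#' hydrophilicity and side-chain-mass values of residues d apart. With f the
#' 20 residue frequencies: `x_u = f_u / (1 + w sum(theta))`,
#' `x_{20+d} = w theta_d / (1 + w sum(theta))`; the vector sums to 1.
#'
#' @param seq Validated sequence string with length > `lambda`.
#' @param lambda Number of correlation factors.
#' @param weight Mixing weight w in (0, 1); `weight = 0` reduces the first
#'   20 entries to plain composition.
#' @return Named vector of length `20 + lambda`.
#' @export
paac <- function(seq, lambda = 30L, weight = 0.05) {
  check_seq(seq, 1L, "paac")
  L <- nchar(seq)
  if (L <= lambda) stop("paac: sequence length ", L, " must exceed lambda ",
                        lambda)
  ch <- seq_chars(seq)
  props <- lapply(list(SCALE_HYDROPATHY, SCALE_HYDROPHILICITY,
                       SCALE_SIDECHAIN_MASS), paac_normalize)
  pv <- lapply(props, function(p) p[ch])
  theta <- vapply(seq_len(lambda), function(d) {
    i <- 1:(L - d)
    mean(Reduce(`+`, lapply(pv, function(p) (p[i] - p[i + d])^2)) / 3)
  }, numeric(1))
  f <- as.vector(table(factor(ch, levels = AA_ALPHABET))) / L
  denom <- 1 + weight * sum(theta)
  out <- c(f, weight * theta) / denom
  names(out) <- c(paste0("paac.", AA_ALPHABET),
                  paste0("paac.lambda", seq_len(lambda)))
  out
}

#' Amphiphilic pseudo amino acid composition (20 + 2 lambda values)
#'
#' APAAC replaces PAAC's pooled correlation factor with separate hydropathy
#' and hydrophilicity correlation factors per lag:
#' `tau_{2d-1} = mean(H1_i H1_{i+d})`, `tau_{2d} = mean(H2_i H2_{i+d})`
#' (means over the L-d positions), combined with the composition exactly as
#' in PAAC. The vector sums to 1 by construction.
#'
#' @inheritParams paac
#' @return Named vector of length `20 + 2 * lambda`.
#' @export
apaac <- function(seq, lambda = 30L, weight = 0.05) {
  check_seq(seq, 1L, "apaac")
  L <- nchar(seq)
  if (L <= lambda) stop("apaac: sequence length ", L, " must exceed lambda ",
                        lambda)
  ch <- seq_chars(seq)
  h1 <- paac_normalize(SCALE_HYDROPATHY)[ch]
  h2 <- paac_normalize(SCALE_HYDROPHILICITY)[ch]
  tau <- numeric(2L * lambda)
  for (d in seq_len(lambda)) {
    i <- 1:(L - d)
    tau[2L * d - 1L] <- sum(h1[i] * h1[i + d]) / (L - d)
    tau[2L * d] <- sum(h2[i] * h2[i + d]) / (L - d)
  }
  f <- as.vector(table(factor(ch, levels = AA_ALPHABET))) / L
  denom <- 1 + weight * sum(tau)
  out <- c(f, weight * tau) / denom
  names(out) <- c(paste0("apaac.", AA_ALPHABET),
                  paste0("apaac.", rep(c("h1", "h2"), lambda), ".lag",
                         rep(seq_len(lambda), each = 2)))
  out
}

#' Conjoint triad descriptors (343 values)
#'
#' Counts of consecutive residue triples after mapping the alphabet onto the
#' seven conjoint classes of Shen et al.; 7^3 = 343 entries summing to L - 2.
#'
#' @param seq Validated sequence string of length >= 3.
#' @return Named 343-vector of triple counts.
#' @export
conjoint_triad <- function(seq) {
  check_seq(seq, 3L, "conjoint_triad")
  ch <- seq_chars(seq)
  L <- length(ch)
  cls <- integer(L)
  for (k in seq_along(CONJOINT_CLASSES)) cls[ch %in% CONJOINT_CLASSES[[k]]] <- k
  i <- 1:(L - 2L)
  lev <- apply(expand.grid(1:7, 1:7, 1:7)[, 3:1], 1, paste, collapse = "")
  triples <- factor(paste0(cls[i], cls[i + 1L], cls[i + 2L]), levels = lev)
  out <- as.vector(table(triples))
  names(out) <- paste0("ct.", lev)
  out
}

# positive/negative net charge (Bjellqvist pKa set) at a given pH
net_charge_at <- function(ch, pH) {
  n_first <- ch[1L]
  pka_n <- if (n_first %in% names(PKA_NTERM)) PKA_NTERM[[n_first]] else
    PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - pka_n))
  for (r in names(PKA_SIDECHAIN_POS)) {
    pos <- pos + sum(ch == r) / (1 + 10^(pH - PKA_SIDECHAIN_POS[[r]]))
  }
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (r in names(PKA_SIDECHAIN_NEG)) {
    neg <- neg + sum(ch == r) / (1 + 10^(PKA_SIDECHAIN_NEG[[r]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection on the net-charge curve (Bjellqvist/Expasy pKa set, N-terminal
#' pKa dependent on the first residue) to |net charge| < 1e-4 on pH 0..14.
#'
#' @param seq Validated sequence string.
#' @return The pI as a single number.
#' @export
isoelectric_point <- function(seq) {
  check_seq(seq, 1L, "isoelectric_point")
  ch <- seq_chars(seq)
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge_at(ch, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' ProtParam-style physicochemical block (28 values)
#'
#' A fixed, versioned 28-feature reconstruction of the classic global
#' physicochemical parameter set: length; molecular weight (average residue
#' masses plus one water); theoretical pI; instability index (Guruprasad
#' dipeptide weights, 10/L scaling); aliphatic index
#' (100 (fA + 2.9 fV + 3.9 (fI + fL))); GRAVY (mean Kyte-Doolittle
#' hydropathy); extinction coefficients at 280 nm with all Cys paired as
#' cystines and fully reduced (Gill-von Hippel); atom counts C, H, N, O, S
#' and their total; counts of negatively (D+E) and positively (R+K) charged
#' residues; net charge at pH 7; N-end-rule half-lives (mammalian, yeast,
#' E. coli; hours, open intervals at their lower bound); aromatic (F+W+Y) and
#' tiny (A+C+G+S+T) fractions; mean residue weight; charge density; 0.1%
#' absorbance for both extinction variants; charged (D+E+R+K) and aliphatic
#' (A+V+I+L) fractions.
#'
#' @param seq Validated sequence string.
#' @return Named 28-vector.
#' @export
physchem_block <- function(seq) {
  check_seq(seq, 1L, "physchem_block")
  ch <- seq_chars(seq)
  L <- length(ch)
  cnt <- as.vector(table(factor(ch, levels = AA_ALPHABET)))
  names(cnt) <- AA_ALPHABET
  mw <- sum(RESIDUE_MASS[ch]) + MASS_WATER
  instab <- if (L < 2L) 0 else
    10 / L * sum(.DIWV[cbind(ch[-L], ch[-1L])])
  aliph <- 100 * (cnt[["A"]] + 2.9 * cnt[["V"]] +
                    3.9 * (cnt[["I"]] + cnt[["L"]])) / L
  gravy <- mean(SCALE_HYDROPATHY[ch])
  n_cystine <- floor(cnt[["C"]] / 2)
  ext_cystine <- cnt[["Y"]] * EXT_TYR + cnt[["W"]] * EXT_TRP +
    n_cystine * EXT_CYSTINE
  ext_reduced <- cnt[["Y"]] * EXT_TYR + cnt[["W"]] * EXT_TRP
  atoms <- as.vector(RESIDUE_ATOMS[, ch, drop = FALSE] %*% rep(1, L)) +
    c(0, 2, 0, 1, 0)  # one water
  names(atoms) <- rownames(RESIDUE_ATOMS)
  n_neg <- cnt[["D"]] + cnt[["E"]]
  n_pos <- cnt[["R"]] + cnt[["K"]]
  qc7 <- net_charge_at(ch, 7)
  hl <- HALF_LIFE[, ch[1L]]
  out <- c(
    length = L,
    mol_weight = mw,
    pi = isoelectric_point(seq),
    instability_index = instab,
    aliphatic_index = aliph,
    gravy = gravy,
    ext_coef_cystine = ext_cystine,
    ext_coef_reduced = ext_reduced,
    atoms_C = atoms[["C"]], atoms_H = atoms[["H"]], atoms_N = atoms[["N"]],
    atoms_O = atoms[["O"]], atoms_S = atoms[["S"]],
    atoms_total = sum(atoms),
    n_negative = n_neg,
    n_positive = n_pos,
    net_charge_ph7 = qc7,
    half_life_mammalian = hl[["mammalian"]],
    half_life_yeast = hl[["yeast"]],
    half_life_ecoli = hl[["ecoli"]],
    frac_aromatic = (cnt[["F"]] + cnt[["W"]] + cnt[["Y"]]) / L,
    frac_tiny = (cnt[["A"]] + cnt[["C"]] + cnt[["G"]] + cnt[["S"]] +
                   cnt[["T"]]) / L,
    mean_residue_weight = sum(RESIDUE_MASS[ch]) / L,
    charge_density = qc7 / L,
    abs_01pct_cystine = ext_cystine / mw,
    abs_01pct_reduced = ext_reduced / mw,
    frac_charged = (n_neg + n_pos) / L,
    frac_aliphatic = (cnt[["A"]] + cnt[["V"]] + cnt[["I"]] + cnt[["L"]]) / L)
  out
}

# minimum sequence length each family needs under a given config
family_min_length <- function(family, config) {
  switch(family,
         aac = 1L, dpc = 2L, ctd = 2L,
         autocorr = config$nlag_autocorr + 1L,
         socn_qso = config$nlag_socn_qso + 1L,
         paac = config$paac_lambda + 1L,
         apaac = config$paac_lambda + 1L,
         conjoint_triad = 3L,
         aa_group = 1L,
         windowed_dipeptide = 2L,
         physchem = 1L)
}

# one record's concatenated feature vector under a config
featurize_one <- function(seq, config) {
  blocks <- lapply(config$enabled_families, function(fam) {
    v <- switch(fam,
      aac = aa_composition(seq),
      dpc = dipeptide_composition(seq),
      ctd = ctd_features(seq),
      autocorr = c(
        autocorrelation(seq, config$scales, config$nlag_autocorr,
                        "moreau_broto"),
        autocorrelation(seq, config$scales, config$nlag_autocorr, "moran"),
        autocorrelation(seq, config$scales, config$nlag_autocorr, "geary")),
      socn_qso = sequence_order_features(seq, config$nlag_socn_qso,
                                         config$qso_weight),
      paac = paac(seq, config$paac_lambda, config$paac_weight),
      apaac = apaac(seq, config$paac_lambda, config$paac_weight),
      conjoint_triad = conjoint_triad(seq),
      aa_group = aa_group_features(seq, config$group_map),
      windowed_dipeptide = windowed_dipeptide_counts(seq, config$window),
      physchem = physchem_block(seq))
    names(v) <- paste0(fam, ".", names(v))
    v
  })
  unlist(blocks)
}

#' Assemble the feature matrix for a set of records
#'
#' Concatenates the enabled descriptor family blocks, in the fixed order of
#' [descriptor_families()], into one named, ordered feature vector per
#' record. Deterministic for a fixed configuration; feature names are
#' namespaced as `family.feature` and stable across runs.
#'
#' @param records Data frame with columns `id` and `sequence` (sequences
#'   already validated), e.g. a dataset from [load_dataset()] or
#'   [read_fasta()] output after validation.
#' @param config A [descriptor_config()].
#' @param on_short `"error"` (default) stops when a record is shorter than an
#'   enabled family's minimum length; `"drop"` excludes such records with a
#'   message.
#' @return A numeric matrix, rows = records (rownames are record ids),
#'   columns = features, with attribute `config_fingerprint`.
#' @export
featurize <- function(records, config = descriptor_config(),
                      on_short = c("error", "drop")) {
  on_short <- match.arg(on_short)
  if (!all(c("id", "sequence") %in% names(records))) {
    stop("records must have columns id and sequence")
  }
  min_len <- max(vapply(config$enabled_families, family_min_length,
                        integer(1), config = config))
  too_short <- nchar(records$sequence) < min_len
  if (any(too_short)) {
    offenders <- records$id[too_short]
    if (on_short == "error") {
      stop("record(s) below the minimum length ", min_len,
           " required by the enabled families: ",
           paste(utils::head(offenders, 5), collapse = ", "))
    }
    message("featurize: dropping ", sum(too_short),
            " record(s) below minimum length ", min_len)
    records <- records[!too_short, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop("no records to featurize")
  rows <- lapply(records$sequence, featurize_one, config = config)
  X <- do.call(rbind, rows)
  rownames(X) <- records$id
  if (any(!is.finite(X))) stop("featurize produced non-finite values")
  attr(X, "config_fingerprint") <- config_fingerprint(config)
  X
}
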