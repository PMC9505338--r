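---
title: "Predicting protein melting temperatures from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein melting temperatures from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The melting temperature Tm of a protein — the temperature at which half of
a cellular protein population precipitates — is an intrinsic, largely
sequence-determined property. Experimental Tm compendia produced by thermal
proteome profiling cover tens of thousands of proteins across organisms
whose optimal growth temperatures span 15–70 °C, with protein Tm values
ranging roughly from the high 20s to almost 100 °C. `thermostab` implements
the standard machine-learning recipe for predicting Tm from sequence alone:
a wide battery of sequence-derived descriptors feeds a gradient-boosted
regression tree ensemble, the battery is pruned by recursive feature
elimination (RFE), and performance is reported with five regression
measures (PCC, RMSE, MSE, MAE, R²) plus a three-class Tm binning at 55 and
65 °C.

No single sequence feature predicts stability strongly; the signal is
spread over many weakly informative descriptors. That shapes every design
choice below: wide feature batteries, tree ensembles that tolerate
thousands of mostly uninformative columns, and aggressive feature
selection afterwards.

## The descriptor battery

`featurize()` concatenates the enabled families in a fixed order with
namespaced column names (`family.feature`); the full default battery is
2131 columns. All families are computed from the validated sequence over
the 20-letter standard alphabet; records containing ambiguous residues
(B, J, O, U, X, Z, gaps, stops) are deleted, not masked.

* **aac / dpc** — amino acid (20) and dipeptide (400) composition; each
  sums to 1.
* **ctd** (147) — composition/transition/distribution over the seven
  classic three-class physicochemical partitions (hydrophobicity,
  normalized van der Waals volume, polarity, polarizability, charge,
  secondary structure, solvent accessibility). Distribution uses the
  positions of the first, 25 %, 50 %, 75 % and last occurrence of each
  class as fractions of the length, with quantile index
  `max(1, round(q·n))`; an absent class contributes zeros.
* **autocorr** (450) — normalized Moreau–Broto, Moran and Geary
  autocorrelation at lags 1–30 over five property scales (Kyte–Doolittle
  hydropathy, Hopp–Woods hydrophilicity, side-chain mass, Grantham
  polarity, Grantham volume), each scale standardized to mean 0, sd 1 over
  the 20 residues.
* **socn_qso** (160) — sequence-order coupling numbers
  τ_d = Σ dist(R_i, R_{i+d})² for d = 1..30 under two residue distance
  matrices, plus the quasi-sequence-order composition/coupling mix
  (weight 0.1) per matrix; each QSO block sums to 1.
* **paac / apaac** (50 + 80) — classical and amphiphilic pseudo amino acid
  composition with λ = 30 correlation factors and weight 0.05; each vector
  sums to 1 by construction.
* **conjoint_triad** (343) — consecutive-triple counts over the seven
  conjoint residue classes.
* **aa_group** (12) — counts and frequencies of the six physicochemical
  groups: hydrophobic (V, I, L, F, M, W, Y, C), negatively charged (D, E),
  positively charged (R, K, H), conformational (G, P), polar (N, Q, S),
  other (A, T).
* **windowed_dipeptide** (441) — ordered pair counts over a 21-symbol
  alphabet accumulated over sliding 21-residue windows (see below).
* **physchem** (28) — a ProtParam-style block of global parameters (see
  below).

### The 441-entry windowed dipeptide block

441 ordered pairs require a 21-symbol alphabet (21² = 441). We complete
the 20 standard letters with one boundary symbol `#`, pad each sequence
with a single `#` at both termini, and count adjacent ordered pairs inside
every sliding window of 21 symbols (stride 1; a padded sequence shorter
than the window forms one truncated window). Each pair is therefore
weighted by the number of windows containing it, and pairs involving `#`
encode N-/C-terminal context. Both the alphabet and the window convention
are deliberate, documented choices: "pair counts in a window" admits
several readings, and only a 21-symbol alphabet yields exactly 441 ordered
pairs.

### The physicochemical block

The 28 columns are a fixed, versioned reconstruction of the classic global
parameter set: length; molecular weight (average residue masses + one
water); theoretical pI; instability index (Guruprasad dipeptide weights,
10/L scaling); aliphatic index; GRAVY; extinction coefficients at 280 nm
(all-cystine and all-reduced, Gill–von Hippel, cystines as
`floor(nCys/2)`); atomic composition C, H, N, O, S and total; counts of
D+E and R+K; net charge at pH 7; N-end-rule half-lives for mammalian
reticulocyte, yeast and E. coli (hours; open intervals such as ">20 h"
encoded at their lower bound, unknowns at the conservative ">10 h" bound);
aromatic and tiny fractions; mean residue weight; charge density; 0.1 %
absorbance for both extinction variants; and charged (D+E+R+K) and
aliphatic (A+V+I+L) fractions. The last two round the named parameter
families out to a fixed 28-column inventory with always-finite values.

The pI solves the Bjellqvist/Expasy net-charge equation (N-terminal pKa
depending on the first residue) by bisection on pH 0–14 to
|net charge| < 1e-4 — the approach of the eponymous web tool. On random
test sequences the block agrees with an independent implementation of the
same definitions to ~1e-5 (pI) and mass-table rounding (molecular weight).

### Residue distance matrices

The Grantham matrix is rebuilt from the published 1974 formula
(α = 1.833, β = 0.1018, γ = 0.000399 on side-chain composition, polarity
and volume, mean off-diagonal distance normalized to 100) rather than
transcribed, eliminating copy errors. The second matrix used by the
sequence-order family is a documented physicochemical distance — Euclidean
distance over the three standardized property scales that also drive PAAC
(hydropathy, hydrophilicity, side-chain mass) — exposed as `"physchem"`.
It plays the same structural role as the hydrophobicity-based distance
matrix traditional in quasi-sequence-order descriptors, for which no
verifiable offline source was available; any user-supplied 20×20 matrix
can be substituted.

### Degenerate inputs and numerical conventions

* Homopolymers: Moran and Geary autocorrelation are 0/0; both are set to 0
  with a warning. Coupling numbers are exactly 0 (zero self-distance), so
  QSO reduces to pure composition; CTD transitions are 0; PAAC correlation
  factors are 0. Nothing non-finite ever enters a feature matrix
  (`featurize()` enforces this).
* Sequences shorter than (max lag + 1) are rejected, not silently
  truncated: truncation would change feature dimensionality per record and
  break the feature-matrix contract. With the default lag 30 this sets the
  dataset minimum length of 31 residues.
* Composition-type blocks satisfy their normalizations to 1e-12; every
  family is checked against an independently coded brute-force oracle to
  1e-10 relative on random sequences.

## The regression model

`train_tm_model()` fits a gradient-boosted regression tree ensemble
(xgboost engine) with the package defaults: 150 rounds, learning rate 0.1,
maximum depth 4, no row/column subsampling, one thread. Sequence–stability
regression is dominated by many weak, largely additive effects; a capacity
profile on planted-signal data (2000 records, 10 informative of 500
features, 3 °C noise) showed depth-6 trees at 100 rounds under-perform
shallower ones even when given the true features (held-out PCC 0.902
vs 0.922), so the defaults favour moderately shallow trees. Single-thread
boosting makes training and prediction bit-reproducible for a fixed seed;
prediction aligns columns to the model's feature contract by name and
refuses missing columns rather than silently reindexing.

## Feature selection

`rfe_select()` recursively prunes the least important 10 % of remaining
features per round (minimum one; the path is clamped to land exactly on
each requested size), using the ensemble's gain importances; features
never used by any tree rank lowest, with ties broken by stable column
order. The default candidate grid is 50, 100, 200, 300, 500, 1000, 2000,
3000 and all features. Per-size scores come from k-fold cross-validation
(pooled out-of-fold predictions); the chosen size maximizes CV PCC with
ties broken toward the smaller size, since a smaller feature set covers
the space of feature combinations better. `rfecv_select()` is the same
protocol with the size chosen by an inner 3-fold CV; `select_features()`
runs the path straight to the final-model default of 200 retained
features. The fractional step keeps the elimination path short at
thousands of features while staying fine-grained near small sizes (the
step is not part of the published protocol and is configurable).

## Evaluation

All five measures use population (1/N) normalization, exactly as their
defining formulas are written — no n−1 sample correction. R² may be
negative (a predictor worse than the constant mean). MSE is reported in
squared degrees, the natural unit of a squared error, even though
performance tables in this literature sometimes label it "°C". The
three-class binning assigns boundary values to the upper category's closed
side (55 → mid, 65 → high); the interval notation "Tm < 55, 55 < Tm < 65,
Tm > 65" leaves the boundaries unassigned, and a half-open convention
guarantees a total partition.

## The synthetic benchmark generator

Real Tm compendia require large downloads; the generator provides planted
ground truth at desk scale instead.

* `generate_sequences()` draws i.i.d. sequences (default uniform residue
  composition, lengths uniform on 50–1000, the length range typical of the
  real training tables).
* `plant_tm()` computes a small set of signal descriptors, z-scores each
  across the cohort, and sets
  Tm = 50 + Σ w_f·z_f + N(0, 3²) °C. The default ten signal features come
  from cheap families (five of the six group frequencies — the sixth is
  omitted because the six sum to one and the weights would otherwise be
  unidentifiable — GRAVY, length, aromatic fraction, net charge, and the
  instability index) with weights of magnitude 3 and alternating sign: a
  planted signal of ≈9.5 °C sd against 3 °C noise, mimicking the dynamic
  range of real Tm distributions around a 50 °C mesophile centre.
* `simulate_feature_matrix()` is the model-layer benchmark: i.i.d. N(0,1)
  columns with a linear signal in the first k, used for the selection and
  recovery experiments (2000 × 500 with 10 informative columns at 3 °C
  noise) — selection protocol behaviour does not depend on the descriptor
  arithmetic, and no descriptor configuration yields exactly 500 columns.

What the generator does **not** emulate: residue composition bias,
homology and phylogenetic correlation between records, species/OGT block
structure (an optional per-group intercept shift exists but is off by
default), length–composition coupling, and any nonlinear or epistatic
dependence of Tm on sequence. Passing recovery tests therefore
demonstrates that the pipeline's machinery — featurization, training,
selection, evaluation — is correct and well-calibrated, not that the
package attains any particular accuracy on real proteomes.

## Problem sizes used by the test-suite experiments

Structural checks run on single sequences; oracle comparisons use 100
random sequences of 40–80 residues per family and 1000 random vector
pairs for the metrics; the selection and recovery experiments use the
2000-record, 500-feature planted-signal matrix with an 80/20 held-out
split; end-to-end pipeline checks use 100–120 record cohorts with the
cheap descriptor families. These sizes were chosen so the full suite
exercises every code path at the generator's reference conditions on a
single CPU.

## Known limitations

* The exact inventory of the historical 6000+-column batteries behind
  published Tm predictors is not recoverable from their descriptions; this
  package's battery is a faithful reconstruction of the named families,
  not a column-for-column replica, and headline accuracies published for
  models trained on the real 34,913-protein compendium are not
  reproducible without that data set.
* The windowed-dipeptide and CTD-distribution conventions are explicit
  choices among several defensible readings (documented above).
* Charge-density (quantum-theoretic) and hierarchical thermodynamic
  descriptor sets are not implemented: the first's software is defunct and
  its features were reported uninformative for stability; the second's
  19-feature inventory is unspecified.
* The multi-layer-perceptron baseline uses a single hidden layer of 20
  units (the environment's neural engine), not a three-layer (20, 20, 20)
  stack; it is an optional baseline, not part of the default path.
* Half-life features are coarse N-end-rule lookups; within any one
  organism class they carry little signal and are retained for inventory
  completeness.
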