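# Per-family correctness against the brute-force oracles, normalization
# invariants, degenerate-input conventions, and featurize assembly.

test_that("amino acid composition matches direct counting", {
  expect_equal(aa_composition("AAAA")[["A"]], 1.0)
  expect_true(all(aa_composition("AAAA")[-1] == 0 |
                    names(aa_composition("AAAA"))[-1] == "A"))
  v <- aa_composition("ACAC")
  expect_equal(v[["A"]], 0.5)
  expect_equal(v[["C"]], 0.5)
  v <- aa_composition("MKVLA")
  expect_equal(unname(v[c("M", "K", "V", "L", "A")]), rep(0.2, 5))
  withr::with_seed(31, {
    for (i in 1:20) {
      s <- random_seq(sample(5:120, 1))
      expect_equal(aa_composition(s), oracle_aac(s), tolerance = 1e-12)
    }
  })
})

test_that("dipeptide composition enumerates adjacent pairs", {
  expect_equal(dipeptide_composition("AAA")[["AA"]], 1.0)
  v <- dipeptide_composition("ACAC")
  expect_equal(v[["AC"]], 2 / 3)
  expect_equal(v[["CA"]], 1 / 3)
  withr::with_seed(32, {
    for (i in 1:10) {
      s <- random_seq(sample(5:80, 1))
      expect_equal(dipeptide_composition(s), oracle_dpc(s),
                   tolerance = 1e-12)
    }
  })
  expect_error(dipeptide_composition("A"), "length")
})

test_that("windowed dipeptide counts have length 441 and match window enumeration", {
  withr::with_seed(33, s <- random_seq(100))
  v <- windowed_dipeptide_counts(s)
  expect_length(v, 441L)
  expect_equal(v, oracle_wdc(s), tolerance = 1e-12)
  # short sequence: single truncated window, plain pair counts
  expect_equal(windowed_dipeptide_counts("AAA", window = 21)[["AA"]], 2)
  # window conventions across lengths straddling the window size
  withr::with_seed(34, {
    for (len in c(5, 19, 20, 21, 22, 40, 150)) {
      s <- random_seq(len)
      expect_equal(windowed_dipeptide_counts(s), oracle_wdc(s),
                   tolerance = 1e-12)
    }
  })
  expect_error(windowed_dipeptide_counts("ACDEF", window = 1), "window")
})

test_that("six-group features count and normalize the physicochemical groups", {
  v <- aa_group_features("DDEE")
  expect_equal(v[["count_negative"]], 4)
  expect_equal(v[["freq_negative"]], 1.0)
  expect_equal(sum(v[paste0("count_",
                            setdiff(names(thermostab:::AA_SIX_GROUPS),
                                    "negative"))]), 0)
  v <- aa_group_features("VILFMWYC")
  expect_equal(v[["count_hydrophobic"]], 8)
  expect_equal(v[["freq_hydrophobic"]], 1.0)
  withr::with_seed(35, {
    for (i in 1:10) {
      s <- random_seq(sample(10:200, 1))
      v <- aa_group_features(s)
      expect_equal(sum(v[1:6]), nchar(s))
      expect_equal(sum(v[7:12]), 1.0, tolerance = 1e-12)
      expect_equal(unname(v), unname(
        oracle_group_features(s, thermostab:::AA_SIX_GROUPS)),
        tolerance = 1e-12)
    }
  })
})

test_that("CTD features match the direct definition and normalize", {
  withr::with_seed(36, s <- random_seq(60))
  v <- ctd_features(s)
  expect_length(v, 147L)
  props <- thermostab:::CTD_PROPERTIES
  for (p in names(props)) {
    block <- v[startsWith(names(v), paste0(p, "."))]
    expect_equal(unname(block), oracle_ctd_one(s, props[[p]]),
                 tolerance = 1e-12)
    expect_equal(sum(block[1:3]), 1.0, tolerance = 1e-12)
  }
})

test_that("homopolymer CTD: one composition class 1, all transitions 0", {
  v <- ctd_features(strrep("G", 30))
  comp <- v[grepl("\\.comp\\.", names(v))]
  trans <- v[grepl("\\.trans\\.", names(v))]
  expect_true(all(tapply(comp, rep(1:7, each = 3), max) == 1))
  expect_true(all(trans == 0))
  expect_true(all(is.finite(v)))
})

test_that("autocorrelation families match brute-force sums", {
  scales <- list(hyd = thermostab:::SCALE_HYDROPATHY,
                 vol = thermostab:::GRANTHAM_VOLUME)
  withr::with_seed(37, {
    for (i in 1:5) {
      s <- random_seq(80)
      for (kind in c("moreau_broto", "moran", "geary")) {
        v <- autocorrelation(s, scales, nlag = 5, kind = kind)
        expect_length(v, 10L)
        for (sc in names(scales)) {
          expect_equal(unname(v[paste0(kind, ".", sc, ".lag", 1:5)]),
                       oracle_autocorr(s, scales[[sc]], 5, kind),
                       tolerance = 1e-10)
        }
      }
    }
  })
  expect_error(autocorrelation("ACDEF", scales, nlag = 10), "exceed")
})

test_that("homopolymer autocorrelation follows the zero-variance convention", {
  s <- strrep("A", 40)
  one <- list(hyd = thermostab:::SCALE_HYDROPATHY)
  expect_warning(v <- autocorrelation(s, one, nlag = 3, kind = "moran"),
                 "zero-variance")
  expect_true(all(v == 0))
  expect_warning(v <- autocorrelation(s, one, nlag = 3, kind = "geary"),
                 "zero-variance")
  expect_true(all(v == 0))
  # Moreau-Broto on a homopolymer equals the squared standardized scale
  # value of that residue at every lag
  sc <- thermostab:::default_scales()
  v <- autocorrelation(s, sc, nlag = 3, kind = "moreau_broto")
  expected <- rep(vapply(sc, function(x)
    thermostab:::standardize_scale(x)[["A"]]^2, numeric(1)), each = 3)
  expect_equal(unname(v), unname(expected), tolerance = 1e-12)
})

test_that("sequence-order coupling numbers and QSO match the direct formulas", {
  mats <- thermostab:::socn_distance_matrices()
  withr::with_seed(38, {
    for (i in 1:5) {
      s <- random_seq(50)
      v <- sequence_order_features(s, nlag = 3, weight = 0.1)
      for (mn in names(mats)) {
        expect_equal(unname(v[paste0("socn.", mn, ".lag", 1:3)]),
                     oracle_socn(s, mats[[mn]], 3), tolerance = 1e-10)
        q <- v[startsWith(names(v), paste0("qso.", mn, "."))]
        expect_equal(unname(q), unname(oracle_qso(s, mats[[mn]], 3, 0.1)),
                     tolerance = 1e-10)
        expect_equal(sum(q), 1.0, tolerance = 1e-12)
      }
    }
  })
  # homopolymer: zero self-distance, QSO reduces to pure composition
  v <- sequence_order_features(strrep("K", 40), nlag = 4)
  expect_true(all(v[startsWith(names(v), "socn.")] == 0))
  expect_equal(v[["qso.grantham.K"]], 1.0)
  expect_error(sequence_order_features("ACDEF", nlag = 10), "exceed")
})

test_that("PAAC and APAAC match the direct formulas and sum to one", {
  h1 <- thermostab:::SCALE_HYDROPATHY
  h2 <- thermostab:::SCALE_HYDROPHILICITY
  h3 <- thermostab:::SCALE_SIDECHAIN_MASS
  withr::with_seed(39, {
    for (i in 1:5) {
      s <- random_seq(60)
      vp <- paac(s, lambda = 4, weight = 0.05)
      expect_length(vp, 24L)
      expect_equal(unname(vp), unname(oracle_paac(s, 4, 0.05, h1, h2, h3)),
                   tolerance = 1e-10)
      expect_equal(sum(vp), 1.0, tolerance = 1e-12)
      va <- apaac(s, lambda = 4, weight = 0.05)
      expect_length(va, 28L)
      expect_equal(unname(va), unname(oracle_apaac(s, 4, 0.05, h1, h2)),
                   tolerance = 1e-10)
      expect_equal(sum(va), 1.0, tolerance = 1e-12)
    }
  })
  expect_error(paac("ACDEF", lambda = 30), "exceed")
})

test_that("PAAC with vanishing weight approaches plain composition", {
  withr::with_seed(40, s <- random_seq(50))
  v <- paac(s, lambda = 3, weight = 1e-12)
  expect_equal(unname(v[1:20]), unname(aa_composition(s)),
               tolerance = 1e-8)
})

test_that("conjoint triads count class triples", {
  v <- conjoint_triad(strrep("A", 5))
  expect_equal(sum(v > 0), 1L)
  expect_equal(max(v), 3)
  withr::with_seed(41, {
    for (i in 1:5) {
      s <- random_seq(40)
      v <- conjoint_triad(s)
      expect_equal(sum(v), nchar(s) - 2)
      expect_equal(unname(v), unname(
        oracle_conjoint(s, thermostab:::CONJOINT_CLASSES)),
        tolerance = 1e-12)
    }
  })
  expect_error(conjoint_triad("AC"), "length")
})

test_that("physicochemical block has the documented 28-column inventory", {
  withr::with_seed(42, s <- random_seq(70))
  v <- physchem_block(s)
  expect_length(v, 28L)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_true(all(is.finite(v)))
})

test_that("GRAVY and molecular weight agree with table lookups", {
  kd_ala <- thermostab:::SCALE_HYDROPATHY[["A"]]
  expect_equal(physchem_block("AAAA")[["gravy"]], kd_ala)
  expect_equal(physchem_block("G")[["mol_weight"]],
               thermostab:::RESIDUE_MASS[["G"]] + thermostab:::MASS_WATER)
})

test_that("pI solves the net-charge equation", {
  withr::with_seed(43, {
    for (i in 1:5) {
      s <- random_seq(60)
      pi_val <- isoelectric_point(s)
      q <- thermostab:::net_charge_at(strsplit(s, "")[[1]], pi_val)
      expect_lt(abs(q), 1e-4)
    }
  })
  # acidic vs basic sequences order correctly
  expect_lt(isoelectric_point(strrep("DE", 20)),
            isoelectric_point(strrep("KR", 20)))
})

test_that("featurize assembles enabled families with stable namespaced names", {
  withr::with_seed(44, {
    recs <- data.frame(id = c("a", "b", "c"),
                       sequence = replicate(3, random_seq(60)))
  })
  cfg <- descriptor_config(
    enabled_families = c("aa_group", "windowed_dipeptide", "physchem"))
  X <- featurize(recs, cfg)
  expect_equal(dim(X), c(3L, 12L + 441L + 28L))
  expect_false(anyDuplicated(colnames(X)) > 0)
  X2 <- featurize(recs, cfg)
  expect_identical(colnames(X), colnames(X2))
  expect_identical(X, X2)
})

test_that("featurize is permutation-equivariant and duplicates give equal rows", {
  withr::with_seed(45, {
    recs <- data.frame(id = c("a", "b", "c"),
                       sequence = c(random_seq(50), random_seq(50),
                                    random_seq(50)))
  })
  recs$sequence[3] <- recs$sequence[1]
  cfg <- descriptor_config(enabled_families = c("aac", "aa_group"))
  X <- featurize(recs, cfg)
  Xp <- featurize(recs[c(3, 1, 2), ], cfg)
  expect_equal(X[c(3, 1, 2), ], Xp, ignore_attr = TRUE)
  expect_equal(unname(X["a", ]), unname(X["c", ]))
})

test_that("featurize enforces family length preconditions", {
  recs <- data.frame(id = c("ok", "short"),
                     sequence = c(strrep("ACDEFGIKLM", 10), "ACDEF"))
  cfg <- descriptor_config()   # default lags require length > 30
  expect_error(featurize(recs, cfg), "short")
  expect_message(X <- featurize(recs, cfg, on_short = "drop"), "dropping")
  expect_equal(rownames(X), "ok")
})

test_that("descriptor_config validates its parameters", {
  expect_error(descriptor_config(paac_weight = 0), "paac_weight")
  expect_error(descriptor_config(window = 1), "window")
  bad_map <- thermostab:::AA_SIX_GROUPS
  bad_map$other <- "A"  # drops T
  expect_error(descriptor_config(group_map = bad_map), "partition")
  expect_error(descriptor_config(enabled_families = "nope"), "unknown")
})
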