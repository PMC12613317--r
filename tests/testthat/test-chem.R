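# Descriptor layer: canonicalization, fingerprints, Tanimoto, logP, charges.

test_that("canonicalization maps equivalent notations to one form and is idempotent", {
  kek <- canonicalizeSmiles("OC1=CC=CC=C1")
  aro <- canonicalizeSmiles("Oc1ccccc1")
  expect_identical(kek, aro)
  expect_identical(canonicalizeSmiles(aro), aro)
  expect_error(canonicalizeSmiles("not_a_smiles"), "unparsable.*not_a_smiles")
  expect_error(canonicalizeSmiles(""), "non-empty")
})

test_that("fingerprints have the contracted length, set bits, and are notation-invariant", {
  fp <- smilesFingerprint("Oc1ccccc1")
  expect_length(fp, 1024L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gt(sum(smilesFingerprint("CCO")), 0)
  # invariance under re-notation (aromatic vs kekulized, atom reordering)
  pairs <- list(c("Oc1ccccc1", "OC1=CC=CC=C1"),
                c("c1ccccc1C(=O)O", "OC(=O)c1ccccc1"),
                c("CCN", "NCC"),
                c("CC(=O)Oc1ccccc1", "c1ccccc1OC(C)=O"))
  for (p in pairs)
    expect_identical(smilesFingerprint(p[1]), smilesFingerprint(p[2]))
  # folding to a divisor length
  expect_length(smilesFingerprint("CCO", nBits = 256L), 256L)
  expect_error(smilesFingerprint("CCO", nBits = 1000L), "divisor")
  # degenerate molecules with no paths are rejected, not silently zero
  expect_error(smilesFingerprint("C"), "degenerate")
})

test_that("tanimoto matches set arithmetic and honours its contracts", {
  # a-only bits {1,2,3}, b-only {3,4}: a=3, b=2, c=1 -> 1/4
  fa <- integer(8); fa[c(1, 2, 3)] <- 1L
  fb <- integer(8); fb[c(3, 4)] <- 1L
  expect_equal(tanimoto(fa, fb), 0.25)
  # self-identity and disjoint vectors
  f <- randomFingerprint(64)
  expect_identical(tanimoto(f, f), 1)
  d1 <- integer(8); d1[1:2] <- 1L
  d2 <- integer(8); d2[5:6] <- 1L
  expect_identical(tanimoto(d1, d2), 0)
  # error contracts
  expect_error(tanimoto(integer(8), integer(16)), "length mismatch")
  expect_error(tanimoto(integer(8), integer(8)), "all-zero")
})

test_that("tanimoto agrees with the set-arithmetic oracle on random pairs", {
  set.seed(42)
  for (i in 1:120) {
    fa <- randomFingerprint(128)
    fb <- randomFingerprint(128)
    ti <- tanimoto(fa, fb)
    expect_identical(ti, oracleTanimoto(fa, fb))
    expect_identical(ti, tanimoto(fb, fa))  # symmetry
    expect_true(ti >= 0 && ti <= 1)
  }
})

test_that("similarity to the reference scaffolds is exactly 1 for the scaffolds themselves", {
  refs <- referenceScaffolds()
  expect_identical(similarityToReference("Oc1ccccc1", "analyte", refs), 1)
  expect_identical(
    similarityToReference("CCCCCCCCCCCCCCCCCCCCC[S-]", "ligand", refs), 1)
  # phenol is at least as phenol-like as bare benzene; both sides recomputed
  # through the set-arithmetic oracle
  ref <- smilesFingerprint("Oc1ccccc1")
  sPhenol <- oracleTanimoto(smilesFingerprint("Oc1ccccc1"), ref)
  sBenzene <- oracleTanimoto(smilesFingerprint("c1ccccc1"), ref)
  expect_gte(sPhenol, sBenzene)
  expect_equal(similarityToReference("c1ccccc1", "analyte", refs), sBenzene)
})

test_that("reference scaffolds default to the canonical strings and must parse", {
  refs <- referenceScaffolds()
  expect_identical(refs@analyteReference, "Oc1ccccc1")
  expect_identical(refs@ligandReference, "CCCCCCCCCCCCCCCCCCCCC[S-]")
  expect_error(referenceScaffolds(analyteReference = "xx"), "unparsable")
})

test_that("Crippen logP is notation-invariant and reproduces reference values", {
  expect_identical(crippenLogP("OC1=CC=CC=C1"), crippenLogP("Oc1ccccc1"))
  # frozen Wildman-Crippen reference values (independently computed with a
  # second implementation of the same parameterization)
  expect_equal(crippenLogP("Oc1ccccc1"), 1.3922, tolerance = 1e-3)
  expect_equal(crippenLogP("CCCCCCCCCCCCCCCCCCCCC[S-]"), 7.9651,
               tolerance = 1e-3)
  expect_equal(crippenLogP("CCO"), -0.0014, tolerance = 1e-3)
  # a long alkylthiolate is far more hydrophobic than a short polyether
  expect_gt(crippenLogP("CCCCCCCCCCCCCCCCCCCCC[S-]"),
            crippenLogP("CCOCCOCCO"))
})

test_that("charge difference is symmetric, non-negative and zero iff equal", {
  expect_identical(chargeDifference(-1, 1), 2)
  expect_identical(chargeDifference(0, 0), 0)
  expect_identical(chargeDifference(1, -1), chargeDifference(-1, 1))
  set.seed(1)
  for (i in 1:50) {
    x <- sample(-3:3, 1); y <- sample(-3:3, 1)
    expect_identical(chargeDifference(x, y), chargeDifference(y, x))
    expect_identical(chargeDifference(x, y) == 0, x == y)
  }
  expect_error(chargeDifference(0.5, 1), "integer")
})

test_that("rule-based charge assignment handles the documented pH 7.4 rules", {
  expect_message(chg <- assignChargeByRules("CC(=O)O"), "net -1")
  expect_identical(chg, -1L)
  expect_message(chg <- assignChargeByRules("CCN"), "net \\+1")
  expect_identical(chg, 1L)
  expect_message(chg <- assignChargeByRules("Oc1ccccc1"), "net \\+0")
  expect_identical(chg, 0L)
  # explicit charges in the SMILES are the starting point
  expect_message(chg <- assignChargeByRules("CCCCS(=O)(=O)[O-]"), "net -1")
  expect_identical(chg, -1L)
})

test_that("moleculeRecord computes and validates all descriptors", {
  m <- moleculeRecord("phenol", "OC1=CC=CC=C1", "analyte", 0)
  expect_s4_class(m, "MoleculeRecord")
  expect_identical(smiles(m), canonicalizeSmiles("Oc1ccccc1"))
  expect_identical(moleculeRole(m), "analyte")
  expect_identical(netCharge(m), 0L)
  expect_length(fingerprintBits(m), 1024L)
  expect_equal(logP(m), crippenLogP("Oc1ccccc1"))
  expect_error(moleculeRecord("x", "CCO", "solvent", 0))
  expect_error(moleculeRecord("x", "bad(((", "analyte", 0), "unparsable")
})
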