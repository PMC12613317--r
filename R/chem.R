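# Descriptor layer: SMILES handling, hashed path fingerprints, Tanimoto
# similarity, Wildman-Crippen logP and charge difference. All molecular
# perception goes through OpenBabel (ChemmineOB); the fingerprint dialect is
# FP2, a 1024-bit Daylight-style hashed linear-path fingerprint (paths up to
# 7 atoms). Absolute Tanimoto values depend on the dialect, so it is recorded
# in every model's provenance.

.FP_DIALECT <- "openbabel-FP2-1024bit-path"

# Run f on the OBMol parsed from one SMILES, with a structured parse error.
.withMol <- function(smiles, f) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("SMILES must be a single non-empty string", call. = FALSE)
  out <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) f(m)),
    error = function(e) stop(sprintf("unparsable SMILES: '%s'", smiles),
                             call. = FALSE))
  out
}

#' Canonicalize a SMILES string
#'
#' Converts any valid SMILES notation of a molecule to its canonical form,
#' so that two notations of the same structure map to one string. Idempotent.
#'
#' @param smiles a single SMILES string
#' @return the canonical SMILES string
#' @examples
#' canonicalizeSmiles("OC1=CC=CC=C1")  # kekulized phenol -> aromatic form
#' @export
canonicalizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("SMILES must be a single non-empty string", call. = FALSE)
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", smiles),
                  error = function(e) "")
  out <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(out))
    stop(sprintf("unparsable SMILES: '%s'", smiles), call. = FALSE)
  out
}

#' Hashed path fingerprint of a molecule
#'
#' 1024-bit hashed linear-path (Daylight-style) topological fingerprint.
#' Deterministic for a fixed canonical structure; invariant under SMILES
#' re-notation. Molecules whose fingerprint has no bits set (single atoms,
#' bare ions) are rejected because their Tanimoto similarity is undefined.
#'
#' @param smiles a single SMILES string
#' @param nBits fingerprint length; 1024 (native) or a divisor of 1024, in
#'   which case the native fingerprint is folded by OR
#' @return integer vector of 0/1 of length `nBits`
#' @export
smilesFingerprint <- function(smiles, nBits = 1024L) {
  nBits <- as.integer(nBits)
  if (nBits < 1L || 1024L %% nBits != 0L)
    stop("nBits must be a positive divisor of 1024", call. = FALSE)
  fp <- .withMol(smiles, function(m) ChemmineOB::fingerprint_OB(list(m), "FP2"))
  fp <- as.integer(fp[[1]])
  if (nBits < 1024L) {
    fp <- as.integer(colSums(matrix(fp, nrow = 1024L %/% nBits,
                                    byrow = TRUE)) > 0L)
  }
  if (sum(fp) == 0L)
    stop(sprintf(
      "degenerate molecule '%s': fingerprint has no bits set (no paths)",
      smiles), call. = FALSE)
  fp
}

#' Tanimoto similarity of two fingerprint bit vectors
#'
#' T = c / (a + b - c), where a and b are the per-vector popcounts and c the
#' popcount of the bitwise AND. Symmetric, bounded in \[0,1\], and exactly 1
#' for identical non-empty vectors. Two all-zero vectors have no defined
#' similarity (0/0) and raise an error.
#'
#' @param fpA,fpB equal-length 0/1 vectors
#' @return Tanimoto coefficient in \[0,1\]
#' @export
tanimoto <- function(fpA, fpB) {
  if (length(fpA) != length(fpB))
    stop("fingerprint length mismatch: ", length(fpA), " vs ", length(fpB),
         call. = FALSE)
  a <- sum(fpA != 0)
  b <- sum(fpB != 0)
  c <- sum(fpA != 0 & fpB != 0)
  if (a + b == 0)
    stop("Tanimoto undefined for two all-zero fingerprints", call. = FALSE)
  c / (a + b - c)
}

#' Reference scaffolds for similarity descriptors
#'
#' Analytes are compared to a phenol scaffold, ligands to a
#' heneicosanethiolate (C21 alkyl thiolate) scaffold. Ligand SMILES are
#' accepted in thiol or thiolate form and used as given; note the ligand
#' reference itself is a thiolate, so thiol/thiolate notation affects the
#' similarity descriptor.
#'
#' @param analyteReference SMILES for the analyte reference
#' @param ligandReference SMILES for the ligand reference
#' @return a [ReferenceScaffolds-class] object
#' @export
referenceScaffolds <- function(analyteReference = "Oc1ccccc1",
                               ligandReference = "CCCCCCCCCCCCCCCCCCCCC[S-]") {
  canonicalizeSmiles(analyteReference)  # both must parse
  canonicalizeSmiles(ligandReference)
  new("ReferenceScaffolds", analyteReference = analyteReference,
      ligandReference = ligandReference)
}

#' Tanimoto similarity of a molecule to its role's reference scaffold
#'
#' @param smiles molecule SMILES
#' @param role `"ligand"` or `"analyte"`; selects the reference
#' @param refs a [ReferenceScaffolds-class] object
#' @return Tanimoto coefficient in \[0,1\]
#' @export
similarityToReference <- function(smiles, role, refs = referenceScaffolds()) {
  role <- match.arg(role, c("ligand", "analyte"))
  ref <- if (role == "analyte") refs@analyteReference else refs@ligandReference
  tanimoto(smilesFingerprint(smiles), smilesFingerprint(ref))
}

#' Wildman-Crippen logP
#'
#' Octanol/water partition coefficient estimated by summing Wildman-Crippen
#' atomic contributions; the standard cheminformatics hydrophobicity
#' descriptor. Deterministic and invariant under SMILES re-notation.
#'
#' @param smiles a single SMILES string
#' @return logP (dimensionless)
#' @export
crippenLogP <- function(smiles) {
  p <- .withMol(smiles, function(m) ChemmineOB::prop_OB(list(m)))
  as.numeric(p[[1]]$logP)
}

#' Absolute ligand-analyte charge difference
#'
#' The charge-complementarity descriptor: |ligand charge - analyte charge|
#' in elementary charges, using net formal charges at pH 7.4. Symmetric in
#' its arguments.
#'
#' @param ligandCharge,analyteCharge integer net charges
#' @return non-negative number
#' @export
chargeDifference <- function(ligandCharge, analyteCharge) {
  if (!is.numeric(ligandCharge) || !is.numeric(analyteCharge) ||
      ligandCharge != round(ligandCharge) || analyteCharge != round(analyteCharge))
    stop("charges must be integers (elementary charges)", call. = FALSE)
  abs(ligandCharge - analyteCharge)
}

#' Rule-based net charge at pH 7.4 (convenience assigner)
#'
#' Starts from the explicit formal charges in the SMILES and applies simple
#' protonation rules for pH 7.4: each neutral carboxylic or sulfonic acid is
#' deprotonated (-1); each neutral aliphatic amine or amidine is protonated
#' (+1). Every assignment is reported via [message()] for audit. This is a
#' convenience only -- curated charges should be supplied with the dataset.
#'
#' @param smiles a single SMILES string
#' @return integer net charge
#' @export
assignChargeByRules <- function(smiles) {
  can <- canonicalizeSmiles(smiles)
  explicit <- .explicitCharge(can)
  counts <- .withMol(can, function(m) {
    vapply(c(acid = "[CX3](=O)[OX2H1]",
             sulfonic = "[SX4](=O)(=O)[OX2H1]",
             amine = "[NX3;H2,H1;!$(NC=O);!$(N-a);!$(N=*)]",
             amidine = "[NX3][CX3]=[NX2]"),
           function(q) as.numeric(
             ChemmineOB::smartsSearch_OB(list(m), q, uniqueMatches = TRUE)),
           numeric(1))
  })[[1]]
  rules <- -counts[["acid"]] - counts[["sulfonic"]] +
    counts[["amine"]] + counts[["amidine"]]
  total <- as.integer(explicit + rules)
  message(sprintf(
    "charge rules for '%s': explicit %+d, acids %d, sulfonic %d, amines %d, amidines %d -> net %+d at pH 7.4",
    can, explicit, counts[["acid"]], counts[["sulfonic"]], counts[["amine"]],
    counts[["amidine"]], total))
  total
}

# Sum of explicit formal charges in bracket atoms of a SMILES string.
.explicitCharge <- function(smiles) {
  atoms <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (!length(atoms)) return(0L)
  chg <- vapply(atoms, function(a) {
    m <- regmatches(a, regexpr("[+-][0-9]*", a))
    if (!length(m) || !nzchar(m)) return(0L)
    sign <- if (substr(m, 1, 1) == "+") 1L else -1L
    num <- substring(m, 2)
    # "[O-]" -> 1; "[Fe+2]" -> 2; "++" shorthand is not produced by OpenBabel
    sign * (if (nzchar(num)) as.integer(num) else 1L)
  }, integer(1))
  as.integer(sum(chg))
}

#' Construct a MoleculeRecord
#'
#' Canonicalizes the SMILES and computes the logP and fingerprint
#' descriptors.
#'
#' @param id short identifier
#' @param smiles SMILES string (any valid notation)
#' @param role `"ligand"` or `"analyte"`
#' @param netCharge integer net formal charge at pH 7.4
#' @return a [MoleculeRecord-class] object
#' @examples
#' moleculeRecord("phenol", "Oc1ccccc1", "analyte", 0)
#' @export
moleculeRecord <- function(id, smiles, role, netCharge = 0L) {
  role <- match.arg(role, c("ligand", "analyte"))
  if (netCharge != round(netCharge))
    stop("netCharge must be an integer", call. = FALSE)
  can <- canonicalizeSmiles(smiles)
  new("MoleculeRecord", id = as.character(id), smiles = can, role = role,
      netCharge = as.integer(netCharge), logp = crippenLogP(can),
      fingerprint = smilesFingerprint(can))
}

#' @describeIn moleculeRecord display a molecule record
#' @param object a `MoleculeRecord`
#' @export
setMethod("show", "MoleculeRecord", function(object) {
  cat(sprintf("MoleculeRecord '%s' (%s)\n  SMILES: %s\n  charge: %+d  logP: %.4f  fingerprint bits: %d/1024\n",
              object@id, object@role, object@smiles, object@netCharge,
              object@logp, sum(object@fingerprint)))
})

# --- accessors ---------------------------------------------------------------

#' @rdname MoleculeRecord-class
#' @param x a `MoleculeRecord`
#' @export
setGeneric("smiles", function(x) standardGeneric("smiles"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("smiles", "MoleculeRecord", function(x) x@smiles)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("moleculeRole", function(x) standardGeneric("moleculeRole"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("moleculeRole", "MoleculeRecord", function(x) x@role)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("netCharge", "MoleculeRecord", function(x) x@netCharge)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("logP", function(x) standardGeneric("logP"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("logP", "MoleculeRecord", function(x) x@logp)

#' @rdname MoleculeRecord-class
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))
#' @rdname MoleculeRecord-class
#' @export
setMethod("fingerprintBits", "MoleculeRecord", function(x) x@fingerprint)
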