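#' @import methods
NULL

.FEATURE_NAMES <- c("charge_difference", "ligand_logp", "analyte_logp",
                    "ligand_tanimoto", "analyte_tanimoto")

#' MoleculeRecord: one ligand or analyte with its computed descriptors
#'
#' Holds a canonicalized SMILES string, the molecule's role on the
#' nanoparticle-analyte pair (monolayer ligand or analyte guest), its net
#' formal charge at pH 7.4 (elementary charges), its Wildman-Crippen logP
#' and a 1024-bit hashed path fingerprint.
#'
#' @slot id short identifier
#' @slot smiles canonical SMILES
#' @slot role `"ligand"` or `"analyte"`
#' @slot netCharge integer net formal charge at pH 7.4
#' @slot logp Wildman-Crippen logP (dimensionless)
#' @slot fingerprint integer vector of 0/1, length 1024
#' @exportClass MoleculeRecord
setClass("MoleculeRecord",
  representation(id = "character", smiles = "character", role = "character",
                 netCharge = "integer", logp = "numeric",
                 fingerprint = "integer"))

setValidity("MoleculeRecord", function(object) {
  msg <- character()
  if (!object@role %in% c("ligand", "analyte"))
    msg <- c(msg, "role must be 'ligand' or 'analyte'")
  if (length(object@fingerprint) != 1024L)
    msg <- c(msg, "fingerprint must have exactly 1024 bits")
  if (length(object@fingerprint) && !all(object@fingerprint %in% c(0L, 1L)))
    msg <- c(msg, "fingerprint entries must be 0/1")
  if (length(object@fingerprint) && sum(object@fingerprint) == 0L)
    msg <- c(msg, "all-zero fingerprint (degenerate molecule)")
  if (length(msg)) msg else TRUE
})

#' ReferenceScaffolds: the two fixed similarity reference molecules
#'
#' Analyte similarity is measured against a phenol scaffold and ligand
#' similarity against a heneicosanethiolate (C21 alkyl thiolate) scaffold.
#' Both are configurable; the defaults are the canonical choices for this
#' scoring function and must not be changed when evaluating the frozen
#' published model.
#'
#' @slot analyteReference SMILES of the analyte reference (default phenol)
#' @slot ligandReference SMILES of the ligand reference (default
#'   heneicosanethiolate)
#' @exportClass ReferenceScaffolds
setClass("ReferenceScaffolds",
  representation(analyteReference = "character", ligandReference = "character"))

#' ScoringModel: intercept plus five named linear coefficients
#'
#' A linear model mapping the 5-descriptor feature vector to a binding free
#' energy in kcal/mol. Coefficients are stored unscaled (raw feature units);
#' scaled (standardized-space) coefficients and the scaling parameters that
#' link the two are optional metadata used for feature-importance ranking.
#'
#' @slot intercept numeric, kcal/mol
#' @slot coefficients named numeric of length 5 (unscaled)
#' @slot scaledCoefficients named numeric of length 5 or 0
#' @slot scaling list with elements `means` and `sds` (may be empty)
#' @slot provenance free-text description (fingerprint dialect, training data)
#' @exportClass ScoringModel
setClass("ScoringModel",
  representation(intercept = "numeric", coefficients = "numeric",
                 scaledCoefficients = "numeric", scaling = "list",
                 provenance = "character"))

setValidity("ScoringModel", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  if (!identical(names(object@coefficients), .FEATURE_NAMES))
    msg <- c(msg, sprintf("coefficients must be named exactly: %s",
                          paste(.FEATURE_NAMES, collapse = ", ")))
  if (length(object@scaledCoefficients) &&
      !identical(names(object@scaledCoefficients), .FEATURE_NAMES))
    msg <- c(msg, "scaledCoefficients names must match the feature names")
  if (length(object@scaling)) {
    if (!all(c("means", "sds") %in% names(object@scaling)))
      msg <- c(msg, "scaling must contain 'means' and 'sds'")
    else if (any(object@scaling$sds <= 0))
      msg <- c(msg, "scaling sds must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' BindingDataset: labelled nanoparticle-analyte systems
#'
#' Rows of systems with experimental binding free energies and the cached
#' n x 5 feature matrix, all computed with one recorded fingerprint dialect.
#' The `molecules` slot retains the input SMILES/charges when the dataset
#' was read from a file; synthetic datasets carry features only.
#'
#' @slot systemId character vector, unique
#' @slot features numeric matrix, n x 5, columns named by the descriptors
#' @slot dgExp numeric, experimental binding free energy, kcal/mol
#' @slot molecules data.frame of per-system molecule inputs (may be 0-row)
#' @slot clusterLabel character vector of length n or 0 (optional grouping)
#' @slot provenance free-text description
#' @exportClass BindingDataset
setClass("BindingDataset",
  representation(systemId = "character", features = "matrix",
                 dgExp = "numeric", molecules = "data.frame",
                 clusterLabel = "character", provenance = "character"))

setValidity("BindingDataset", function(object) {
  msg <- character()
  n <- length(object@systemId)
  if (n < 2L) msg <- c(msg, "a dataset needs at least 2 systems")
  if (anyDuplicated(object@systemId))
    msg <- c(msg, "duplicate system_id values")
  if (!identical(colnames(object@features), .FEATURE_NAMES))
    msg <- c(msg, "feature columns must be the 5 canonical descriptors")
  if (nrow(object@features) != n || length(object@dgExp) != n)
    msg <- c(msg, "systemId, features and dgExp lengths disagree")
  if (!all(is.finite(object@dgExp)))
    msg <- c(msg, "dg_exp must be finite")
  if (length(object@clusterLabel) && length(object@clusterLabel) != n)
    msg <- c(msg, "clusterLabel must be empty or length n")
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: pairwise Tanimoto similarities within one role group
#'
#' @slot ids molecule identifiers (row/column order)
#' @slot similarity symmetric matrix of Tanimoto coefficients in \[0,1\]
#' @slot role `"ligand"` or `"analyte"`
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
  representation(ids = "character", similarity = "matrix", role = "character"))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  S <- object@similarity
  if (nrow(S) != length(object@ids) || ncol(S) != length(object@ids))
    msg <- c(msg, "matrix dimension must match ids")
  if (nrow(S) && any(abs(diag(S) - 1) > 1e-12))
    msg <- c(msg, "diagonal must be 1")
  if (nrow(S) && max(abs(S - t(S))) > 1e-12)
    msg <- c(msg, "matrix must be symmetric")
  if (nrow(S) && (min(S) < -1e-12 || max(S) > 1 + 1e-12))
    msg <- c(msg, "entries must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ClusterTree: agglomerative merge structure over molecules
#'
#' Wraps the standard merge/height encoding (as in [stats::hclust()]):
#' n-1 merges over n leaves, with 1 - Tanimoto merge heights.
#'
#' @slot merge integer matrix (n-1) x 2, hclust merge encoding
#' @slot height numeric merge heights
#' @slot labels leaf identifiers
#' @slot method linkage method name
#' @slot order leaf ordering for display
#' @exportClass ClusterTree
setClass("ClusterTree",
  representation(merge = "matrix", height = "numeric", labels = "character",
                 method = "character", order = "integer"))

setValidity("ClusterTree", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L)
    msg <- c(msg, "a tree over n leaves must have n-1 merges")
  if (length(object@height) != n - 1L)
    msg <- c(msg, "height length must be n-1")
  if (length(msg)) msg else TRUE
})

#' CVResult: nested repeated cross-validation output
#'
#' @slot predictions n x n_repeats matrix of out-of-fold predictions
#' @slot chosenAlpha n_folds x n_repeats matrix of selected alphas
#' @slot perRepeatMetrics data.frame with MSE, MAE, RMSE, R2 per repeat
#' @slot summary list of aggregate metrics with percentile confidence intervals
#' @slot meanPrediction mean predicted dG per system across repeats
#' @slot config the CV configuration used
#' @exportClass CVResult
setClass("CVResult",
  representation(predictions = "matrix", chosenAlpha = "matrix",
                 perRepeatMetrics = "data.frame", summary = "list",
                 meanPrediction = "numeric", config = "list"))
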