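# The scoring function proper: 5-descriptor feature vectors, the frozen
# published linear model, and prediction.

# Training dG range of the published model, kcal/mol; predictions outside it
# are extrapolations and are flagged.
.DG_TRAIN_RANGE <- c(-8.71, -2.85)

#' Assemble a 5-descriptor feature vector
#'
#' Builds the named numeric feature vector for one nanoparticle-analyte pair:
#' `charge_difference`, `ligand_logp`, `analyte_logp`, `ligand_tanimoto`,
#' `analyte_tanimoto`.
#'
#' @param chargeDifference non-negative charge difference
#' @param ligandLogP,analyteLogP Crippen logP values
#' @param ligandTanimoto,analyteTanimoto Tanimoto similarities in \[0,1\]
#' @return named numeric vector of length 5
#' @export
featureVector <- function(chargeDifference, ligandLogP, analyteLogP,
                          ligandTanimoto, analyteTanimoto) {
  v <- c(charge_difference = as.numeric(chargeDifference),
         ligand_logp = as.numeric(ligandLogP),
         analyte_logp = as.numeric(analyteLogP),
         ligand_tanimoto = as.numeric(ligandTanimoto),
         analyte_tanimoto = as.numeric(analyteTanimoto))
  .checkFeatures(v)
  v
}

.checkFeatures <- function(v) {
  if (!is.numeric(v) || length(v) != 5L || !identical(names(v), .FEATURE_NAMES))
    stop("a feature vector must be numeric with names exactly: ",
         paste(.FEATURE_NAMES, collapse = ", "), call. = FALSE)
  if (!all(is.finite(v)))
    stop("feature values must be finite", call. = FALSE)
  if (v[["charge_difference"]] < 0)
    stop("charge_difference must be non-negative", call. = FALSE)
  if (v[["ligand_tanimoto"]] < 0 || v[["ligand_tanimoto"]] > 1 ||
      v[["analyte_tanimoto"]] < 0 || v[["analyte_tanimoto"]] > 1)
    stop("Tanimoto features must lie in [0,1]", call. = FALSE)
  invisible(v)
}

#' Featurize a ligand-analyte pair
#'
#' Computes the five descriptors from two [MoleculeRecord-class] objects:
#' absolute charge difference, ligand and analyte Crippen logP, and Tanimoto
#' similarity of each molecule to its role's reference scaffold.
#'
#' @param ligand a `MoleculeRecord` with role `"ligand"`
#' @param analyte a `MoleculeRecord` with role `"analyte"`
#' @param refs a [ReferenceScaffolds-class] object
#' @return named numeric feature vector of length 5
#' @export
featurize <- function(ligand, analyte, refs = referenceScaffolds()) {
  stopifnot(is(ligand, "MoleculeRecord"), is(analyte, "MoleculeRecord"))
  if (ligand@role != "ligand")
    stop("first argument must have role 'ligand', got '", ligand@role, "'",
         call. = FALSE)
  if (analyte@role != "analyte")
    stop("second argument must have role 'analyte', got '", analyte@role, "'",
         call. = FALSE)
  refLig <- smilesFingerprint(refs@ligandReference)
  refAna <- smilesFingerprint(refs@analyteReference)
  featureVector(
    chargeDifference = chargeDifference(ligand@netCharge, analyte@netCharge),
    ligandLogP = ligand@logp,
    analyteLogP = analyte@logp,
    ligandTanimoto = tanimoto(ligand@fingerprint, refLig),
    analyteTanimoto = tanimoto(analyte@fingerprint, refAna))
}

#' Construct a ScoringModel
#'
#' @param intercept intercept, kcal/mol
#' @param coefficients named numeric of length 5 (unscaled, kcal/mol per
#'   feature unit); names must be the canonical descriptor names
#' @param scaledCoefficients optional named numeric of length 5
#'   (standardized-space coefficients, for importance ranking)
#' @param scaling optional list with `means` and `sds`
#' @param provenance free-text provenance
#' @return a [ScoringModel-class] object
#' @export
scoringModel <- function(intercept, coefficients, scaledCoefficients = numeric(0),
                         scaling = list(), provenance = "") {
  coefficients <- coefficients[.FEATURE_NAMES]
  names(coefficients) <- .FEATURE_NAMES
  if (length(scaledCoefficients)) {
    scaledCoefficients <- scaledCoefficients[.FEATURE_NAMES]
    names(scaledCoefficients) <- .FEATURE_NAMES
  }
  new("ScoringModel", intercept = as.numeric(intercept),
      coefficients = coefficients, scaledCoefficients = scaledCoefficients,
      scaling = scaling, provenance = provenance)
}

#' The frozen published scoring function
#'
#' The final ridge-regression scoring function for AuNP-analyte binding,
#' stored as a versioned constant (not re-fit at load time):
#'
#' dG = 0.5450 - 2.5822*ChargeDifference - 0.4023*logP_ligand
#'      - 0.4902*logP_analyte - 4.7748*Tanimoto_ligand
#'      + 0.6395*Tanimoto_analyte  (kcal/mol)
#'
#' Scaled (standardized-space) coefficients, used for feature-importance
#' ranking, are carried alongside.
#'
#' @return a [ScoringModel-class] object
#' @examples
#' m <- publishedModel()
#' scoreFeatures(featureVector(0, 0, 0, 0, 0), m)  # the intercept, 0.5450
#' @export
publishedModel <- function() {
  scoringModel(
    intercept = 0.5450,
    coefficients = c(charge_difference = -2.5822,
                     ligand_logp = -0.4023,
                     analyte_logp = -0.4902,
                     ligand_tanimoto = -4.7748,
                     analyte_tanimoto = 0.6395),
    scaledCoefficients = c(charge_difference = -0.753,
                           ligand_logp = -0.581,
                           analyte_logp = -0.471,
                           ligand_tanimoto = -0.410,
                           analyte_tanimoto = 0.044),
    provenance = paste0(
      "published AuNP-analyte scoring function v1; trained on 32 literature ",
      "systems (dG -2.85..-8.71 kcal/mol); fingerprint dialect: ",
      .FP_DIALECT, "; references: phenol (analyte), heneicosanethiolate ",
      "(ligand)"))
}

#' Predict binding free energy from a feature vector
#'
#' Evaluates the linear model: intercept + sum(coefficient_i * feature_i).
#'
#' @param features named numeric feature vector (see [featureVector()])
#' @param model a [ScoringModel-class] object
#' @return predicted dG, kcal/mol
#' @export
scoreFeatures <- function(features, model = publishedModel()) {
  .checkFeatures(features)
  stopifnot(is(model, "ScoringModel"))
  unname(model@intercept + sum(model@coefficients * features[.FEATURE_NAMES]))
}

#' @describeIn scoreFeatures `predict` method: evaluates the model on a
#'   feature vector or an n x 5 feature matrix
#' @param object a `ScoringModel`
#' @param newdata feature vector or matrix with the canonical columns
#' @param ... ignored
#' @export
setMethod("predict", "ScoringModel", function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    stopifnot(identical(colnames(newdata), .FEATURE_NAMES))
    unname(drop(object@intercept + newdata %*% object@coefficients))
  } else {
    scoreFeatures(newdata, object)
  }
})

#' Score one ligand-analyte pair from SMILES
#'
#' One-call convenience composing [moleculeRecord()], [featurize()] and
#' [scoreFeatures()]. Predictions outside the training range of the
#' published model (-8.71 to -2.85 kcal/mol) are returned unchanged but
#' flagged with a logged extrapolation note; the scoring function was
#' trained only on measurable binders and is not designed to rank
#' non-binders.
#'
#' @param ligandSmiles,analyteSmiles SMILES strings
#' @param ligandCharge,analyteCharge integer net charges at pH 7.4
#' @param model a [ScoringModel-class] object
#' @param refs a [ReferenceScaffolds-class] object
#' @return list with `dg` (kcal/mol), `features` (named numeric),
#'   `extrapolated` (logical)
#' @export
scorePair <- function(ligandSmiles, ligandCharge, analyteSmiles, analyteCharge,
                      model = publishedModel(), refs = referenceScaffolds()) {
  lig <- moleculeRecord("ligand", ligandSmiles, "ligand", ligandCharge)
  ana <- moleculeRecord("analyte", analyteSmiles, "analyte", analyteCharge)
  f <- featurize(lig, ana, refs)
  dg <- scoreFeatures(f, model)
  extrap <- dg < .DG_TRAIN_RANGE[1] || dg > .DG_TRAIN_RANGE[2]
  if (extrap)
    message(sprintf(
      "predicted dG %.4f kcal/mol lies outside the training range [%.2f, %.2f]: extrapolation",
      dg, .DG_TRAIN_RANGE[1], .DG_TRAIN_RANGE[2]))
  list(dg = dg, features = f, extrapolated = extrap)
}

#' @describeIn scoringModel display a scoring model
#' @param object a `ScoringModel`
#' @export
setMethod("show", "ScoringModel", function(object) {
  cat("ScoringModel (dG, kcal/mol)\n")
  cat(sprintf("  intercept: %.4f\n", object@intercept))
  for (nm in .FEATURE_NAMES)
    cat(sprintf("  %-18s %+9.4f%s\n", nm, object@coefficients[[nm]],
                if (length(object@scaledCoefficients))
                  sprintf("  (scaled %+.3f)", object@scaledCoefficients[[nm]])
                else ""))
  if (nzchar(object@provenance))
    cat("  provenance:", strtrim(object@provenance, 70), "...\n")
})

#' @rdname ScoringModel-class
#' @param object a `ScoringModel`
#' @export
setGeneric("modelIntercept", function(object) standardGeneric("modelIntercept"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelIntercept", "ScoringModel", function(object) object@intercept)

#' @rdname ScoringModel-class
#' @export
setGeneric("modelCoefficients",
           function(object) standardGeneric("modelCoefficients"))
#' @rdname ScoringModel-class
#' @export
setMethod("modelCoefficients", "ScoringModel",
          function(object) object@coefficients)

#' @rdname ScoringModel-class
#' @export
setGeneric("scaledCoefficients",
           function(object) standardGeneric("scaledCoefficients"))
#' @rdname ScoringModel-class
#' @export
setMethod("scaledCoefficients", "ScoringModel",
          function(object) object@scaledCoefficients)
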