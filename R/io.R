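# Readers and writers: dataset CSV, .smi files, model JSON.
# CSV dialect: comma-separated, UTF-8, header required, "." decimal
# separator. Typographic minus signs (en dash, true minus), which appear
# when dG values are pasted from typeset tables, are normalized on read.

.DATASET_COLS <- c("system_id", "ligand_id", "ligand_smiles", "ligand_charge",
                   "analyte_id", "analyte_smiles", "analyte_charge",
                   "dg_exp_kcal_mol")

.normalizeMinus <- function(x) gsub("[–−]", "-", x)

#' Read a binding dataset from CSV
#'
#' Expects columns `system_id, ligand_id, ligand_smiles, ligand_charge,
#' analyte_id, analyte_smiles, analyte_charge, dg_exp_kcal_mol` and an
#' optional `cluster_label`. Every row is validated (SMILES parse, integer
#' charges, finite dG) with the offending row reported on failure; the
#' 5-descriptor feature matrix is computed and cached on the returned
#' object.
#'
#' @param path CSV file path
#' @param refs a [ReferenceScaffolds-class] for the similarity descriptors
#' @return a [BindingDataset-class] object
#' @export
readDataset <- function(path, refs = referenceScaffolds()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty dataset file: ", path, call. = FALSE)
  missing <- setdiff(.DATASET_COLS, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  df$dg_exp_kcal_mol <- as.numeric(.normalizeMinus(as.character(df$dg_exp_kcal_mol)))
  if (anyDuplicated(df$system_id))
    stop("duplicate system_id: ",
         paste(unique(df$system_id[duplicated(df$system_id)]), collapse = ", "),
         call. = FALSE)
  for (col in c("ligand_charge", "analyte_charge")) {
    v <- suppressWarnings(as.numeric(.normalizeMinus(as.character(df[[col]]))))
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad))
      stop(sprintf("row %d: %s is not an integer", bad[1], col), call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  bad <- which(!is.finite(df$dg_exp_kcal_mol))
  if (length(bad))
    stop(sprintf("row %d: dg_exp_kcal_mol is not a finite number", bad[1]),
         call. = FALSE)
  feats <- matrix(NA_real_, nrow(df), 5,
                  dimnames = list(df$system_id, .FEATURE_NAMES))
  for (i in seq_len(nrow(df))) {
    lig <- tryCatch(
      moleculeRecord(df$ligand_id[i], df$ligand_smiles[i], "ligand",
                     df$ligand_charge[i]),
      error = function(e) stop(sprintf("row %d (ligand): %s", i,
                                       conditionMessage(e)), call. = FALSE))
    ana <- tryCatch(
      moleculeRecord(df$analyte_id[i], df$analyte_smiles[i], "analyte",
                     df$analyte_charge[i]),
      error = function(e) stop(sprintf("row %d (analyte): %s", i,
                                       conditionMessage(e)), call. = FALSE))
    feats[i, ] <- featurize(lig, ana, refs)
  }
  new("BindingDataset", systemId = as.character(df$system_id),
      features = feats, dgExp = df$dg_exp_kcal_mol,
      molecules = df[, intersect(.DATASET_COLS, names(df))],
      clusterLabel = if ("cluster_label" %in% names(df))
        as.character(df$cluster_label) else character(0),
      provenance = sprintf("read from %s; fingerprint dialect: %s",
                           basename(path), .FP_DIALECT))
}

#' Write / read a dataset CSV
#'
#' Writes the molecule columns (and dG) of a dataset back to the standard
#' CSV schema. Feature-only (synthetic) datasets are written with their
#' feature matrix and dG instead.
#'
#' @param dataset a [BindingDataset-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeDataset <- function(dataset, path) {
  stopifnot(is(dataset, "BindingDataset"))
  if (nrow(dataset@molecules)) {
    df <- dataset@molecules
    df$dg_exp_kcal_mol <- dataset@dgExp
  } else {
    df <- data.frame(system_id = dataset@systemId,
                     as.data.frame(dataset@features),
                     dg_exp_kcal_mol = dataset@dgExp)
  }
  if (length(dataset@clusterLabel)) df$cluster_label <- dataset@clusterLabel
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a .smi file
#'
#' One `SMILES<whitespace>id` per line; lines with no id get `mol<n>`.
#'
#' @param path .smi file path
#' @param role `"ligand"` or `"analyte"` assigned to every molecule
#' @param charges optional integer vector of net charges (default all 0)
#' @return list of [MoleculeRecord-class] objects
#' @export
readSmi <- function(path, role, charges = NULL) {
  role <- match.arg(role, c("ligand", "analyte"))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty .smi file: ", path, call. = FALSE)
  parts <- strsplit(lines, "[ \t]+")
  if (is.null(charges)) charges <- rep(0L, length(lines))
  stopifnot(length(charges) == length(lines))
  lapply(seq_along(parts), function(i) {
    id <- if (length(parts[[i]]) >= 2L) parts[[i]][2] else sprintf("mol%d", i)
    moleculeRecord(id, parts[[i]][1], role, charges[i])
  })
}

# Canonical serialization string of a model, used for checksumming.
.modelCanonicalString <- function(model) {
  paste(c(sprintf("%.10g", model@intercept),
          sprintf("%s=%.10g", .FEATURE_NAMES,
                  model@coefficients[.FEATURE_NAMES])),
        collapse = ";")
}

.modelChecksum <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(.modelCanonicalString(model), f)
  unname(tools::md5sum(f))
}

#' Write a scoring model to JSON
#'
#' Lossless round-trip including scaled coefficients, scaling metadata,
#' provenance and an md5 checksum over the intercept and coefficients.
#'
#' @param model a [ScoringModel-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "ScoringModel"))
  obj <- list(intercept = model@intercept,
              coefficients = as.list(model@coefficients),
              provenance = model@provenance,
              checksum = .modelChecksum(model))
  if (length(model@scaledCoefficients))
    obj$scaled_coefficients <- as.list(model@scaledCoefficients)
  if (length(model@scaling))
    obj$scaling <- list(means = as.list(model@scaling$means),
                        sds = as.list(model@scaling$sds))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a scoring model from JSON
#'
#' Validates coefficient names and, when a checksum is present, verifies it
#' against the stored intercept/coefficients; a mismatch is a hard error
#' (guards the bundled published model against silent edits).
#'
#' @param path model JSON path
#' @return a [ScoringModel-class]
#' @export
readModel <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("cannot parse model file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (!all(c("intercept", "coefficients") %in% names(obj)))
    stop("model file missing intercept/coefficients", call. = FALSE)
  cf <- unlist(obj$coefficients)
  unknown <- setdiff(names(cf), .FEATURE_NAMES)
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!setequal(names(cf), .FEATURE_NAMES))
    stop("model file must define all five coefficients", call. = FALSE)
  model <- scoringModel(
    intercept = obj$intercept, coefficients = cf,
    scaledCoefficients = if (!is.null(obj$scaled_coefficients))
      unlist(obj$scaled_coefficients) else numeric(0),
    scaling = if (!is.null(obj$scaling))
      list(means = unlist(obj$scaling$means), sds = unlist(obj$scaling$sds))
    else list(),
    provenance = if (!is.null(obj$provenance)) obj$provenance else "")
  if (!is.null(obj$checksum) &&
      !identical(unname(obj$checksum), unname(.modelChecksum(model))))
    stop("model checksum mismatch in ", path,
         ": file was edited or corrupted", call. = FALSE)
  model
}

#' @describeIn readDataset display a binding dataset
#' @param object a `BindingDataset`
#' @export
setMethod("show", "BindingDataset", function(object) {
  cat(sprintf("BindingDataset: %d systems, dG %.2f..%.2f kcal/mol\n",
              length(object@systemId), min(object@dgExp), max(object@dgExp)))
  if (nzchar(object@provenance)) cat(" ", object@provenance, "\n")
})

#' @rdname BindingDataset-class
#' @param object a `BindingDataset`
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname BindingDataset-class
#' @export
setMethod("featureMatrix", "BindingDataset", function(object) object@features)

#' @rdname BindingDataset-class
#' @export
setGeneric("dgExperimental", function(object) standardGeneric("dgExperimental"))
#' @rdname BindingDataset-class
#' @export
setMethod("dgExperimental", "BindingDataset", function(object) object@dgExp)

#' @rdname BindingDataset-class
#' @export
setGeneric("systemIds", function(object) standardGeneric("systemIds"))
#' @rdname BindingDataset-class
#' @export
setMethod("systemIds", "BindingDataset", function(object) object@systemId)
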