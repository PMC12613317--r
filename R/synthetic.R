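# Synthetic data: feature-level binding datasets with the statistical
# structure the scoring function assumes, and template-grammar molecules for
# clustering tests. The 32 literature systems behind the published model are
# not redistributable, so these generators emulate the printed summary
# characteristics (dataset size, dG range, descriptor ranges) -- an
# emulation, not a reconstruction.

#' Generate a synthetic binding dataset
#'
#' Draws feature vectors from the descriptor ranges the real data span --
#' charge difference uniform on \{0,1,2,3\} (integer formal charges at pH
#' 7.4), logP uniform on \[-2.1, 2.6\], Tanimoto uniform on \[0,1\] -- and
#' sets dG = generating model prediction + Gaussian noise. Returns both the
#' dataset and the generating truth so parameter-recovery tests can compare
#' against it. Fully reproducible from the seed.
#'
#' @param nSystems number of systems (default 32, the size of the
#'   literature dataset)
#' @param model generating [ScoringModel-class] (default: published model)
#' @param noiseSd Gaussian noise sd in kcal/mol (default 0.45, matching the
#'   published model's dataset-level MAE)
#' @param seed RNG seed
#' @return list with `dataset` (a [BindingDataset-class]) and `truth`
#'   (list: `intercept`, `coefficients`, `noiseSd`, `seed`)
#' @examples
#' d <- generateBindingData(nSystems = 32, seed = 7)
#' d$dataset
#' @export
generateBindingData <- function(nSystems = 32L, model = publishedModel(),
                                noiseSd = 0.45, seed = 1L) {
  stopifnot(nSystems >= 2L, noiseSd >= 0, is(model, "ScoringModel"))
  set.seed(seed)
  X <- cbind(
    charge_difference = as.numeric(sample(0:3, nSystems, replace = TRUE)),
    ligand_logp = stats::runif(nSystems, -2.1, 2.6),
    analyte_logp = stats::runif(nSystems, -2.1, 2.6),
    ligand_tanimoto = stats::runif(nSystems, 0, 1),
    analyte_tanimoto = stats::runif(nSystems, 0, 1))
  dg <- drop(model@intercept + X %*% model@coefficients) +
    stats::rnorm(nSystems, 0, noiseSd)
  ds <- new("BindingDataset",
            systemId = sprintf("synth%03d", seq_len(nSystems)),
            features = X, dgExp = dg,
            molecules = data.frame(), clusterLabel = character(0),
            provenance = sprintf(
              "synthetic dataset: n=%d, noise sd=%g kcal/mol, seed=%d, generating model: %s",
              nSystems, noiseSd, seed, strtrim(model@provenance, 60)))
  list(dataset = ds,
       truth = list(intercept = model@intercept,
                    coefficients = model@coefficients,
                    noiseSd = noiseSd, seed = seed))
}

.ANALYTE_SUBS <- c("O", "N", "OC", "C", "CC", "F", "Cl", "C(=O)O", "CO",
                   "[N+](C)(C)C", "C=O", "OCC", "C(=O)C", "[N+](=O)[O-]")
.LIGAND_TAILS <- c("C(=O)O", "OC", "N", "C(=O)NC", "O", "OCCOC", "S(=O)(=O)O",
                   "[N+](C)(C)C")

#' Generate random template molecules
#'
#' Produces parseable SMILES from a small template grammar: substituted
#' benzenes for analytes (every analyte is guaranteed a benzene ring, like
#' the aromatic analytes of the real dataset) and alkyl thiolates with
#' varied chain lengths and terminal headgroups for ligands. Deterministic
#' from the seed. Intended for exercising the clustering machinery, not as
#' chemically curated structures.
#'
#' @param n number of molecules
#' @param role `"ligand"` or `"analyte"`
#' @param seed RNG seed
#' @return list of [MoleculeRecord-class] objects
#' @export
generateMolecules <- function(n, role = c("analyte", "ligand"), seed = 1L) {
  role <- match.arg(role)
  stopifnot(n >= 1L)
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (role == "analyte") {
      k <- sample(1:2, 1)
      subs <- sample(.ANALYTE_SUBS, k)
      # branch attachment (first atom of the substituent bonds the ring)
      smi <- if (k == 1L) sprintf("c1ccc(%s)cc1", subs[1])
             else sprintf("c1cc(%s)cc(%s)c1", subs[1], subs[2])
    } else {
      chain <- paste(rep("C", sample(4:16, 1)), collapse = "")
      tail <- sample(.LIGAND_TAILS, 1)
      smi <- sprintf("[S-]%s%s", chain, tail)
    }
    out[[i]] <- moleculeRecord(sprintf("%s%03d", substr(role, 1, 1), i),
                               smi, role, 0L)
  }
  out
}
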