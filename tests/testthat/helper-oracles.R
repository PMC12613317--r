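# Independent oracles used to cross-check the implementation.

# Set-arithmetic Tanimoto: recompute a, b, c from explicit bit-index sets,
# independent of the vectorized implementation.
oracleTanimoto <- function(fpA, fpB) {
  A <- which(fpA != 0)
  B <- which(fpB != 0)
  a <- length(A)
  b <- length(B)
  c <- length(intersect(A, B))
  c / (a + b - c)
}

# Iterative ridge solver: minimizes ||y - b0 - X b||^2 + alpha ||b||^2
# (intercept unpenalized) by conjugate gradients on its stationarity
# system, implemented from scratch -- no matrix inversion, independent of
# the closed-form path under test. Exact for quadratics at convergence.
oracleRidge <- function(X, y, alpha, maxIter = 10000L, tol = 1e-14) {
  Z <- cbind(1, X)
  d <- c(0, rep(1, ncol(X)))          # penalty mask: intercept unpenalized
  applyA <- function(v) drop(crossprod(Z, Z %*% v)) + alpha * d * v
  b <- drop(crossprod(Z, y))
  theta <- numeric(ncol(Z))
  r <- b - applyA(theta)
  p <- r
  rs <- sum(r * r)
  for (i in seq_len(maxIter)) {
    Ap <- applyA(p)
    ak <- rs / sum(p * Ap)
    theta <- theta + ak * p
    r <- r - ak * Ap
    rsNew <- sum(r * r)
    if (sqrt(rsNew) < tol * max(1, sqrt(sum(b * b)))) break
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  theta <- unname(theta)
  list(intercept = theta[1], coefficients = theta[-1])
}

# Per-feature OLS oracle for variance inflation factors: VIF_j = 1/(1-R2_j)
# from regressing column j on the others with lm().
oracleVif <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# Random 0/1 fingerprint with a controlled popcount.
randomFingerprint <- function(nBits = 64L, nSet = NULL) {
  if (is.null(nSet)) nSet <- sample(1:nBits, 1)
  fp <- integer(nBits)
  fp[sample.int(nBits, nSet)] <- 1L
  fp
}

# Random symmetric similarity matrix with unit diagonal.
randomSimilarityMatrix <- function(n, ids = sprintf("m%02d", seq_len(n))) {
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  new("SimilarityMatrix", ids = ids, similarity = S, role = "analyte")
}

# A small in-memory dataset CSV written to a temp file.
writeTestDatasetCsv <- function(path,
                                ids = c("s1", "s2", "s3"),
                                dg = c("-5.10", "-4.20", "-6.30")) {
  writeLines(c(
    "system_id,ligand_id,ligand_smiles,ligand_charge,analyte_id,analyte_smiles,analyte_charge,dg_exp_kcal_mol",
    sprintf("%s,L1,CCCCCCCCCCCS,0,A%d,Oc1ccccc1,0,%s", ids, seq_along(ids), dg)),
    path)
  path
}
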