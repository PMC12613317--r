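# Chemical clustering: pairwise Tanimoto similarity within a role group,
# agglomerative hierarchical clustering on 1 - Tanimoto, flat cluster
# extraction and Newick/merge-table export.

#' Pairwise Tanimoto similarity matrix
#'
#' Computes all pairwise Tanimoto similarities among molecules of one role
#' (ligands and analytes are clustered as separate groups).
#'
#' @param molecules list of [MoleculeRecord-class] objects, all same role
#' @return a [SimilarityMatrix-class] object
#' @export
pairwiseSimilarity <- function(molecules) {
  stopifnot(length(molecules) >= 2L,
            all(vapply(molecules, is, logical(1), "MoleculeRecord")))
  roles <- vapply(molecules, function(m) m@role, character(1))
  if (length(unique(roles)) != 1L)
    stop("all molecules must share one role; got: ",
         paste(unique(roles), collapse = ", "), call. = FALSE)
  ids <- vapply(molecules, function(m) m@id, character(1))
  fps <- do.call(rbind, lapply(molecules, function(m) m@fingerprint))
  # vectorized: c = FF', a+b from row popcounts
  pc <- rowSums(fps)
  C <- tcrossprod(fps)
  S <- C / (outer(pc, pc, "+") - C)
  dimnames(S) <- list(ids, ids)
  new("SimilarityMatrix", ids = ids, similarity = S, role = roles[1])
}

#' Similarity of each molecule to the role's reference scaffold
#'
#' The one-dimensional alternative to the full pairwise matrix: Tanimoto
#' similarity of every molecule to its reference scaffold.
#'
#' @param molecules list of [MoleculeRecord-class] objects, all same role
#' @param refs a [ReferenceScaffolds-class] object
#' @return named numeric vector
#' @export
referenceSimilarities <- function(molecules, refs = referenceScaffolds()) {
  vapply(molecules, function(m)
    similarityToReference(m@smiles, m@role, refs), numeric(1)) |>
    stats::setNames(vapply(molecules, function(m) m@id, character(1)))
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering on the dissimilarity 1 - Tanimoto. Average
#' linkage (UPGMA) is the default -- the standard choice for fingerprint
#' dissimilarities; single, complete and Ward linkage are available.
#' Deterministic for a fixed input order.
#'
#' @param simMatrix a [SimilarityMatrix-class] object
#' @param linkage `"average"`, `"single"`, `"complete"` or `"ward"`
#' @return a [ClusterTree-class] object
#' @export
hierarchicalCluster <- function(simMatrix, linkage = "average") {
  stopifnot(is(simMatrix, "SimilarityMatrix"))
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward"))
  n <- length(simMatrix@ids)
  if (n < 2L) stop("need at least 2 molecules to cluster", call. = FALSE)
  d <- stats::as.dist(1 - simMatrix@similarity)
  hc <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else linkage)
  new("ClusterTree", merge = hc$merge, height = hc$height,
      labels = simMatrix@ids, method = linkage, order = as.integer(hc$order))
}

# Back-convert to the stats::hclust representation.
.asHclust <- function(tree) {
  structure(list(merge = tree@merge, height = tree@height,
                 order = tree@order, labels = tree@labels,
                 method = tree@method, call = NULL,
                 dist.method = "1 - Tanimoto"),
            class = "hclust")
}

#' Cut a cluster tree into k flat clusters
#'
#' Cuts after the (n-k)-th merge. Clusters are nested: the k-cluster
#' solution is a coarsening of the (k+1)-cluster solution. Labels are
#' stable across runs for fixed input.
#'
#' @param tree a [ClusterTree-class] object
#' @param k number of clusters, 1 <= k <= n
#' @return named integer vector of cluster labels
#' @export
cutClusters <- function(tree, k) {
  stopifnot(is(tree, "ClusterTree"))
  n <- length(tree@labels)
  if (k < 1L || k > n)
    stop("k must lie in 1..", n, call. = FALSE)
  stats::cutree(.asHclust(tree), k = k)
}

# Recursive Newick builder: child branch length = parent height - child
# height (leaves sit at height 0), so the tree is ultrametric in the merge
# heights.
.newickNode <- function(tree, node, parentHeight) {
  if (node < 0) {  # leaf (hclust encodes leaves as negative indices)
    lab <- gsub("[,;:()\\s]", "_", tree@labels[-node], perl = TRUE)
    sprintf("%s:%g", lab, parentHeight)
  } else {
    h <- tree@height[node]
    sprintf("(%s,%s):%g",
            .newickNode(tree, tree@merge[node, 1], h),
            .newickNode(tree, tree@merge[node, 2], h),
            parentHeight - h)
  }
}

#' Export a cluster tree as text
#'
#' Newick export writes merge heights as ultrametric branch lengths;
#' merge-table export writes a TSV of the raw merge structure.
#'
#' @param tree a [ClusterTree-class] object
#' @param format `"newick"` or `"merge_table"`
#' @return a single string (Newick) or TSV text
#' @export
exportTree <- function(tree, format = c("newick", "merge_table")) {
  stopifnot(is(tree, "ClusterTree"))
  format <- match.arg(format)
  if (format == "newick") {
    root <- nrow(tree@merge)
    h <- tree@height[root]
    paste0(sprintf("(%s,%s);",
                   .newickNode(tree, tree@merge[root, 1], h),
                   .newickNode(tree, tree@merge[root, 2], h)))
  } else {
    hdr <- "merge\tleft\tright\theight"
    rows <- sprintf("%d\t%d\t%d\t%g", seq_along(tree@height),
                    tree@merge[, 1], tree@merge[, 2], tree@height)
    paste(c(hdr, rows), collapse = "\n")
  }
}

#' @describeIn hierarchicalCluster display a cluster tree
#' @param object a `ClusterTree`
#' @export
setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d leaves, %s linkage, merge heights %.3f..%.3f\n",
              length(object@labels), object@method, min(object@height),
              max(object@height)))
})

#' @describeIn pairwiseSimilarity display a similarity matrix
#' @param object a `SimilarityMatrix`
#' @export
setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d %ss, Tanimoto range %.3f..%.3f (off-diagonal)\n",
              length(object@ids), object@role,
              min(object@similarity[upper.tri(object@similarity)]),
              max(object@similarity[upper.tri(object@similarity)])))
})

#' @rdname SimilarityMatrix-class
#' @param object a `SimilarityMatrix`
#' @export
setGeneric("similarityValues",
           function(object) standardGeneric("similarityValues"))
#' @rdname SimilarityMatrix-class
#' @export
setMethod("similarityValues", "SimilarityMatrix",
          function(object) object@similarity)
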