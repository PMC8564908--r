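#' Ward bi-clustering of an expression matrix
#'
#' Agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion on Euclidean distances, applied independently to samples and
#' to features of a median-centered log2 matrix, each dendrogram cut into
#' exactly two groups. This is the unsupervised step that partitions a PDX
#' cohort into two candidate response clusters defined by two blocks of
#' differential features. Linkage uses the squared-distance Lance-Williams
#' update (`hclust` method `"ward.D2"`, matching the classical Ward
#' algorithm on Euclidean input); the merge histories of both dendrograms
#' are kept in the returned object.
#'
#' Cluster labels are deterministic: cluster `"A"` is the sample cluster
#' containing the first sample in matrix order (likewise `"group1"` for
#' features), so permuting input order changes no memberships, only which
#' partition happens to be called `A`.
#'
#' @param x a [ProfileMatrix-class] or numeric matrix (features x samples)
#'   with at least 2 samples and 2 features.
#' @return A [ClusterAssignment-class] with phenotype unset.
#' @seealso [labelClusters()]
#' @examples
#' cohort <- generateCohort(cohortSpec(nSamples = 16, nFeatures = 30,
#'                                     seed = 2))
#' wardBicluster(cohort$protein)
#' @export
wardBicluster <- function(x) {
  m <- if (is(x, "ProfileMatrix")) SummarizedExperiment::assay(x, "exprs")
       else x
  if (!is.matrix(m) || nrow(m) < 2 || ncol(m) < 2)
    inputError("bi-clustering needs at least 2 samples and 2 features")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    inputError("matrix must carry feature and sample names")

  cut2 <- function(vectors, ids) {
    hc <- hclust(dist(vectors), method = "ward.D2")
    k2 <- cutree(hc, k = 2)
    ## canonical labels: the group containing the first id is the first level
    first <- k2[[1]]
    link <- data.frame(merge1 = hc$merge[, 1], merge2 = hc$merge[, 2],
                       height = hc$height)
    list(groups = ifelse(k2 == first, 1L, 2L), linkage = link)
  }
  samples <- cut2(t(m), colnames(m))
  features <- cut2(m, rownames(m))

  new("ClusterAssignment",
      sampleCluster = factor(setNames(c("A", "B")[samples$groups],
                                      colnames(m)), levels = c("A", "B")),
      featureGroup = factor(setNames(c("group1", "group2")[features$groups],
                                     rownames(m)),
                            levels = c("group1", "group2")),
      phenotype = character(),
      sampleLinkage = samples$linkage,
      featureLinkage = features$linkage)
}

#' Label clusters as predicted sensitive or resistant
#'
#' Assigns the response phenotype to the two sample clusters: the cluster
#' with the higher mean expression over a supplied set of
#' sensitivity-associated features (e.g. probes of RTK-driven MAPK/PI3K
#' signaling, whose high expression marks candidate responders) is labeled
#' `predicted_sensitive`, the other `predicted_resistant`. An exact tie is
#' broken deterministically — the cluster containing the lexicographically
#' smallest sample ID becomes `predicted_sensitive` — with a warning.
#'
#' @param assignment a [ClusterAssignment-class] from [wardBicluster()].
#' @param x the clustered [ProfileMatrix-class] (or matrix).
#' @param sensitivityFeatures nonempty character vector of features whose
#'   high expression indicates sensitivity; for synthetic cohorts the
#'   planted group-1 block (`metadata(x)$signature$group1`).
#' @return the `ClusterAssignment` with phenotype set.
#' @export
labelClusters <- function(assignment, x, sensitivityFeatures) {
  if (!is(assignment, "ClusterAssignment"))
    inputError("'assignment' must be a ClusterAssignment")
  m <- if (is(x, "ProfileMatrix")) SummarizedExperiment::assay(x, "exprs")
       else x
  if (length(sensitivityFeatures) == 0)
    inputError("'sensitivityFeatures' must be nonempty")
  if (!all(sensitivityFeatures %in% rownames(m)))
    inputError("some 'sensitivityFeatures' are absent from the matrix")
  cl <- assignment@sampleCluster[colnames(m)]
  if (anyNA(cl))
    inputError("matrix samples do not match the cluster assignment")
  means <- vapply(c(A = "A", B = "B"), function(g)
    mean(m[sensitivityFeatures, names(cl)[cl == g], drop = FALSE]),
    numeric(1))
  if (means[["A"]] == means[["B"]]) {
    warning("exact tie of sensitivity-feature means; ",
            "breaking toward the cluster with the smallest sample ID")
    first <- as.character(cl[order(names(cl))][1])
    sens <- first
  } else {
    sens <- names(which.max(means))
  }
  pheno <- setNames(ifelse(c("A", "B") == sens, "predicted_sensitive",
                           "predicted_resistant"), c("A", "B"))
  assignment@phenotype <- pheno
  validObject(assignment)
  assignment
}

#' Diagnostic bi-cluster heatmap
#'
#' Thin wrapper over `pheatmap` showing the matrix ordered by the two-way
#' partition, with cluster annotations.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param x the clustered [ProfileMatrix-class].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotBicluster <- function(assignment, x, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    inputError("plotBicluster requires the 'pheatmap' package")
  m <- SummarizedExperiment::assay(x, "exprs")
  ann_col <- data.frame(cluster = assignment@sampleCluster[colnames(m)],
                        row.names = colnames(m))
  ann_row <- data.frame(group = assignment@featureGroup[rownames(m)],
                        row.names = rownames(m))
  ph <- pheatmap::pheatmap(m, clustering_method = "ward.D2",
                           annotation_col = ann_col,
                           annotation_row = ann_row,
                           show_colnames = ncol(m) <= 40,
                           show_rownames = nrow(m) <= 40, ...)
  invisible(ph)
}
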