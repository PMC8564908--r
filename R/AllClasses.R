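#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

#' ProfileMatrix: a median-centered log2 expression matrix
#'
#' `ProfileMatrix` extends [SummarizedExperiment::SummarizedExperiment] with a
#' `modality` tag (`"protein"` for RPPA probe intensities, `"mrna"` for
#' RNA-seq gene expression). Features are rows and samples are columns, the
#' Bioconductor convention; the on-disk TSV layout written by
#' [writeProfile()] is transposed (samples as rows). Values are unitless
#' median-centered log2 intensities: every feature has median 0 across
#' samples. The feature-to-gene-symbol map (which may contain `NA` for
#' probes with no mRNA counterpart, e.g. phospho-probes or non-protein
#' epitopes) lives in `rowData(x)$gene_symbol`.
#'
#' @slot modality character, `"protein"` or `"mrna"`.
#' @export
setClass("ProfileMatrix",
         contains = "SummarizedExperiment",
         slots = c(modality = "character"))

validProfileMatrix <- function(object) {
  msg <- character()
  if (length(object@modality) != 1L ||
      !object@modality %in% c("protein", "mrna"))
    msg <- c(msg, "modality must be 'protein' or 'mrna'")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(m))
      msg <- c(msg, "expression values must not contain NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature IDs")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample IDs")
  if (length(msg)) msg else TRUE
}
setValidity("ProfileMatrix", validProfileMatrix)

#' Construct a ProfileMatrix
#'
#' @param values numeric matrix of median-centered log2 values, features as
#'   rows and samples as columns (both dimnames required).
#' @param modality `"protein"` or `"mrna"`.
#' @param geneMap named character vector mapping feature IDs to gene symbols;
#'   features absent from the map (or mapped to `NA`) have no mRNA
#'   counterpart. Defaults to the identity map, the natural choice for mRNA
#'   matrices indexed by gene symbol.
#' @param metadata list of free-form provenance (e.g. the generating spec).
#' @return A [ProfileMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' m <- m - apply(m, 1, median)
#' ProfileMatrix(m, "protein")
#' @export
ProfileMatrix <- function(values, modality = c("protein", "mrna"),
                          geneMap = NULL, metadata = list()) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    inputError("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    inputError("'values' must have feature rownames and sample colnames")
  if (is.null(geneMap))
    geneMap <- setNames(rownames(values), rownames(values))
  symbols <- unname(geneMap[rownames(values)])
  rd <- S4Vectors::DataFrame(gene_symbol = symbols,
                             row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(exprs = values),
    rowData = rd, metadata = metadata)
  new("ProfileMatrix", se, modality = modality)
}

#' @rdname ProfileMatrix
#' @param x,object a `ProfileMatrix`.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname ProfileMatrix
#' @export
setMethod("modality", "ProfileMatrix", function(x) x@modality)

#' @rdname ProfileMatrix
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname ProfileMatrix
#' @export
setMethod("geneMap", "ProfileMatrix", function(x)
  setNames(rowData(x)$gene_symbol, rownames(x)))

#' @rdname ProfileMatrix
#' @export
setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix (%s): %d features x %d samples\n",
              object@modality, nrow(object), ncol(object)))
  n_unmapped <- sum(is.na(rowData(object)$gene_symbol))
  if (n_unmapped > 0)
    cat(sprintf("  %d feature(s) without a gene symbol\n", n_unmapped))
  invisible(object)
})

#' ClusterAssignment: result of Ward bi-clustering
#'
#' Holds the two-way partition produced by [wardBicluster()]: samples into
#' clusters `A`/`B`, features into `group1`/`group2`, plus the full merge
#' history of both dendrograms for reproducibility. The `phenotype` slot maps
#' cluster to `predicted_sensitive`/`predicted_resistant`; it is empty until
#' [labelClusters()] is called.
#'
#' @slot sampleCluster named factor, sample ID to `"A"`/`"B"`.
#' @slot featureGroup named factor, feature ID to `"group1"`/`"group2"`.
#' @slot phenotype named character of length 0 or 2, cluster to phenotype.
#' @slot sampleLinkage,featureLinkage data.frame merge records
#'   (columns `merge1`, `merge2`, `height`; hclust encoding).
#' @export
setClass("ClusterAssignment",
         slots = c(sampleCluster = "factor",
                   featureGroup = "factor",
                   phenotype = "character",
                   sampleLinkage = "data.frame",
                   featureLinkage = "data.frame"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (nlevels(droplevels(object@sampleCluster)) != 2L)
    msg <- c(msg, "exactly 2 nonempty sample clusters required")
  if (nlevels(droplevels(object@featureGroup)) != 2L)
    msg <- c(msg, "exactly 2 nonempty feature groups required")
  if (length(object@phenotype) &&
      (length(object@phenotype) != 2L ||
       !setequal(names(object@phenotype), c("A", "B")) ||
       !setequal(unname(object@phenotype),
                 c("predicted_sensitive", "predicted_resistant"))))
    msg <- c(msg, paste("phenotype must be a bijection {A,B} ->",
                        "{predicted_sensitive, predicted_resistant}"))
  if (length(msg)) msg else TRUE
})

#' @rdname ClusterAssignment
#' @param x,object a `ClusterAssignment`.
#' @export
setGeneric("sampleClusters", function(x) standardGeneric("sampleClusters"))

#' @rdname ClusterAssignment
#' @export
setMethod("sampleClusters", "ClusterAssignment", function(x) x@sampleCluster)

#' @rdname ClusterAssignment
#' @export
setGeneric("featureGroups", function(x) standardGeneric("featureGroups"))

#' @rdname ClusterAssignment
#' @export
setMethod("featureGroups", "ClusterAssignment", function(x) x@featureGroup)

#' @rdname ClusterAssignment
#' @export
setGeneric("clusterPhenotype", function(x) standardGeneric("clusterPhenotype"))

#' @rdname ClusterAssignment
#' @export
setMethod("clusterPhenotype", "ClusterAssignment", function(x) x@phenotype)

#' Per-sample predicted phenotype
#'
#' @param x a labelled `ClusterAssignment`.
#' @return named character vector, sample ID to
#'   `"predicted_sensitive"`/`"predicted_resistant"`.
#' @export
setGeneric("predictedPhenotype", function(x)
  standardGeneric("predictedPhenotype"))

#' @rdname predictedPhenotype
#' @export
setMethod("predictedPhenotype", "ClusterAssignment", function(x) {
  if (!length(x@phenotype))
    inputError("phenotype not set; call labelClusters() first")
  setNames(unname(x@phenotype[as.character(x@sampleCluster)]),
           names(x@sampleCluster))
})

#' @rdname ClusterAssignment
#' @export
setMethod("show", "ClusterAssignment", function(object) {
  ns <- table(object@sampleCluster)
  nf <- table(object@featureGroup)
  cat(sprintf("ClusterAssignment: samples A=%d B=%d; features group1=%d group2=%d\n",
              ns[["A"]], ns[["B"]], nf[["group1"]], nf[["group2"]]))
  if (length(object@phenotype))
    cat(sprintf("  phenotype: A=%s, B=%s\n",
                object@phenotype[["A"]], object@phenotype[["B"]]))
  else cat("  phenotype: unset\n")
  invisible(object)
})

#' ContingencySummary: prediction-vs-observation counts and rates
#'
#' 2x2 evaluation of cluster-predicted drug response against observed in-vivo
#' calls, with the sensitive class as positive. Counts split each predicted
#' arm by correctness (`tp`/`fn` the predicted-sensitive arm, `tn`/`fp` the
#' predicted-resistant arm; see [evaluatePredictions()]). Rates are stored
#' as exact percentages; [reportRates()] applies half-up integer rounding
#' for report tables. Confidence intervals are exact Clopper-Pearson at the
#' stored `alpha`.
#'
#' @slot counts named numeric `tp`, `fp`, `tn`, `fn`.
#' @slot rates named numeric percentages `accuracy`, `tpr`, `tnr`, `fpr`,
#'   `fnr` (exact, unrounded).
#' @slot ci list of length-2 numeric `(lower, upper)` proportions for
#'   `accuracy`, `tpr`, `tnr`.
#' @slot alpha numeric, CI level (default 0.05 gives 95% intervals).
#' @export
setClass("ContingencySummary",
         slots = c(counts = "numeric", rates = "numeric",
                   ci = "list", alpha = "numeric"))

setValidity("ContingencySummary", function(object) {
  msg <- character()
  if (!setequal(names(object@counts), c("tp", "fp", "tn", "fn")))
    msg <- c(msg, "counts must be named tp, fp, tn, fn")
  r <- object@rates
  if (!all(c("accuracy", "tpr", "tnr", "fpr", "fnr") %in% names(r)))
    msg <- c(msg, "rates must include accuracy, tpr, tnr, fpr, fnr")
  else {
    if (!is.na(r[["tpr"]]) && abs(r[["tpr"]] + r[["fnr"]] - 100) > 1e-9)
      msg <- c(msg, "tpr + fnr must equal 100")
    if (!is.na(r[["tnr"]]) && abs(r[["tnr"]] + r[["fpr"]] - 100) > 1e-9)
      msg <- c(msg, "tnr + fpr must equal 100")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname ContingencySummary
#' @param x,object a `ContingencySummary`.
#' @export
setGeneric("reportRates", function(x) standardGeneric("reportRates"))

#' @rdname ContingencySummary
#' @export
setMethod("reportRates", "ContingencySummary", function(x)
  roundHalfUp(x@rates))

#' @rdname ContingencySummary
#' @export
setMethod("show", "ContingencySummary", function(object) {
  ct <- object@counts
  rr <- reportRates(object)
  cat("ContingencySummary (positive = sensitive)\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              ct[["tp"]], ct[["fp"]], ct[["tn"]], ct[["fn"]], sum(ct)))
  cat(sprintf("  accuracy %d%%  TPR %d%%  TNR %d%%  FPR %d%%  FNR %d%%\n",
              rr[["accuracy"]], rr[["tpr"]], rr[["tnr"]],
              rr[["fpr"]], rr[["fnr"]]))
  for (nm in names(object@ci)) {
    ci <- object@ci[[nm]]
    if (all(is.finite(ci)))
      cat(sprintf("  %s %d%% CI: %d%%-%d%%\n", nm,
                  round(100 * (1 - object@alpha)),
                  roundHalfUp(100 * ci[1]), roundHalfUp(100 * ci[2])))
  }
  invisible(object)
})

#' BiomarkerSet: features surviving a fold-change threshold
#'
#' The set of differential features at one |log2FC| threshold of the sweep:
#' all members satisfy `p_value < pCut` and `|log2fc| >= threshold`, so sets
#' are nested across increasing thresholds. Direction follows the resistant
#' minus sensitive sign convention: positive log2FC means up in resistant.
#'
#' @slot threshold numeric |log2FC| cutoff.
#' @slot features character vector of member feature IDs.
#' @slot direction named character, `"up_in_resistant"`/`"up_in_sensitive"`.
#' @slot stats data.frame of per-member differential statistics.
#' @slot pCut numeric p-value filter used.
#' @export
setClass("BiomarkerSet",
         slots = c(threshold = "numeric", features = "character",
                   direction = "character", stats = "data.frame",
                   pCut = "numeric"))

setValidity("BiomarkerSet", function(object) {
  msg <- character()
  if (!identical(sort(names(object@direction)), sort(object@features)))
    msg <- c(msg, "direction must be named by the member features")
  if (length(object@direction) &&
      !all(object@direction %in% c("up_in_resistant", "up_in_sensitive")))
    msg <- c(msg, "invalid direction labels")
  if (length(msg)) msg else TRUE
})

#' @rdname BiomarkerSet
#' @param x,object a `BiomarkerSet`.
#' @export
setGeneric("setFeatures", function(x) standardGeneric("setFeatures"))

#' @rdname BiomarkerSet
#' @export
setMethod("setFeatures", "BiomarkerSet", function(x) x@features)

#' @rdname BiomarkerSet
#' @export
setGeneric("setThreshold", function(x) standardGeneric("setThreshold"))

#' @rdname BiomarkerSet
#' @export
setMethod("setThreshold", "BiomarkerSet", function(x) x@threshold)

#' @rdname BiomarkerSet
#' @export
setGeneric("featureDirection", function(x) standardGeneric("featureDirection"))

#' @rdname BiomarkerSet
#' @export
setMethod("featureDirection", "BiomarkerSet", function(x) x@direction)

#' @rdname BiomarkerSet
#' @export
setMethod("show", "BiomarkerSet", function(object) {
  cat(sprintf("BiomarkerSet: |log2FC| >= %.2g, p < %.2g, %d feature(s)\n",
              object@threshold, object@pCut, length(object@features)))
  if (length(object@features)) {
    up_r <- sum(object@direction == "up_in_resistant")
    cat(sprintf("  %d up in resistant, %d up in sensitive\n",
                up_r, length(object@features) - up_r))
    cat("  ", paste(head(object@features, 10), collapse = ", "),
        if (length(object@features) > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(object)
})

#' ClassifierEval: PR/ROC evaluation of one biomarker set
#'
#' Decision-score evaluation of a protein-trained SVM on held-out validated
#' samples, for one threshold and one test modality. The positive class is
#' sensitive. ROC AUC uses trapezoidal integration (tied scores contribute by
#' the midpoint convention, so constant scores give 0.5); PR AUC uses
#' step-wise interpolation (average precision).
#'
#' @slot threshold numeric sweep threshold of the evaluated set.
#' @slot modality character, test-set modality.
#' @slot prAUC,rocAUC numeric areas in \[0, 1\].
#' @slot prCurve data.frame with columns `recall`, `precision`.
#' @slot rocCurve data.frame with columns `fpr`, `tpr`.
#' @slot scores named numeric decision scores (higher = more sensitive).
#' @slot labels named character observed responses of the test samples.
#' @slot nFeatures integer, features actually used (after mRNA mapping).
#' @export
setClass("ClassifierEval",
         slots = c(threshold = "numeric", modality = "character",
                   prAUC = "numeric", rocAUC = "numeric",
                   prCurve = "data.frame", rocCurve = "data.frame",
                   scores = "numeric", labels = "character",
                   nFeatures = "integer"))

#' @rdname ClassifierEval
#' @param x,object a `ClassifierEval`.
#' @export
setGeneric("prAUC", function(x) standardGeneric("prAUC"))

#' @rdname ClassifierEval
#' @export
setMethod("prAUC", "ClassifierEval", function(x) x@prAUC)

#' @rdname ClassifierEval
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))

#' @rdname ClassifierEval
#' @export
setMethod("rocAUC", "ClassifierEval", function(x) x@rocAUC)

#' @rdname ClassifierEval
#' @export
setMethod("show", "ClassifierEval", function(object) {
  cat(sprintf(
    "ClassifierEval: threshold %.2g, %s test set (%d samples, %d features)\n",
    object@threshold, object@modality, length(object@scores),
    object@nFeatures))
  cat(sprintf("  PR AUC = %.3f, ROC AUC = %.3f\n",
              object@prAUC, object@rocAUC))
  invisible(object)
})

#' ConcordanceResult: cross-cohort fold-change agreement
#'
#' Per-gene log2 fold changes (resistant minus sensitive) in two cohorts over
#' their shared genes, their Pearson correlation, and — after
#' [randomizationControl()] — a label-permutation null distribution of the
#' correlation.
#'
#' @slot internalFC,externalFC named numeric per-gene log2FC (shared genes).
#' @slot pearsonR,pValue numeric correlation and two-tailed p.
#' @slot nullR numeric vector of permutation correlations (possibly empty).
#' @slot nPermutations integer, seed integer.
#' @slot seed integer seed used for the permutation null.
#' @slot droppedGenes character, genes excluded for lack of overlap.
#' @export
setClass("ConcordanceResult",
         slots = c(internalFC = "numeric", externalFC = "numeric",
                   pearsonR = "numeric", pValue = "numeric",
                   nullR = "numeric", nPermutations = "integer",
                   seed = "integer", droppedGenes = "character"))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (!identical(names(object@internalFC), names(object@externalFC)))
    msg <- c(msg, "internal and external FC must share gene names")
  if (is.finite(object@pearsonR) &&
      (object@pearsonR < -1 || object@pearsonR > 1))
    msg <- c(msg, "pearsonR outside [-1, 1]")
  if (length(object@nullR) && length(object@nullR) != object@nPermutations)
    msg <- c(msg, "null distribution length must equal nPermutations")
  if (length(msg)) msg else TRUE
})

#' @rdname ConcordanceResult
#' @param x,object a `ConcordanceResult`.
#' @export
setGeneric("pearsonR", function(x) standardGeneric("pearsonR"))

#' @rdname ConcordanceResult
#' @export
setMethod("pearsonR", "ConcordanceResult", function(x) x@pearsonR)

#' @rdname ConcordanceResult
#' @export
setGeneric("nullR", function(x) standardGeneric("nullR"))

#' @rdname ConcordanceResult
#' @export
setMethod("nullR", "ConcordanceResult", function(x) x@nullR)

#' @rdname ConcordanceResult
#' @export
setMethod("show", "ConcordanceResult", function(object) {
  cat(sprintf("ConcordanceResult: %d shared genes, R = %.3f (p = %.3g)\n",
              length(object@internalFC), object@pearsonR, object@pValue))
  if (length(object@droppedGenes))
    cat(sprintf("  dropped (not shared): %s\n",
                paste(object@droppedGenes, collapse = ", ")))
  if (length(object@nullR)) {
    qs <- quantile(object@nullR, c(0.025, 0.975))
    cat(sprintf("  permutation null (n=%d): mean %.3f, 95%% band [%.3f, %.3f]\n",
                length(object@nullR), mean(object@nullR), qs[1], qs[2]))
  }
  invisible(object)
})
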