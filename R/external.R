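#' Fold-change concordance between two cohorts
#'
#' Computes per-gene log2 fold changes (resistant minus sensitive) in an
#' internal cohort — using its predicted phenotype — and in an external
#' cohort with observed labels, over their shared genes, and reports the
#' Pearson correlation with its two-tailed p-value. Genes absent from
#' either cohort are dropped and recorded, never imputed.
#'
#' @param internal internal [ProfileMatrix-class] (mRNA by convention; fold
#'   changes for this comparison are mRNA-vs-mRNA, though a protein matrix
#'   is accepted).
#' @param phenotype named predicted phenotype over internal samples.
#' @param external external [ProfileMatrix-class].
#' @param externalLabels named observed labels over external samples
#'   (`"resistant"`/`"sensitive"`).
#' @return A [ConcordanceResult-class] with an empty permutation null.
#' @seealso [randomizationControl()]
#' @export
foldChangeConcordance <- function(internal, phenotype, external,
                                  externalLabels) {
  int_fc <- groupFoldChange(internal, phenotype)
  ext_fc <- groupFoldChange(external, externalLabels)
  shared <- intersect(names(int_fc), names(ext_fc))
  if (length(shared) < 3)
    degenerateError("fewer than 3 genes shared between the cohorts")
  dropped <- sort(union(setdiff(names(int_fc), shared),
                        setdiff(names(ext_fc), shared)))
  ct <- cor.test(int_fc[shared], ext_fc[shared], method = "pearson")
  new("ConcordanceResult",
      internalFC = int_fc[shared], externalFC = ext_fc[shared],
      pearsonR = unname(ct$estimate), pValue = ct$p.value,
      nullR = numeric(), nPermutations = 0L, seed = NA_integer_,
      droppedGenes = dropped)
}

## Per-gene mean(resistant) - mean(sensitive) on a ProfileMatrix/matrix.
groupFoldChange <- function(x, labels) {
  m <- if (is(x, "ProfileMatrix")) SummarizedExperiment::assay(x, "exprs")
       else x
  if (is.null(names(labels)))
    inputError("labels must be named by sample")
  lab <- sub("^predicted_", "", labels[colnames(m)])
  if (anyNA(lab))
    inputError("every sample needs a label")
  if (!all(lab %in% c("resistant", "sensitive")))
    inputError("labels must be (predicted_)resistant/sensitive")
  if (sum(lab == "resistant") < 2 || sum(lab == "sensitive") < 2)
    degenerateError("each labeled group needs at least 2 samples")
  rowMeans(m[, lab == "resistant", drop = FALSE]) -
    rowMeans(m[, lab == "sensitive", drop = FALSE])
}

#' Label-randomization control for fold-change concordance
#'
#' Permutes the external cohort's response labels (preserving group sizes),
#' recomputes the external fold changes and their correlation with the
#' internal fold changes for each permutation, and attaches the resulting
#' null distribution to the concordance result. A genuine biological
#' concordance should sit far outside the null's 95% band, while the null
#' mean should be near zero.
#'
#' @param concordance a [ConcordanceResult-class] from
#'   [foldChangeConcordance()].
#' @param external the external [ProfileMatrix-class].
#' @param externalLabels the observed external labels (named).
#' @param nPermutations number of label permutations (>= 100; default
#'   1000).
#' @param seed integer seed for the permutations.
#' @return the [ConcordanceResult-class] with `nullR` filled.
#' @export
randomizationControl <- function(concordance, external, externalLabels,
                                 nPermutations = 1000L, seed = 1L) {
  if (!is(concordance, "ConcordanceResult"))
    inputError("'concordance' must come from foldChangeConcordance()")
  checkScalarNumber(nPermutations, "nPermutations", lower = 100)
  m <- SummarizedExperiment::assay(external, "exprs")
  shared <- names(concordance@internalFC)
  if (!all(shared %in% rownames(m)))
    inputError("external matrix lacks the shared genes of 'concordance'")
  m <- m[shared, , drop = FALSE]
  lab <- sub("^predicted_", "", externalLabels[colnames(m)])
  if (anyNA(lab) || !all(lab %in% c("resistant", "sensitive")))
    inputError("invalid external labels")
  if (sum(lab == "resistant") < 2 || sum(lab == "sensitive") < 2)
    degenerateError("each external group needs at least 2 samples")
  int_fc <- concordance@internalFC
  null_r <- withSeed(seed, vapply(seq_len(nPermutations), function(i) {
    perm <- sample(lab)
    fc <- rowMeans(m[, perm == "resistant", drop = FALSE]) -
      rowMeans(m[, perm == "sensitive", drop = FALSE])
    cor(int_fc, fc)
  }, numeric(1)))
  concordance@nullR <- null_r
  concordance@nPermutations <- as.integer(nPermutations)
  concordance@seed <- as.integer(seed)
  validObject(concordance)
  concordance
}
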