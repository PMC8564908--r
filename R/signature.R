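#' Per-feature differential statistics between predicted clusters
#'
#' For each feature, the mean median-centered log2 value in the predicted
#' resistant and predicted sensitive clusters, their difference (log2 fold
#' change, resistant minus sensitive) and a two-tailed pooled-variance
#' Student t-test of the difference. Features with zero pooled variance get
#' p = 1 when the means are equal, otherwise the p-value degenerates to the
#' smallest representable positive number with a warning.
#'
#' @param x a [ProfileMatrix-class] or numeric matrix (features x samples).
#' @param phenotype named vector over the samples of `x` with values
#'   `"predicted_resistant"`/`"predicted_sensitive"` (or bare labels), each
#'   class holding at least 2 samples.
#' @return data.frame with columns `feature_id`, `mean_R`, `mean_S`,
#'   `log2fc`, `t_stat`, `p_value`.
#' @export
differentialStats <- function(x, phenotype) {
  m <- if (is(x, "ProfileMatrix")) SummarizedExperiment::assay(x, "exprs")
       else x
  if (is.null(names(phenotype)))
    inputError("'phenotype' must be named by sample")
  lab <- sub("^predicted_", "", phenotype[colnames(m)])
  if (anyNA(lab))
    inputError("every sample of 'x' needs a phenotype label")
  if (!all(lab %in% c("resistant", "sensitive")))
    inputError("phenotype labels must be (predicted_)resistant/sensitive")
  idx_r <- which(lab == "resistant")
  idx_s <- which(lab == "sensitive")
  if (length(idx_r) < 2 || length(idx_s) < 2)
    degenerateError("both phenotype groups need at least 2 samples")
  res <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, idx_r]
    s <- m[i, idx_s]
    pooled_ss <- sum((r - mean(r))^2) + sum((s - mean(s))^2)
    if (pooled_ss == 0) {
      if (mean(r) == mean(s)) {
        t_stat <- 0
        p <- 1
      } else {
        warning(sprintf(
          "feature '%s': zero pooled variance with unequal means; p degenerates to 0",
          rownames(m)[i]))
        t_stat <- sign(mean(r) - mean(s)) * Inf
        p <- .Machine$double.xmin
      }
    } else {
      tt <- t.test(r, s, var.equal = TRUE)
      t_stat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(feature_id = rownames(m)[i], mean_R = mean(r),
               mean_S = mean(s), log2fc = mean(r) - mean(s),
               t_stat = t_stat, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Sweep nested biomarker sets over |log2FC| thresholds
#'
#' Applies the significance filter (`p < pCut`) once, then extracts the
#' feature set at each absolute fold-change threshold of the grid. With the
#' default grid (0.1 to 1.5 in 0.1 increments) this yields 15 sets, nested
#' by construction: a higher threshold's set is always a subset of a lower
#' one's. Empty sets are retained and flagged so downstream evaluation can
#' skip them with a recorded reason.
#'
#' @param diffs output of [differentialStats()].
#' @param thresholds numeric grid of |log2FC| cutoffs.
#' @param pCut p-value filter (default 0.01).
#' @return list of [BiomarkerSet-class], one per threshold, in grid order.
#' @examples
#' d <- data.frame(feature_id = c("a", "b", "c"),
#'                 mean_R = c(1.2, -1.1, 0.5), mean_S = 0,
#'                 log2fc = c(1.2, -1.1, 0.5), t_stat = 5,
#'                 p_value = c(1e-4, 1e-4, 1e-4))
#' length(setFeatures(sweepBiomarkerSets(d, thresholds = 1)[[1]]))  # 2
#' @export
sweepBiomarkerSets <- function(diffs, thresholds = seq(0.1, 1.5, by = 0.1),
                               pCut = 0.01) {
  req <- c("feature_id", "log2fc", "p_value")
  if (!is.data.frame(diffs) || nrow(diffs) == 0 ||
      !all(req %in% names(diffs)))
    inputError("'diffs' must be a nonempty differentialStats() result")
  if (!is.numeric(thresholds) || !length(thresholds))
    inputError("'thresholds' must be a nonempty numeric vector")
  signif_f <- diffs[diffs$p_value < pCut, , drop = FALSE]
  lapply(thresholds, function(tau) {
    members <- signif_f[abs(signif_f$log2fc) >= tau, , drop = FALSE]
    if (nrow(members) == 0)
      message(sprintf("threshold %.2g yields an empty biomarker set", tau))
    new("BiomarkerSet", threshold = tau,
        features = members$feature_id,
        direction = setNames(
          as.character(ifelse(members$log2fc > 0, "up_in_resistant",
                              "up_in_sensitive")),
          members$feature_id),
        stats = members, pCut = pCut)
  })
}

#' Train a maximum-margin linear classifier on a biomarker set
#'
#' Fits a linear support vector machine (margin penalty `cost`, no feature
#' scaling — inputs are already median-centered log2 values) on the
#' training samples, predicting the cluster phenotype from the set's
#' features. Held-out samples are removed inside this function and recorded
#' on the model, so downstream evaluation can verify structurally that
#' training never saw them.
#'
#' @param x a [ProfileMatrix-class] or matrix (features x samples) of the
#'   training modality (protein).
#' @param features feature IDs to use (e.g. [setFeatures()] of a
#'   [BiomarkerSet-class]).
#' @param labels named phenotype vector over training candidates
#'   (`predicted_sensitive`/`predicted_resistant` or bare labels).
#' @param holdout sample IDs excluded from training (the validated set).
#' @param cost SVM margin penalty (default 1).
#' @return an object of class `svmSignatureModel`.
#' @export
trainSVM <- function(x, features, labels, holdout = character(), cost = 1) {
  m <- if (is(x, "ProfileMatrix")) SummarizedExperiment::assay(x, "exprs")
       else x
  if (!length(features))
    inputError("'features' is empty")
  if (!all(features %in% rownames(m)))
    inputError("some 'features' are absent from the training matrix")
  if (is.null(names(labels)))
    inputError("'labels' must be named by sample")
  train_ids <- setdiff(intersect(names(labels), colnames(m)), holdout)
  if (length(train_ids) < 2)
    inputError("fewer than 2 training samples after holdout exclusion")
  y <- factor(sub("^predicted_", "", labels[train_ids]),
              levels = c("resistant", "sensitive"))
  if (nlevels(droplevels(y)) < 2)
    degenerateError("training data contain a single class")
  fit <- e1071::svm(x = t(m[features, train_ids, drop = FALSE]), y = y,
                    kernel = "linear", cost = cost, scale = FALSE)
  structure(list(fit = fit, features = features,
                 trainSamples = train_ids, holdout = holdout,
                 cost = cost),
            class = "svmSignatureModel")
}

#' @export
print.svmSignatureModel <- function(x, ...) {
  cat(sprintf(
    "svmSignatureModel: linear SVM, %d feature(s), %d training samples (cost = %g)\n",
    length(x$features), length(x$trainSamples), x$cost))
  invisible(x)
}

## Decision scores oriented so that higher means more sensitive.
svmScores <- function(model, test_matrix) {
  pr <- predict(model$fit, t(test_matrix), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pos_class <- strsplit(colnames(dv)[1], "/")[[1]][1]
  score <- dv[, 1]
  if (pos_class != "sensitive") score <- -score
  setNames(score, colnames(test_matrix))
}

## Threshold-swept precision-recall and ROC curves with tie grouping.
## PR AUC is step-wise (average precision); ROC AUC is trapezoidal, which
## on the tie-grouped curve equals the midpoint (rank) convention.
scoreCurves <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- positive[ord]
  P <- sum(positive)
  N <- sum(!positive)
  cum_tp <- cumsum(y)
  cum_fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tie block
  tp <- cum_tp[last]
  fp <- cum_fp[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  roc_auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(pr = data.frame(recall = recall, precision = precision),
       roc = data.frame(fpr = fpr, tpr = tpr),
       pr_auc = pr_auc, roc_auc = roc_auc)
}

#' Evaluate a trained classifier on held-out samples
#'
#' Computes continuous decision scores on the test samples and derives
#' precision-recall and ROC curves against the observed in-vivo responses,
#' with sensitive as the positive class. For mRNA test sets, supply a
#' `featureMap` from [matchFeatures()]; the test matrix rows are then the
#' mapped genes, renamed back to the model's protein features. Any overlap
#' between test samples and the model's training samples is an error, as is
#' a single-class test set (the PR curve is undefined).
#'
#' @param model an `svmSignatureModel` from [trainSVM()].
#' @param test a [ProfileMatrix-class] or matrix holding the test samples.
#' @param testLabels named observed responses (`sensitive`/`resistant`) of
#'   the test samples.
#' @param featureMap optional data.frame from [matchFeatures()] used to
#'   translate model features to test-matrix rows.
#' @param threshold sweep threshold recorded on the result (default `NA`).
#' @return A [ClassifierEval-class].
#' @export
evaluateClassifier <- function(model, test, testLabels, featureMap = NULL,
                               threshold = NA_real_) {
  if (!inherits(model, "svmSignatureModel"))
    inputError("'model' must come from trainSVM()")
  mod_modality <- if (is(test, "ProfileMatrix")) modality(test) else "protein"
  m <- if (is(test, "ProfileMatrix")) SummarizedExperiment::assay(test, "exprs")
       else test
  if (is.null(names(testLabels)))
    inputError("'testLabels' must be named by sample")
  ids <- intersect(names(testLabels), colnames(m))
  if (!length(ids))
    inputError("no test sample is present in the test matrix")
  leaked <- intersect(ids, model$trainSamples)
  if (length(leaked))
    inputError(sprintf("test samples seen in training: %s",
                       paste(head(leaked, 5), collapse = ", ")))
  if (is.null(featureMap)) {
    if (!all(model$features %in% rownames(m)))
      inputError("model features missing from the test matrix")
    tm <- m[model$features, ids, drop = FALSE]
  } else {
    fm <- featureMap[featureMap$protein_feature %in% model$features, ,
                     drop = FALSE]
    if (!setequal(fm$protein_feature, model$features))
      inputError("featureMap does not cover all model features")
    if (!all(fm$mrna_feature %in% rownames(m)))
      inputError("mapped features missing from the test matrix")
    tm <- m[fm$mrna_feature, ids, drop = FALSE]
    rownames(tm) <- fm$protein_feature
    tm <- tm[model$features, , drop = FALSE]
  }
  obs <- sub("^predicted_", "", testLabels[ids])
  if (!all(obs %in% c("sensitive", "resistant")))
    inputError("test labels must be 'sensitive' or 'resistant'")
  positive <- obs == "sensitive"
  if (all(positive) || !any(positive))
    degenerateError("test set contains a single class; PR AUC undefined")
  scores <- svmScores(model, tm)
  cur <- scoreCurves(scores, positive)
  new("ClassifierEval", threshold = threshold, modality = mod_modality,
      prAUC = cur$pr_auc, rocAUC = cur$roc_auc,
      prCurve = cur$pr, rocCurve = cur$roc,
      scores = scores, labels = setNames(obs, ids),
      nFeatures = length(model$features))
}

#' Evaluate every biomarker set of a sweep across modalities
#'
#' Orchestrates the train/test protocol of the threshold sweep: for each
#' nonempty biomarker set, a linear SVM is trained on the protein values of
#' the non-validated samples against the cluster phenotype, then evaluated
#' on the validated samples using (a) their protein values and (b) their
#' mRNA values via gene-symbol matching (the model is retrained on the
#' mappable feature subset, since unmapped probes have no mRNA
#' counterpart). Empty sets, single-class situations and unmappable sets
#' are skipped with a recorded reason.
#'
#' @param protein protein [ProfileMatrix-class] (training modality).
#' @param mrna mRNA [ProfileMatrix-class], or `NULL` to evaluate
#'   protein-only.
#' @param sets list of [BiomarkerSet-class] from [sweepBiomarkerSets()].
#' @param phenotype named predicted phenotype per sample
#'   (from [predictedPhenotype()]).
#' @param observed named observed responses of the validated samples (the
#'   test set).
#' @param cost SVM margin penalty.
#' @return list with `evals` (list of [ClassifierEval-class]) and `summary`
#'   (data.frame with one row per set x modality, including skip reasons).
#' @export
evaluateSweep <- function(protein, mrna, sets, phenotype, observed,
                          cost = 1) {
  if (!length(sets))
    inputError("'sets' is empty")
  holdout <- names(observed)
  evals <- list()
  rows <- list()
  note <- function(threshold, mod, nfeat, pr, roc, reason)
    data.frame(threshold = threshold, modality = mod, n_features = nfeat,
               pr_auc = pr, roc_auc = roc,
               skipped = !is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  for (set in sets) {
    tau <- set@threshold
    if (!length(set@features)) {
      for (mod in c("protein", if (!is.null(mrna)) "mrna"))
        rows[[length(rows) + 1L]] <-
          note(tau, mod, 0L, NA_real_, NA_real_, "empty set")
      next
    }
    res <- tryCatch({
      model <- trainSVM(protein, set@features, phenotype, holdout, cost)
      evaluateClassifier(model, protein, observed, threshold = tau)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows[[length(rows) + 1L]] <-
        note(tau, "protein", length(set@features), NA_real_, NA_real_, res)
    } else {
      evals[[length(evals) + 1L]] <- res
      rows[[length(rows) + 1L]] <-
        note(tau, "protein", length(set@features), res@prAUC, res@rocAUC,
             NA_character_)
    }
    if (is.null(mrna)) next
    res_m <- tryCatch({
      fm <- matchFeatures(protein, mrna, set@features)
      model_m <- trainSVM(protein, fm$protein_feature, phenotype, holdout,
                          cost)
      evaluateClassifier(model_m, mrna, observed, featureMap = fm,
                         threshold = tau)
    }, error = function(e) conditionMessage(e))
    if (is.character(res_m)) {
      rows[[length(rows) + 1L]] <-
        note(tau, "mrna", length(set@features), NA_real_, NA_real_, res_m)
    } else {
      evals[[length(evals) + 1L]] <- res_m
      rows[[length(rows) + 1L]] <-
        note(tau, "mrna", res_m@nFeatures, res_m@prAUC, res_m@rocAUC,
             NA_character_)
    }
  }
  list(evals = evals, summary = do.call(rbind, rows))
}

#' Choose the best threshold across modalities
#'
#' Selects the sweep threshold whose biomarker set maximizes the minimum
#' PR AUC across the evaluated modalities — the least-assumptive reading of
#' "best for both" — breaking ties toward the larger threshold (the smaller
#' signature). Thresholds missing a non-skipped evaluation in any modality
#' present in the sweep are not eligible.
#'
#' @param sweep result of [evaluateSweep()] (or its `summary` data.frame).
#' @param sets the list of [BiomarkerSet-class] evaluated.
#' @return list with `threshold`, `set` (the chosen
#'   [BiomarkerSet-class]), and `criterion` (per-threshold min PR AUC).
#' @export
selectSignature <- function(sweep, sets) {
  summ <- if (is.data.frame(sweep)) sweep else sweep$summary
  ok <- summ[!summ$skipped, , drop = FALSE]
  if (nrow(ok) == 0)
    degenerateError("all classifier evaluations were skipped")
  modalities <- unique(summ$modality)
  per_thr <- split(ok, ok$threshold)
  crit <- vapply(per_thr, function(d) {
    if (!all(modalities %in% d$modality)) NA_real_ else min(d$pr_auc)
  }, numeric(1))
  crit <- crit[!is.na(crit)]
  if (!length(crit))
    degenerateError("no threshold has a valid evaluation in every modality")
  thr_vals <- as.numeric(names(crit))
  best <- max(crit)
  chosen <- max(thr_vals[crit >= best - 1e-12])
  taus <- vapply(sets, slot, numeric(1), "threshold")
  list(threshold = chosen,
       set = sets[[which.min(abs(taus - chosen))]],
       criterion = setNames(crit, names(crit)))
}

#' Finalize a signature to gene-mappable members
#'
#' Drops features without a gene symbol (probes not measurable at the mRNA
#' level, such as the PAR polymer probe) and records each remaining
#' feature's direction, yielding the cross-modality signature.
#'
#' @param set a nonempty [BiomarkerSet-class].
#' @param geneMap named character feature-to-symbol map (`NA` = unmapped),
#'   e.g. [geneMap()] of the protein matrix or [readGeneMap()].
#' @return a [BiomarkerSet-class] restricted to mapped features; dropped
#'   features are reported in `attr(, "dropped")`.
#' @export
finalizeSignature <- function(set, geneMap) {
  if (!is(set, "BiomarkerSet") || !length(set@features))
    inputError("'set' must be a nonempty BiomarkerSet")
  mapped <- set@features[!is.na(geneMap[set@features])]
  dropped <- setdiff(set@features, mapped)
  if (!length(mapped))
    degenerateError("no signature feature has a gene symbol")
  out <- new("BiomarkerSet", threshold = set@threshold,
             features = mapped,
             direction = set@direction[mapped],
             stats = set@stats[set@stats$feature_id %in% mapped, ,
                               drop = FALSE],
             pCut = set@pCut)
  attr(out, "dropped") <- dropped
  out
}
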