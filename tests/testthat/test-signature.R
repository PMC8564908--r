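test_that("differentialStats matches the pooled-t textbook formula", {
  withr::local_seed(11)
  m <- matrix(rnorm(30 * 10), nrow = 30,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  ph <- setNames(rep(c("predicted_resistant", "predicted_sensitive"),
                     each = 5), colnames(m))
  d <- differentialStats(m, ph)
  expect_identical(d$feature_id, rownames(m))
  expect_equal(d$log2fc, d$mean_R - d$mean_S, tolerance = 1e-15)
  for (i in c(1, 7, 30)) {
    o <- studentTOracle(m[i, 1:5], m[i, 6:10])
    expect_equal(d$t_stat[i], o$t, tolerance = 1e-12)
    expect_equal(d$p_value[i], o$p, tolerance = 1e-12)
  }
})

test_that("differentialStats handles degenerate variance per contract", {
  m <- rbind(flat = rep(1, 8), shifted = rep(c(0, 1), each = 4))
  colnames(m) <- paste0("s", 1:8)
  ph <- setNames(rep(c("resistant", "sensitive"), each = 4), colnames(m))
  expect_warning(d <- differentialStats(m, ph), "zero pooled variance")
  expect_identical(d$p_value[d$feature_id == "flat"], 1)
  expect_identical(d$log2fc[d$feature_id == "flat"], 0)
  expect_lt(d$p_value[d$feature_id == "shifted"], 1e-100)

  expect_error(differentialStats(m, ph[1:5]), class = "rppasig_input_error")
  ph_small <- setNames(c("resistant", rep("sensitive", 7)), colnames(m))
  expect_error(suppressWarnings(differentialStats(m, ph_small)),
               class = "rppasig_degenerate_error")
})

test_that("sweepBiomarkerSets yields the default 15 nested, filtered sets", {
  co <- smallCohortRun(seed = 1)
  d <- differentialStats(co$protein, co$phenotype)
  sets <- sweepBiomarkerSets(d)
  expect_length(sets, 15)
  expect_equal(vapply(sets, setThreshold, numeric(1)),
               seq(0.1, 1.5, by = 0.1))
  for (s in sets) {
    st <- s@stats
    expect_true(all(st$p_value < 0.01))
    expect_true(all(abs(st$log2fc) >= setThreshold(s)))
  }
  ## nestedness across every adjacent pair
  for (i in seq_len(14))
    expect_true(all(setFeatures(sets[[i + 1]]) %in% setFeatures(sets[[i]])))
})

test_that("sweep membership and directions follow the definitions", {
  d <- data.frame(feature_id = c("a", "b", "c"),
                  mean_R = c(1.2, -1.1, 0.5), mean_S = 0,
                  log2fc = c(1.2, -1.1, 0.5), t_stat = 5,
                  p_value = c(1e-4, 1e-4, 1e-4))
  s1 <- sweepBiomarkerSets(d, thresholds = 1)[[1]]
  expect_setequal(setFeatures(s1), c("a", "b"))
  expect_identical(unname(featureDirection(s1)[c("a", "b")]),
                   c("up_in_resistant", "up_in_sensitive"))

  ## p-filter removes otherwise-large fold changes
  d$p_value[1] <- 0.5
  expect_identical(setFeatures(sweepBiomarkerSets(d, thresholds = 1)[[1]]),
                   "b")
  ## empty set is retained and flagged
  expect_message(empty <- sweepBiomarkerSets(d, thresholds = 5)[[1]],
                 "empty")
  expect_length(setFeatures(empty), 0)
  expect_error(sweepBiomarkerSets(d[0, ]), class = "rppasig_input_error")
})

test_that("trainSVM separates separable data and guards its contract", {
  m <- rbind(f1 = c(rep(2, 5), rep(-2, 5)) + rnorm(10, sd = 0.1),
             f2 = c(rep(2, 5), rep(-2, 5)) + rnorm(10, sd = 0.1))
  colnames(m) <- paste0("s", 1:10)
  lab <- setNames(rep(c("predicted_sensitive", "predicted_resistant"),
                      each = 5), colnames(m))
  model <- trainSVM(m, c("f1", "f2"), lab)
  pred <- predict(model$fit, t(m[model$features, ]))
  expect_identical(mean(pred == sub("predicted_", "", lab)), 1)

  one_class <- setNames(rep("predicted_sensitive", 10), colnames(m))
  expect_error(trainSVM(m, c("f1", "f2"), one_class),
               class = "rppasig_degenerate_error")
  expect_error(trainSVM(m, character(), lab), class = "rppasig_input_error")

  ## holdout samples are excluded structurally, and leakage is rejected
  held <- c("s1", "s6")
  model_h <- trainSVM(m, c("f1", "f2"), lab, holdout = held)
  expect_length(intersect(model_h$trainSamples, held), 0)
  obs <- setNames(c("sensitive", "resistant"), held)
  ev <- evaluateClassifier(model_h, m, obs)
  expect_s4_class(ev, "ClassifierEval")
  leaky <- setNames(c("sensitive", "resistant"), c("s2", "s7"))
  expect_error(evaluateClassifier(model_h, m, leaky), "training",
               class = "rppasig_input_error")
})

test_that("curve construction follows the stated tie and interpolation conventions", {
  sc <- rppasig:::scoreCurves
  ## perfect ranking
  perfect <- sc(c(5, 4, 3, 2, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(perfect$pr_auc, 1)
  expect_identical(perfect$roc_auc, 1)
  ## constant scores: one operating point, midpoint ROC convention
  const <- sc(rep(1, 6), rep(c(TRUE, FALSE), 3))
  expect_identical(const$roc_auc, 0.5)
  expect_identical(const$pr_auc, 0.5)  # precision = prevalence at recall 1
  ## worst ranking
  worst <- sc(1:4, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(worst$roc_auc, 0)
})

test_that("PR and ROC AUCs agree with exhaustive threshold oracles", {
  withr::local_seed(19)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    npos <- sample(seq_len(n - 1), 1)
    positive <- sample(rep(c(TRUE, FALSE), c(npos, n - npos)))
    scores <- if (rep %% 3 == 0)
      sample(seq_len(3), n, replace = TRUE)  # heavy ties
    else rnorm(n)
    got <- rppasig:::scoreCurves(scores, positive)
    expect_equal(got$roc_auc, rocAucOracle(scores, positive),
                 tolerance = 1e-12)
    expect_equal(got$pr_auc, prAucOracle(scores, positive),
                 tolerance = 1e-12)
  }
})

test_that("cross-modality evaluation transfers protein-trained models to mRNA", {
  co <- smallCohortRun(seed = 3)
  obs <- setNames(co$metadata$observed_response[co$metadata$validated],
                  co$metadata$sample_id[co$metadata$validated])
  d <- differentialStats(co$protein, co$phenotype)
  sets <- sweepBiomarkerSets(d)
  sw <- evaluateSweep(co$protein, co$mrna, sets, co$phenotype, obs)
  expect_true(all(c("protein", "mrna") %in% sw$summary$modality))
  ok <- sw$summary[!sw$summary$skipped, ]
  expect_true(all(ok$pr_auc >= 0 & ok$pr_auc <= 1))
  ## strong planted signal: held-out performance is high in both modalities
  expect_gt(min(ok$pr_auc), 0.9)
  ## no evaluation ever trains on a validated sample (structural assert)
  for (ev in sw$evals)
    expect_length(intersect(names(ev@scores), co$metadata$sample_id[
      !co$metadata$validated]), 0)
})

test_that("single-class test sets are rejected, PR AUC being undefined", {
  co <- smallCohortRun(seed = 4)
  model <- trainSVM(co$protein, co$signature$group1, co$phenotype,
                    holdout = c("PDX_01", "PDX_02"))
  obs_one <- c(PDX_01 = "sensitive", PDX_02 = "sensitive")
  expect_error(evaluateClassifier(model, co$protein, obs_one),
               class = "rppasig_degenerate_error")
})

test_that("selectSignature maximizes the cross-modality minimum with tie rules", {
  mk <- function(threshold, modality, pr)
    data.frame(threshold = threshold, modality = modality, n_features = 5,
               pr_auc = pr, roc_auc = pr, skipped = FALSE,
               reason = NA_character_)
  sets <- sweepBiomarkerSets(
    data.frame(feature_id = letters[1:5], mean_R = 2, mean_S = 0,
               log2fc = 2, t_stat = 9, p_value = 1e-5),
    thresholds = c(0.5, 1.0, 1.5))
  summ <- rbind(mk(0.5, "protein", 0.6), mk(0.5, "mrna", 0.5),
                mk(1.0, "protein", 0.9), mk(1.0, "mrna", 0.9),
                mk(1.5, "protein", 0.8), mk(1.5, "mrna", 0.7))
  expect_identical(selectSignature(summ, sets)$threshold, 1.0)

  tied <- rbind(mk(0.5, "protein", 0.9), mk(0.5, "mrna", 0.9),
                mk(1.0, "protein", 0.9), mk(1.0, "mrna", 0.9),
                mk(1.5, "protein", 0.9), mk(1.5, "mrna", 0.9))
  expect_identical(selectSignature(tied, sets)$threshold, 1.5)

  ## a threshold missing one modality is ineligible
  partial <- rbind(mk(0.5, "protein", 0.7), mk(0.5, "mrna", 0.6),
                   mk(1.5, "protein", 1.0))
  partial$skipped[3] <- TRUE
  partial$reason[3] <- "empty set"
  expect_identical(selectSignature(partial, sets)$threshold, 0.5)

  none <- mk(1, "protein", NA_real_)
  none$skipped <- TRUE
  expect_error(selectSignature(none, sets),
               class = "rppasig_degenerate_error")
})

test_that("finalizeSignature drops unmapped probes and keeps directions", {
  stats9 <- data.frame(
    feature_id = c("GJA1", "CAV1", "AXL", "FN1", "TMEM173", "SOX2",
                   "BRD4", "CLDN7", "PAR"),
    mean_R = c(-1.5, -1.8, -1.2, -1.1, 1.4, 1.9, 1.2, 1.1, 1.3),
    mean_S = 0, t_stat = 8, p_value = 1e-6)
  stats9$log2fc <- stats9$mean_R
  set9 <- sweepBiomarkerSets(stats9, thresholds = 1)[[1]]
  expect_length(setFeatures(set9), 9)
  gm <- readGeneMap(system.file("extdata", "signature_gene_map.csv",
                                package = "rppasig"))
  final <- finalizeSignature(set9, gm)
  expect_length(setFeatures(final), 8)
  expect_identical(attr(final, "dropped"), "PAR")
  dir <- featureDirection(final)
  expect_true(all(dir[c("GJA1", "CAV1", "AXL", "FN1")] == "up_in_sensitive"))
  expect_true(all(dir[c("TMEM173", "SOX2", "BRD4", "CLDN7")] ==
                    "up_in_resistant"))

  expect_identical(setFeatures(finalizeSignature(set9,
                                                 setNames(stats9$feature_id,
                                                          stats9$feature_id))),
                   setFeatures(set9))
  all_na <- setNames(rep(NA_character_, 9), stats9$feature_id)
  expect_error(finalizeSignature(set9, all_na),
               class = "rppasig_degenerate_error")
})
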