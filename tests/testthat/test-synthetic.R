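test_that("generateCohort produces the specified dimensions and structure", {
  cohort <- generateCohort(cohortSpec(seed = 1))
  expect_s4_class(cohort$protein, "ProfileMatrix")
  expect_identical(dim(cohort$protein), c(247L, 65L))
  expect_identical(modality(cohort$protein), "protein")
  expect_identical(modality(cohort$mrna), "mrna")
  expect_identical(ncol(cohort$mrna), 65L)
  ## mRNA covers exactly the gene-mapped protein features
  gm <- geneMap(cohort$protein)
  expect_identical(nrow(cohort$mrna), sum(!is.na(gm)))
  expect_true(all(stats::na.omit(gm) %in% rownames(cohort$mrna)))

  md <- cohort$metadata
  expect_identical(nrow(md), 65L)
  expect_identical(sum(md$validated), 17L)
  ## stratified validation split: 10 sensitive + 7 resistant at defaults
  expect_identical(as.vector(table(md$true_cluster[md$validated])[
    c("sensitive", "resistant")]), c(10L, 7L))
  expect_true(all(md$observed_response[md$validated] != "unknown"))
  expect_true(all(md$observed_response[!md$validated] == "unknown"))
  expect_identical(md$observed_response[md$validated],
                   md$true_cluster[md$validated])
})

test_that("generated matrices are median-centered per feature and deterministic", {
  spec <- cohortSpec(nSamples = 24, nFeatures = 40, seed = 9)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(assay(a$protein), assay(b$protein))
  expect_identical(assay(a$mrna), assay(b$mrna))
  expect_identical(a$metadata, b$metadata)
  c2 <- generateCohort(cohortSpec(nSamples = 24, nFeatures = 40, seed = 10))
  expect_false(identical(assay(a$protein), assay(c2$protein)))

  for (m in list(assay(a$protein), assay(a$mrna)))
    expect_lt(max(abs(apply(m, 1, median))), 1e-9)
})

test_that("cohortSpec rejects invalid parameters, naming the field", {
  expect_error(cohortSpec(nSignatureFeatures = 30, nFeatures = 40),
               "nSignatureFeatures", class = "rppasig_input_error")
  expect_error(cohortSpec(resistantFraction = 0), "resistantFraction",
               class = "rppasig_input_error")
  expect_error(cohortSpec(noiseSd = 0), "noiseSd",
               class = "rppasig_input_error")
  expect_error(cohortSpec(proteinMrnaCorr = 1.2), "proteinMrnaCorr",
               class = "rppasig_input_error")
  expect_error(generateCohort(list()), class = "rppasig_input_error")
})

test_that("planted effect size controls cluster recoverability monotonically", {
  ## recovery (ARI against planted truth) must be non-decreasing in the
  ## effect/noise ratio, from chance at zero effect to exact at high effect
  mean_ari <- vapply(c(0, 0.6, 2), function(es) {
    mean(vapply(1:20, function(s) {
      co <- generateCohort(cohortSpec(nSamples = 30, nFeatures = 60,
                                      nValidated = 8,
                                      effectSize = es, seed = s))
      cl <- sampleClusters(wardBicluster(co$protein))
      ari(as.character(cl), co$metadata$true_cluster)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_ari) >= -0.02))
  expect_lt(abs(mean_ari[1]), 0.1)   # chance at effect 0
  expect_gt(mean_ari[3], 0.99)       # exact at strong separation
})

test_that("near-zero noise with strong effect recovers the planted partition exactly", {
  co <- generateCohort(cohortSpec(nSamples = 20, nFeatures = 30,
                                  nValidated = 6,
                                  effectSize = 2, noiseSd = 1e-4, seed = 4))
  cl <- sampleClusters(wardBicluster(co$protein))
  expect_identical(ari(as.character(cl), co$metadata$true_cluster), 1)
})

test_that("realized protein-mRNA correlation tracks the target", {
  for (rho in c(0.4, 0.7, 0.9)) {
    co <- generateCohort(cohortSpec(proteinMrnaCorr = rho, seed = 21))
    gm <- geneMap(co$protein)
    mapped <- names(gm)[!is.na(gm)]
    cors <- vapply(mapped, function(f)
      cor(assay(co$protein)[f, ], assay(co$mrna)[gm[[f]], ]), numeric(1))
    expect_lt(abs(mean(cors) - rho), 0.1)
  }
})

test_that("growth generation respects truth labels and the endpoint-ratio rule", {
  ## noiseless construction: calls must equal the planted labels
  spec0 <- growthSpec(measurementCv = 0, seed = 1)
  calls <- callResponse(generateGrowth(spec0, c(P1 = "sensitive",
                                                P2 = "resistant")))
  expect_identical(setNames(calls$call, calls$pdx_id),
                   c(P1 = "sensitive", P2 = "resistant"))
  rat <- setNames(calls$endpoint_ratio, calls$pdx_id)
  expect_lt(rat[["P1"]], 0.5)
  expect_gt(rat[["P2"]], 0.5)

  ## default measurement noise: label recovery across seeds stays >= 95%
  hits <- vapply(1:100, function(s) {
    g <- generateGrowth(growthSpec(seed = s),
                        c(A = "sensitive", B = "resistant"))
    calls <- callResponse(g)
    all(setNames(calls$call, calls$pdx_id) == c(A = "sensitive",
                                                B = "resistant"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("growthSpec validates its effect-size invariants and inputs", {
  expect_error(growthSpec(sensitiveEffect = 0.9), "sensitiveEffect",
               class = "rppasig_input_error")
  expect_error(growthSpec(resistantEffect = 0), "resistantEffect",
               class = "rppasig_input_error")
  expect_error(growthSpec(initialVolume = -5), class = "rppasig_input_error")
  expect_error(generateGrowth(growthSpec(), character()),
               class = "rppasig_input_error")
  expect_error(generateGrowth(growthSpec(), c(A = "maybe")),
               class = "rppasig_input_error")
})

test_that("external cohort generation honors arm sizes, signs and determinism", {
  fc <- setNames(c(rnorm(40, sd = 0.1), 2, -2, 1.5, -1.5),
                 c(sprintf("G%02d", 1:40), "AXL", "SOX2", "CAV1", "BRD4"))
  ext <- generateExternalCohort(fc, nResistant = 4, nSensitive = 7,
                                seed = 3)
  expect_identical(ncol(ext$mrna), 11L)
  expect_identical(as.vector(table(ext$labels)[c("resistant", "sensitive")]),
                   c(4L, 7L))
  again <- generateExternalCohort(fc, nResistant = 4, nSensitive = 7,
                                  seed = 3)
  expect_identical(assay(ext$mrna), assay(again$mrna))

  ## discordant features flip their fold-change sign relative to internal
  ext_d <- generateExternalCohort(fc, discordantFeatures = "AXL",
                                  noiseSd = 0.05, seed = 3)
  ext_fc <- rppasig:::groupFoldChange(ext_d$mrna, ext_d$labels)
  expect_lt(sign(ext_fc[["AXL"]]) * sign(fc[["AXL"]]), 0)
  expect_gt(sign(ext_fc[["CAV1"]]) * sign(fc[["CAV1"]]), 0)

  expect_error(generateExternalCohort(fc, discordantFeatures = "NOPE"),
               class = "rppasig_input_error")
})

test_that("IHC cell generation matches the requested positive fraction", {
  thr <- 1
  all_neg <- generateIHCCells(500, 0, thr, seed = 2)
  expect_identical(scoreSection(all_neg, thr)$pct_positive, 0)
  all_pos <- generateIHCCells(500, 1, thr, seed = 2)
  expect_identical(scoreSection(all_pos, thr)$pct_positive, 100)
  mid <- generateIHCCells(10000, 0.3, thr, seed = 5)
  pct <- scoreSection(mid, thr)$pct_positive
  ## binomial 99% interval around 30% at n = 10000
  expect_gt(pct, 27)
  expect_lt(pct, 33)
  expect_error(generateIHCCells(0, 0.5), class = "rppasig_input_error")
  expect_identical(generateIHCCells(50, 0.4, seed = 8),
                   generateIHCCells(50, 0.4, seed = 8))
})
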