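test_that("tumorVolume applies the L x W^2 / 2 formula with dimension policing", {
  expect_identical(tumorVolume(10, 4), 80)
  expect_identical(tumorVolume(6, 6), 108)
  expect_warning(v <- tumorVolume(4, 10), "swap")
  expect_identical(v, 80)
  expect_error(tumorVolume(0, 1), class = "rppasig_input_error")
  expect_error(tumorVolume(5, -1), class = "rppasig_input_error")
})

test_that("callResponse uses the inclusive 50%-reduction rule at endpoint", {
  mk <- function(pdx, arm, vols, day = 21)
    data.frame(pdx_id = pdx, arm = arm,
               animal = paste0(pdx, arm, seq_along(vols)),
               day = day, volume_mm3 = vols)
  boundary <- rbind(mk("P1", "drug", c(90, 110)),
                    mk("P1", "vehicle", c(200, 200)))
  call <- callResponse(boundary)
  expect_identical(call$endpoint_ratio, 0.5)
  expect_identical(call$call, "sensitive")   # boundary inclusive

  resistant <- rbind(mk("P2", "drug", 180), mk("P2", "vehicle", 200))
  expect_identical(callResponse(resistant)$call, "resistant")

  ## only the final day enters the endpoint ratio
  multi <- rbind(mk("P3", "drug", 50, day = 7), mk("P3", "drug", 100),
                 mk("P3", "vehicle", 100, day = 7),
                 mk("P3", "vehicle", 400))
  expect_identical(callResponse(multi)$endpoint_ratio, 0.25)

  expect_error(callResponse(mk("P4", "drug", 100)),
               class = "rppasig_input_error")
  uneven <- rbind(mk("P5", "drug", 100, day = 18),
                  mk("P5", "vehicle", 300, day = 21))
  expect_warning(call5 <- callResponse(uneven), "different days")
  expect_identical(call5$endpoint_ratio, 1 / 3)
})

test_that("evaluatePredictions reproduces contingency rates from validation counts", {
  ## 10 predicted-sensitive all correct; 5 of 7 predicted-resistant correct
  pred <- setNames(rep(c("predicted_sensitive", "predicted_resistant"),
                       c(10, 7)), sprintf("P%02d", 1:17))
  obs <- setNames(c(rep("sensitive", 10), rep("resistant", 5),
                    rep("sensitive", 2)), sprintf("P%02d", 1:17))
  cs <- evaluatePredictions(pred, obs)
  expect_identical(cs@counts, c(tp = 10L, fp = 2L, tn = 5L, fn = 0L))
  rr <- reportRates(cs)
  expect_identical(rr[["accuracy"]], 88)
  expect_identical(rr[["tpr"]], 100)
  expect_identical(rr[["tnr"]], 71)
  expect_identical(rr[["fpr"]], 29)
  expect_identical(rr[["fnr"]], 0)

  ## per-arm exact CIs: 10/10 -> 69-100, 15/17 -> 64-99; for 5/7 the exact
  ## interval starts at 29.04%, i.e. 29 after rounding
  ci_pct <- lapply(cs@ci, function(ci)
    unname(rppasig:::roundHalfUp(100 * ci)))
  expect_identical(ci_pct$tpr, c(69, 100))
  expect_identical(ci_pct$accuracy, c(64, 99))
  expect_identical(ci_pct$tnr, c(29, 96))
})

test_that("perfect and inverted predictions hit the rate extremes", {
  pred <- setNames(rep(c("sensitive", "resistant"), each = 4),
                   paste0("x", 1:8))
  cs <- evaluatePredictions(pred, pred)
  expect_identical(reportRates(cs)[["accuracy"]], 100)
  expect_identical(reportRates(cs)[["fpr"]], 0)
  expect_identical(reportRates(cs)[["fnr"]], 0)

  inv <- setNames(rep(c("resistant", "sensitive"), each = 4),
                  paste0("x", 1:8))
  expect_identical(reportRates(evaluatePredictions(pred, inv))[["accuracy"]],
                   0)
  expect_error(evaluatePredictions(pred, setNames(inv, paste0("y", 1:8))),
               class = "rppasig_input_error")
})

test_that("clopperPearson matches the closed forms and the inversion oracle", {
  ci <- clopperPearson(10, 10, 0.05)
  expect_equal(ci[["lower"]], 0.025^(1 / 10), tolerance = 1e-12)
  expect_identical(ci[["upper"]], 1)
  ci0 <- clopperPearson(0, 10, 0.05)
  expect_identical(ci0[["lower"]], 0)
  expect_equal(ci0[["upper"]], 1 - 0.025^(1 / 10), tolerance = 1e-12)

  withr::local_seed(7)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    x <- sample(0:n, 1)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(clopperPearson(x, n, alpha),
                 clopperPearsonOracle(x, n, alpha), tolerance = 1e-8)
  }

  expect_error(clopperPearson(5, 4), class = "rppasig_input_error")
  expect_error(clopperPearson(-1, 4), class = "rppasig_input_error")
  expect_error(clopperPearson(1, 4, alpha = 0), class = "rppasig_input_error")
})

test_that("clopperPearson intervals are monotone and contain the estimate", {
  n <- 17
  lowers <- vapply(0:n, function(x) clopperPearson(x, n)[["lower"]],
                   numeric(1))
  expect_true(!is.unsorted(lowers))
  for (x in 0:n) {
    ci <- clopperPearson(x, n)
    expect_lte(ci[["lower"]], x / n)
    expect_gte(ci[["upper"]], x / n)
  }
})

test_that("cramersV matches the chi-squared definition and is symmetric", {
  a <- rep(c("u", "v"), each = 5)
  expect_equal(cramersV(a, a)$cramers_v, 1)

  ## independent-by-construction product table gives V = 0
  a2 <- rep(c("u", "v"), each = 10)
  b2 <- rep(rep(c("p", "q"), each = 5), 2)
  expect_equal(cramersV(a2, b2)$cramers_v, 0)

  ## [[10, 0], [2, 5]] against the hand-computed oracle
  a3 <- rep(c("x", "x", "y", "y"), c(10, 0, 2, 5))
  b3 <- rep(c("p", "q", "p", "q"), c(10, 0, 2, 5))
  got <- cramersV(a3, b3)
  want <- cramersVOracle(table(a3, b3))
  expect_equal(got$cramers_v, want$v, tolerance = 1e-12)
  expect_equal(got$chi2, want$chi2, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  ## symmetry and relabeling invariance
  expect_equal(cramersV(b3, a3)$cramers_v, got$cramers_v)
  relab <- c(x = "first", y = "second")[a3]
  expect_equal(cramersV(relab, b3)$cramers_v, got$cramers_v)

  expect_error(cramersV(rep("x", 6), b3[1:6]),
               class = "rppasig_degenerate_error")
  expect_error(cramersV(a3, b3[1:5]), class = "rppasig_input_error")
})

test_that("associationTable ranks cluster prediction among covariates", {
  co <- smallCohortRun(seed = 2)
  tab <- associationTable(co$metadata, predicted = co$phenotype)
  expect_true("biomarker_cluster" %in% tab$covariate)
  expect_true(all(tab$cramers_v >= 0 & tab$cramers_v <= 1))
  ## prediction derives from the planted structure: it should dominate
  expect_identical(tab$covariate[1], "biomarker_cluster")
})
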