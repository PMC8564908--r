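suppressPackageStartupMessages(library(SummarizedExperiment))

## Independent brute-force oracles used to cross-check the package's
## statistics. Each is written from the textbook definition, not by calling
## the code path it checks.

## Naive O(n^3) agglomerative Ward clustering via the Lance-Williams update
## on squared Euclidean distances. Returns the merge cost sequence and the
## two-cluster partition.
naiveWard2 <- function(x) {
  n <- nrow(x)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  repeat {
    k <- length(active)
    if (k == 2) break
    best <- c(NA, NA)
    best_cost <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ci <- active[[i]]
      cj <- active[[j]]
      ## Ward merge cost: increase in within-cluster sum of squares
      mi <- colMeans(x[ci, , drop = FALSE])
      mj <- colMeans(x[cj, , drop = FALSE])
      cc <- length(ci) * length(cj) / (length(ci) + length(cj)) *
        sum((mi - mj)^2)
      if (cc < best_cost - 1e-12) {
        best_cost <- cc
        best <- c(i, j)
      }
    }
    heights <- c(heights, best_cost)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best[2]]
  }
  part <- integer(n)
  part[active[[1]]] <- 1L
  part[active[[2]]] <- 2L
  list(partition = part, heights = heights)
}

## Rank-based ROC AUC: probability a positive outscores a negative,
## ties counting 1/2.
rocAucOracle <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

## Step-wise PR AUC by exhaustive threshold enumeration: one operating
## point per distinct score, precision held constant over each recall step.
prAucOracle <- function(scores, positive) {
  P <- sum(positive)
  pts <- t(vapply(sort(unique(scores), decreasing = TRUE), function(t) {
    pred <- scores >= t
    c(recall = sum(pred & positive) / P,
      precision = sum(pred & positive) / sum(pred))
  }, c(recall = 0, precision = 0)))
  pts <- pts[order(pts[, "recall"]), , drop = FALSE]
  sum(diff(c(0, pts[, "recall"])) * pts[, "precision"])
}

## Pearson chi-squared and Cramer's V from the definitions.
cramersVOracle <- function(tab) {
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1)))
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(chi2 = chi2, v = v, p = pchisq(chi2, df, lower.tail = FALSE))
}

## Pooled-variance two-sample Student t from the textbook formula.
studentTOracle <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = na + nb - 2))
}

## Clopper-Pearson by direct interval inversion of the binomial tails.
clopperPearsonOracle <- function(x, n, alpha = 0.05) {
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

## Chance-corrected agreement between two partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## Shared fixture: a small cohort plus its clustering-derived phenotype.
smallCohortRun <- function(seed = 1, ...) {
  cohort <- generateCohort(cohortSpec(nSamples = 30, nFeatures = 60,
                                      nValidated = 10, seed = seed, ...))
  sig <- S4Vectors::metadata(cohort$protein)$signature
  assignment <- labelClusters(wardBicluster(cohort$protein),
                              cohort$protein, sig$group1)
  cohort$assignment <- assignment
  cohort$phenotype <- predictedPhenotype(assignment)
  cohort$truth <- setNames(cohort$metadata$true_cluster,
                           cohort$metadata$sample_id)
  cohort$signature <- sig
  cohort
}
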