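#' Specify a synthetic PDX cohort
#'
#' Defines the statistical structure of a simulated PDX molecular-profiling
#' cohort: two planted sample clusters (drug-sensitive and drug-resistant)
#' separated by block differential expression of two signature feature
#' groups, pure-noise background features, and an mRNA matrix correlated
#' gene-wise with the protein matrix. Defaults emulate the dimensions of an
#' RPPA screen of 65 PDX tumors across 247 antibody probes, with a
#' validation subset of 17 tumors (10 sensitive, 7 resistant) carrying
#' observed in-vivo response labels.
#'
#' @param nSamples number of PDX samples (default 65).
#' @param nFeatures number of protein probes (default 247).
#' @param nSignatureFeatures planted signature features per biomarker group
#'   (default 5; group 1 is up in sensitive samples, group 2 up in
#'   resistant).
#' @param resistantFraction proportion of resistant samples in (0, 1)
#'   (default 25/65).
#' @param effectSize mean log2 shift of signature features between clusters
#'   (default 2).
#' @param noiseSd within-cluster standard deviation on the log2 scale
#'   (default 0.3).
#' @param proteinMrnaCorr target per-gene Pearson correlation between
#'   protein and mRNA values, in \[-1, 1\] (default 0.7).
#' @param nValidated samples flagged for in-vivo validation, stratified by
#'   cluster (default 17).
#' @param hpvPosRateResistant,hpvPosRateSensitive probability of HPV-positive
#'   status per cluster; defaults (14/25, 1/40) make roughly 14 of 15
#'   HPV-positive samples fall in the resistant cluster.
#' @param phosphoFraction fraction of background probes emulating
#'   phospho-epitopes with no mRNA counterpart (default 0.2).
#' @param unmappedSignature number of group-2 signature probes given no gene
#'   symbol (default 0), to exercise signature finalization.
#' @param seed integer seed; identical spec and seed give bit-identical
#'   output.
#' @return A `CohortSpec` object (validated list).
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nSamples = 65L, nFeatures = 247L,
                       nSignatureFeatures = 5L,
                       resistantFraction = 25 / 65,
                       effectSize = 2, noiseSd = 0.3,
                       proteinMrnaCorr = 0.7, nValidated = 17L,
                       hpvPosRateResistant = 14 / 25,
                       hpvPosRateSensitive = 1 / 40,
                       phosphoFraction = 0.2,
                       unmappedSignature = 0L,
                       seed = 1L) {
  checkScalarNumber(nSamples, "nSamples", lower = 4)
  checkScalarNumber(nFeatures, "nFeatures", lower = 2)
  checkScalarNumber(nSignatureFeatures, "nSignatureFeatures", lower = 1)
  if (2 * nSignatureFeatures > nFeatures)
    inputError("'nSignatureFeatures' x 2 must not exceed 'nFeatures'")
  checkScalarNumber(resistantFraction, "resistantFraction", 0, 1,
                    strict_lower = TRUE, strict_upper = TRUE)
  checkScalarNumber(effectSize, "effectSize", lower = 0)
  checkScalarNumber(noiseSd, "noiseSd", lower = 0, strict_lower = TRUE)
  checkScalarNumber(proteinMrnaCorr, "proteinMrnaCorr", -1, 1)
  checkScalarNumber(nValidated, "nValidated", lower = 2, upper = nSamples)
  checkScalarNumber(hpvPosRateResistant, "hpvPosRateResistant", 0, 1)
  checkScalarNumber(hpvPosRateSensitive, "hpvPosRateSensitive", 0, 1)
  checkScalarNumber(phosphoFraction, "phosphoFraction", 0, 1)
  checkScalarNumber(unmappedSignature, "unmappedSignature", 0,
                    nSignatureFeatures)
  checkScalarNumber(seed, "seed")
  structure(list(nSamples = as.integer(nSamples),
                 nFeatures = as.integer(nFeatures),
                 nSignatureFeatures = as.integer(nSignatureFeatures),
                 resistantFraction = resistantFraction,
                 effectSize = effectSize, noiseSd = noiseSd,
                 proteinMrnaCorr = proteinMrnaCorr,
                 nValidated = as.integer(nValidated),
                 hpvPosRateResistant = hpvPosRateResistant,
                 hpvPosRateSensitive = hpvPosRateSensitive,
                 phosphoFraction = phosphoFraction,
                 unmappedSignature = as.integer(unmappedSignature),
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

## Signature probes reuse the gene symbols of the field's canonical
## sensitivity/resistance markers so fixtures read naturally; surplus
## features get synthetic names.
signatureFeatureNames <- function(n_per_group) {
  sens <- c("GJA1", "CAV1", "AXL", "FN1")
  res <- c("TMEM173", "SOX2", "BRD4", "CLDN7")
  pad <- function(base, k, prefix)
    c(base, sprintf("%s%02d", prefix, seq_len(max(0L, k - length(base)))))[seq_len(k)]
  list(group1 = pad(sens, n_per_group, "SENS"),
       group2 = pad(res, n_per_group, "RESI"))
}

#' Generate a synthetic PDX cohort
#'
#' Draws a protein (RPPA-like) matrix, a matched mRNA matrix and a
#' per-sample metadata table according to a [cohortSpec()]. Group-2
#' signature features are shifted up by `effectSize` in resistant samples
#' and group-1 features up in sensitive samples; background features are
#' pure Gaussian noise. mRNA values share each gene's protein signal plus
#' independent noise scaled so the per-gene Pearson correlation is
#' approximately `proteinMrnaCorr`; a `phosphoFraction` of background probes
#' has no mRNA counterpart. Both matrices are median-centered per feature.
#'
#' @param spec a `CohortSpec`.
#' @return list with elements `protein` and `mrna` ([ProfileMatrix-class])
#'   and `metadata` (data.frame with `sample_id`, `true_cluster`,
#'   `hpv_status`, `sex`, `ajcc_stage`, `primary_site`, `age`, `validated`,
#'   `observed_response`).
#' @examples
#' cohort <- generateCohort(cohortSpec(nSamples = 20, nFeatures = 40,
#'                                     seed = 7))
#' cohort$protein
#' table(cohort$metadata$true_cluster)
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec"))
    inputError("'spec' must be created by cohortSpec()")
  withSeed(spec$seed, {
    n <- spec$nSamples
    p <- spec$nFeatures
    k <- spec$nSignatureFeatures
    sample_ids <- sprintf("PDX_%02d", seq_len(n))

    n_res <- max(1L, min(n - 1L, round(spec$resistantFraction * n)))
    resistant <- sort(sample(n, n_res))
    truth <- ifelse(seq_len(n) %in% resistant, "resistant", "sensitive")

    sig <- signatureFeatureNames(k)
    n_bg <- p - 2L * k
    bg <- sprintf("probe_%03d", seq_len(n_bg))
    ## phospho-probes: background features with no mRNA counterpart
    n_phos <- round(spec$phosphoFraction * n_bg)
    phos_idx <- if (n_phos > 0) sample(n_bg, n_phos) else integer()
    bg[phos_idx] <- sprintf("probe_%03d_pT%d", phos_idx,
                            sample(100:999, n_phos, replace = TRUE))
    features <- c(sig$group1, sig$group2, bg)

    shift <- matrix(0, nrow = p, ncol = n,
                    dimnames = list(features, sample_ids))
    shift[sig$group1, truth == "sensitive"] <- spec$effectSize
    shift[sig$group2, truth == "resistant"] <- spec$effectSize

    noise <- matrix(rnorm(p * n, sd = spec$noiseSd), nrow = p)
    protein_raw <- shift + noise

    ## gene map: background phospho-probes and (optionally) the last
    ## unmappedSignature group-2 probes lack symbols
    gene_map <- setNames(features, features)
    gene_map[bg[phos_idx]] <- NA_character_
    if (spec$unmappedSignature > 0) {
      unmapped <- rev(sig$group2)[seq_len(spec$unmappedSignature)]
      gene_map[unmapped] <- NA_character_
    }

    mapped <- features[!is.na(gene_map)]
    ## mRNA shares the gene's protein signal plus independent noise scaled
    ## (from the theoretical per-feature variance) to hit the target
    ## correlation in expectation
    f_res <- n_res / n
    var_theory <- rep(spec$noiseSd^2, p)
    names(var_theory) <- features
    var_theory[c(sig$group1, sig$group2)] <-
      spec$noiseSd^2 + spec$effectSize^2 * f_res * (1 - f_res)
    rho <- spec$proteinMrnaCorr
    mrna_raw <- matrix(0, nrow = length(mapped), ncol = n,
                       dimnames = list(unname(gene_map[mapped]), sample_ids))
    for (i in seq_along(mapped)) {
      f <- mapped[i]
      if (abs(rho) < 1e-12) {
        mrna_raw[i, ] <- rnorm(n, sd = spec$noiseSd)
      } else {
        tau <- sqrt(var_theory[[f]] * (1 - rho^2)) / abs(rho)
        mrna_raw[i, ] <- sign(rho) * (protein_raw[f, ] + rnorm(n, sd = tau))
      }
    }

    protein <- ProfileMatrix(centerRowMedians(protein_raw), "protein",
                             geneMap = gene_map,
                             metadata = list(spec = spec,
                                             signature = sig,
                                             true_cluster = setNames(truth, sample_ids)))
    mrna <- ProfileMatrix(centerRowMedians(mrna_raw), "mrna",
                          metadata = list(spec = spec))

    ## validation subset stratified by cluster (rounding favours the
    ## resistant arm, giving the canonical 10 + 7 split at the defaults)
    nv_res <- max(1L, min(n_res, round(spec$nValidated * spec$resistantFraction)))
    nv_sen <- spec$nValidated - nv_res
    val <- c(sample(which(truth == "resistant"), nv_res),
             sample(which(truth == "sensitive"), nv_sen))
    validated <- seq_len(n) %in% val

    hpv_prob <- ifelse(truth == "resistant", spec$hpvPosRateResistant,
                       spec$hpvPosRateSensitive)
    metadata <- data.frame(
      sample_id = sample_ids,
      true_cluster = truth,
      hpv_status = ifelse(runif(n) < hpv_prob, "positive", "negative"),
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.75, 0.25)),
      ajcc_stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                          prob = c(0.10, 0.15, 0.25, 0.50)),
      primary_site = sample(c("oral_cavity", "oropharynx", "larynx",
                              "hypopharynx"), n, replace = TRUE,
                            prob = c(0.40, 0.35, 0.15, 0.10)),
      age = as.integer(pmin(90, pmax(30, round(rnorm(n, mean = 62,
                                                     sd = 10))))),
      validated = validated,
      observed_response = ifelse(validated, truth, "unknown"),
      stringsAsFactors = FALSE)

    list(protein = protein, mrna = mrna, metadata = metadata)
  })
}
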