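#' Generate an external validation cohort
#'
#' Builds an mRNA expression matrix for an independent cohort with known
#' response labels whose per-gene fold changes (resistant minus sensitive)
#' agree with a supplied internal fold-change profile at a target Pearson
#' correlation, except for explicitly discordant genes whose fold-change
#' sign is flipped. The construction first draws true external fold changes
#' correlated with the internal profile (the extra spread is sized so that,
#' after per-gene sampling noise from the finite cohort, the realized
#' correlation is close to `concordance`), then assembles per-sample values
#' around them. The output matrix is median-centered per gene.
#'
#' @param internal named numeric vector of internal per-gene log2 fold
#'   changes (resistant minus sensitive), e.g. the `log2fc` column of
#'   [differentialStats()], or a [BiomarkerSet-class] whose stats are used.
#' @param nResistant,nSensitive external cohort arm sizes (defaults 4 and 7).
#' @param concordance target Pearson correlation with the internal fold
#'   changes (default 0.7).
#' @param discordantFeatures genes whose external fold-change sign is
#'   flipped relative to the internal profile (must be named in `internal`).
#' @param noiseSd per-sample within-group standard deviation (default 0.3).
#' @param seed integer seed.
#' @return list with `mrna` ([ProfileMatrix-class], genes x samples) and
#'   `labels` (named character, `"resistant"`/`"sensitive"`).
#' @examples
#' fc <- setNames(rnorm(50), paste0("G", 1:50))
#' ext <- generateExternalCohort(fc, seed = 11)
#' table(ext$labels)
#' @export
generateExternalCohort <- function(internal, nResistant = 4L,
                                   nSensitive = 7L, concordance = 0.7,
                                   discordantFeatures = character(),
                                   noiseSd = 0.3, seed = 1L) {
  if (is(internal, "BiomarkerSet"))
    internal <- setNames(internal@stats$log2fc, internal@stats$feature_id)
  if (!is.numeric(internal) || length(internal) == 0 ||
      is.null(names(internal)))
    inputError("'internal' must be a nonempty named numeric fold-change vector")
  checkScalarNumber(nResistant, "nResistant", lower = 2)
  checkScalarNumber(nSensitive, "nSensitive", lower = 2)
  checkScalarNumber(concordance, "concordance", -1, 1)
  checkScalarNumber(noiseSd, "noiseSd", lower = 0)
  if (length(discordantFeatures) &&
      !all(discordantFeatures %in% names(internal)))
    inputError("'discordantFeatures' must all be named in 'internal'")
  withSeed(seed, {
    genes <- names(internal)
    rho <- concordance
    sx <- sd(internal)
    ## sampling noise of a realized fold change in the external cohort
    se2 <- noiseSd^2 * (1 / nResistant + 1 / nSensitive)
    if (abs(rho) < 1e-12) {
      delta <- rnorm(length(genes), sd = max(sx, noiseSd))
    } else {
      b2 <- sx^2 * (1 - rho^2) / rho^2 - se2
      if (b2 < 0) {
        warning("target concordance unreachable at this noise level; ",
                "generating at the maximum achievable correlation")
        b2 <- 0
      }
      delta <- sign(rho) * (internal + rnorm(length(genes), sd = sqrt(b2)))
    }
    names(delta) <- genes
    delta[discordantFeatures] <- -delta[discordantFeatures]

    n <- as.integer(nResistant + nSensitive)
    sample_ids <- sprintf("EXT_%02d", seq_len(n))
    labels <- setNames(rep(c("resistant", "sensitive"),
                           c(nResistant, nSensitive)), sample_ids)
    group_sign <- ifelse(labels == "resistant", 0.5, -0.5)
    values <- outer(delta, group_sign) +
      matrix(rnorm(length(genes) * n, sd = noiseSd), nrow = length(genes))
    dimnames(values) <- list(genes, sample_ids)
    mrna <- ProfileMatrix(centerRowMedians(values), "mrna",
                          metadata = list(concordance = concordance,
                                          true_fc = delta,
                                          discordant = discordantFeatures))
    list(mrna = mrna, labels = labels)
  })
}

#' Generate per-cell IHC intensity records
#'
#' Simulates the per-cell mean-intensity table produced by automated
#' image quantification of an immunostained tumor section: each cell is
#' positive with probability `positiveFraction`, positives drawing
#' intensities above `intensityThreshold` and negatives below it.
#'
#' @param nCells number of cells in the section (must be >= 1).
#' @param positiveFraction probability a cell is marker-positive, in
#'   \[0, 1\].
#' @param intensityThreshold positivity threshold on mean intensity
#'   (default 1).
#' @param seed integer seed.
#' @param sectionId,marker identifiers recorded on every row.
#' @return data.frame with columns `section_id`, `cell_id`, `marker`,
#'   `mean_intensity`.
#' @seealso [scoreSection()]
#' @export
generateIHCCells <- function(nCells, positiveFraction,
                             intensityThreshold = 1, seed = 1L,
                             sectionId = "S1", marker = "CAV1") {
  checkScalarNumber(nCells, "nCells", lower = 1)
  checkScalarNumber(positiveFraction, "positiveFraction", 0, 1)
  checkScalarNumber(intensityThreshold, "intensityThreshold", lower = 0,
                    strict_lower = TRUE)
  withSeed(seed, {
    nCells <- as.integer(nCells)
    positive <- runif(nCells) < positiveFraction
    intensity <- numeric(nCells)
    ## supra-threshold lognormal tail for positives, sub-threshold for
    ## negatives; strictly > threshold counts as positive downstream
    intensity[positive] <- intensityThreshold *
      exp(abs(rnorm(sum(positive), sd = 0.5)) + 1e-6)
    intensity[!positive] <- intensityThreshold *
      exp(-abs(rnorm(sum(!positive), sd = 0.6)) - 1e-6)
    data.frame(section_id = sectionId,
               cell_id = sprintf("%s_c%05d", sectionId, seq_len(nCells)),
               marker = marker,
               mean_intensity = intensity,
               stringsAsFactors = FALSE)
  })
}
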