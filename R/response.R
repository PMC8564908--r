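#' Caliper tumor volume
#'
#' Ellipsoid approximation used throughout xenograft work:
#' volume = length x width^2 / 2, in mm^3. If width exceeds length the two
#' are swapped with a warning (the formula assumes length is the larger
#' dimension).
#'
#' @param length,width caliper dimensions in mm, both positive.
#' @return volume in mm^3 (vectorized).
#' @examples
#' tumorVolume(10, 4)  # 80
#' @export
tumorVolume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0))
    inputError("'length' and 'width' must be positive")
  swap <- width > length
  if (any(swap)) {
    warning("width > length for some measurements; swapping dimensions")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Call in-vivo drug response from growth records
#'
#' For each PDX, computes the endpoint ratio — mean drug-arm volume divided
#' by mean vehicle-arm volume on the final measurement day — and calls the
#' tumor `sensitive` when the ratio is at most 0.5 (at least a 50%
#' reduction relative to vehicle; the boundary is inclusive) and
#' `resistant` otherwise. If the two arms end on different days each arm's
#' own last day is used, with a warning.
#'
#' @param growth long-format data.frame with columns `pdx_id`, `arm`
#'   (`"vehicle"` and one drug arm), `animal`, `day`, `volume_mm3`.
#' @return data.frame with one row per PDX: `pdx_id`, `endpoint_ratio`,
#'   `endpoint_day`, `call`.
#' @examples
#' g <- generateGrowth(growthSpec(measurementCv = 0, seed = 1),
#'                     c(P1 = "sensitive", P2 = "resistant"))
#' callResponse(g)
#' @export
callResponse <- function(growth) {
  req <- c("pdx_id", "arm", "animal", "day", "volume_mm3")
  if (!is.data.frame(growth) || !all(req %in% names(growth)))
    inputError(sprintf("'growth' must contain columns: %s",
                       paste(req, collapse = ", ")))
  res <- lapply(split(growth, growth$pdx_id), function(g) {
    arms <- unique(g$arm)
    if (!"vehicle" %in% arms || length(arms) < 2)
      inputError(sprintf("PDX '%s' must have a vehicle arm and a drug arm",
                         g$pdx_id[1]))
    drug_arm <- setdiff(arms, "vehicle")[1]
    last_day <- vapply(c(vehicle = "vehicle", drug = drug_arm), function(a)
      max(g$day[g$arm == a]), numeric(1))
    if (last_day[["vehicle"]] != last_day[["drug"]])
      warning(sprintf(
        "PDX '%s': arms end on different days (%g vs %g); using each arm's last day",
        g$pdx_id[1], last_day[["drug"]], last_day[["vehicle"]]))
    endpoint_mean <- function(a, d) mean(g$volume_mm3[g$arm == a & g$day == d])
    ratio <- endpoint_mean(drug_arm, last_day[["drug"]]) /
      endpoint_mean("vehicle", last_day[["vehicle"]])
    data.frame(pdx_id = g$pdx_id[1],
               endpoint_ratio = ratio,
               endpoint_day = last_day[["drug"]],
               call = if (ratio <= 0.5) "sensitive" else "resistant",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Exact interval from Beta-distribution quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0) and
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param successes,trials integer counts, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param alpha two-sided level in (0, 1); 0.05 gives a 95% interval.
#' @return numeric `(lower, upper)` proportions.
#' @examples
#' clopperPearson(10, 10)   # lower = 0.025^(1/10), about 0.69
#' @export
clopperPearson <- function(successes, trials, alpha = 0.05) {
  checkScalarNumber(successes, "successes", lower = 0)
  checkScalarNumber(trials, "trials", lower = 1)
  checkScalarNumber(alpha, "alpha", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  if (successes > trials)
    inputError("'successes' must not exceed 'trials'")
  x <- successes
  n <- trials
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Score cluster predictions against observed responses
#'
#' Builds the 2x2 contingency of predicted versus observed drug response
#' over the validated samples, with sensitive as the positive class, and
#' derives accuracy, TPR, TNR, FPR, FNR (exact percentages; see
#' [reportRates()] for half-up integer rounding) with exact Clopper-Pearson
#' confidence intervals for accuracy, TPR and TNR.
#'
#' Rates follow the convention of in-vivo validation studies, where each
#' predicted arm is treated experimentally and scored for correctness:
#' `tp`/`fn` split the predicted-sensitive arm into confirmed and refuted
#' calls, and `tn`/`fp` split the predicted-resistant arm likewise. TPR is
#' therefore the fraction of predicted-sensitive tumors that responded
#' (`tp / (tp + fn)`), and FPR the fraction of predicted-resistant tumors
#' that in fact responded (`fp / (fp + tn)`). With 10/10 correct
#' predicted-sensitive and 5/7 correct predicted-resistant calls this gives
#' accuracy 88%, TPR 100%, TNR 71%, FPR 29%, FNR 0%.
#'
#' @param predicted named vector of `"predicted_sensitive"` /
#'   `"predicted_resistant"` (or bare `"sensitive"`/`"resistant"`).
#' @param observed named vector of `"sensitive"`/`"resistant"`; names must
#'   cover every predicted sample being evaluated (evaluation is over the
#'   intersection of names, which must be nonempty and complete).
#' @param alpha CI level (default 0.05).
#' @return A [ContingencySummary-class].
#' @examples
#' pred <- setNames(rep(c("sensitive", "resistant"), c(10, 7)),
#'                  paste0("P", 1:17))
#' obs <- setNames(rep(c("sensitive", "resistant", "sensitive"), c(10, 5, 2)),
#'                 paste0("P", 1:17))
#' evaluatePredictions(pred, obs)
#' @export
evaluatePredictions <- function(predicted, observed, alpha = 0.05) {
  if (is.null(names(predicted)) || is.null(names(observed)))
    inputError("'predicted' and 'observed' must be named by sample")
  predicted <- sub("^predicted_", "", predicted)
  ids <- intersect(names(predicted), names(observed))
  if (length(ids) == 0)
    inputError("no samples carry both a prediction and an observation")
  pred <- predicted[ids]
  obs <- observed[ids]
  if (!all(pred %in% c("sensitive", "resistant")) ||
      !all(obs %in% c("sensitive", "resistant")))
    inputError("labels must be 'sensitive' or 'resistant'")
  tp <- sum(pred == "sensitive" & obs == "sensitive")
  fn <- sum(pred == "sensitive" & obs == "resistant")
  tn <- sum(pred == "resistant" & obs == "resistant")
  fp <- sum(pred == "resistant" & obs == "sensitive")
  n_pos <- tp + fn   # predicted-sensitive arm
  n_neg <- tn + fp   # predicted-resistant arm
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  rates <- c(accuracy = pct(tp + tn, length(ids)),
             tpr = pct(tp, n_pos), tnr = pct(tn, n_neg),
             fpr = pct(fp, n_neg), fnr = pct(fn, n_pos))
  ci <- list(accuracy = clopperPearson(tp + tn, length(ids), alpha))
  ci$tpr <- if (n_pos > 0) clopperPearson(tp, n_pos, alpha) else c(NA, NA)
  ci$tnr <- if (n_neg > 0) clopperPearson(tn, n_neg, alpha) else c(NA, NA)
  new("ContingencySummary",
      counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
      rates = rates, ci = ci, alpha = alpha)
}

#' Cramer's V association between two categorical vectors
#'
#' Effect-size companion to the uncorrected Pearson chi-squared test:
#' `V = sqrt(chi2 / (n * (min(r, c) - 1)))`, with the p-value from the
#' chi-squared distribution on `(r - 1)(c - 1)` degrees of freedom. Used to
#' compare how strongly cluster membership, HPV status, stage, sex or
#' primary site associate with observed drug response.
#'
#' @param a,b equal-length vectors, each with at least 2 levels present.
#' @return data.frame with columns `cramers_v`, `chi2`, `df`, `p_value`.
#' @examples
#' cramersV(rep(c("x", "y"), each = 5), rep(c("p", "q"), each = 5))
#' @export
cramersV <- function(a, b) {
  if (length(a) != length(b))
    inputError("'a' and 'b' must have equal length")
  a <- factor(a)
  b <- factor(b)
  tab <- table(droplevels(a), droplevels(b))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    degenerateError("each factor must have at least 2 levels present")
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  n <- sum(tab)
  v <- sqrt(unname(chi$statistic) / (n * (min(dim(tab)) - 1)))
  data.frame(cramers_v = v, chi2 = unname(chi$statistic),
             df = unname(chi$parameter), p_value = chi$p.value)
}

#' Covariate association table
#'
#' Applies [cramersV()] to each metadata covariate against the observed
#' response over the validated samples, mirroring the comparison of
#' cluster-based prediction against clinical covariates.
#'
#' @param metadata metadata data.frame (see [generateCohort()]).
#' @param predicted optional named phenotype vector to include as the
#'   `biomarker_cluster` row.
#' @param covariates covariate columns to test.
#' @return data.frame with one row per covariate, sorted by descending V.
#' @export
associationTable <- function(metadata, predicted = NULL,
                             covariates = c("hpv_status", "ajcc_stage",
                                            "sex", "primary_site")) {
  val <- metadata[metadata$validated, ]
  if (nrow(val) == 0)
    inputError("no validated samples in metadata")
  obs <- setNames(val$observed_response, val$sample_id)
  rows <- list()
  if (!is.null(predicted)) {
    pred <- sub("^predicted_", "", predicted[val$sample_id])
    rows$biomarker_cluster <- cramersV(pred, obs)
  }
  for (cv in covariates) {
    if (!cv %in% names(metadata)) next
    res <- tryCatch(cramersV(val[[cv]], obs), error = function(e) NULL)
    if (!is.null(res)) rows[[cv]] <- res
  }
  if (!length(rows))
    degenerateError("no covariate could be tested")
  out <- do.call(rbind, rows)
  out <- cbind(covariate = names(rows), out)
  rownames(out) <- NULL
  out[order(-out$cramers_v), ]
}
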