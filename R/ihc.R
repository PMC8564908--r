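#' Calibrate an IHC positivity threshold on control tissue
#'
#' Represents threshold calibration against control sections: the threshold
#' is a stated quantile (default the 99th percentile) of control-cell
#' intensities, so that at most ~1% of control cells would be called
#' positive.
#'
#' @param controlIntensities numeric vector of per-cell mean intensities
#'   from control tissue.
#' @param probs quantile used as threshold (default 0.99).
#' @return numeric threshold.
#' @export
calibrateThreshold <- function(controlIntensities, probs = 0.99) {
  if (!is.numeric(controlIntensities) || !length(controlIntensities))
    inputError("'controlIntensities' must be a nonempty numeric vector")
  checkScalarNumber(probs, "probs", 0, 1)
  unname(quantile(controlIntensities, probs))
}

#' Score marker positivity of one tumor section
#'
#' Percentage of cells whose mean staining intensity exceeds the positivity
#' threshold, for one section and one marker. Scores are invariant to cell
#' order and to common rescaling of intensities and threshold.
#'
#' @param cells data.frame with columns `section_id`, `cell_id`, `marker`,
#'   `mean_intensity` for a single section and marker (at least one row;
#'   intensities must be nonnegative).
#' @param intensityThreshold positivity cutoff; cells strictly above it are
#'   positive.
#' @return data.frame with columns `section_id`, `marker`, `n_cells`,
#'   `pct_positive`, `intensity_threshold`.
#' @examples
#' cells <- data.frame(section_id = "S1", cell_id = paste0("c", 1:4),
#'                     marker = "CAV1", mean_intensity = 1:4)
#' scoreSection(cells, 2.5)  # 50%
#' @export
scoreSection <- function(cells, intensityThreshold) {
  req <- c("section_id", "cell_id", "marker", "mean_intensity")
  if (!is.data.frame(cells) || nrow(cells) == 0)
    inputError("'cells' must be a nonempty data.frame")
  if (!all(req %in% names(cells)))
    inputError(sprintf("'cells' must contain columns: %s",
                       paste(req, collapse = ", ")))
  if (any(cells$mean_intensity < 0))
    inputError("negative cell intensities are not allowed")
  if (length(unique(cells$section_id)) > 1 ||
      length(unique(cells$marker)) > 1)
    inputError("'cells' must cover a single section and a single marker")
  checkScalarNumber(intensityThreshold, "intensityThreshold", lower = 0)
  data.frame(section_id = cells$section_id[1],
             marker = cells$marker[1],
             n_cells = nrow(cells),
             pct_positive = 100 * mean(cells$mean_intensity >
                                         intensityThreshold),
             intensity_threshold = intensityThreshold,
             stringsAsFactors = FALSE)
}

#' Two-marker positivity difference metric
#'
#' The within-section difference between the percentage of cells positive
#' for the sensitivity marker (caveolin-1) and for the resistance marker
#' (Sox-2), in percentage points. Sections with a difference above the
#' cutoff are predicted complete response (CR); the boundary and below are
#' assigned to progressive disease (PD), the non-response class.
#'
#' @param cav1,sox2 single-row [scoreSection()] results for the same
#'   section.
#' @param cutoff CR/PD classification cutoff on the difference (default 0).
#' @return data.frame with columns `section_id`, `value`,
#'   `predicted_response`.
#' @examples
#' s <- function(m, p) data.frame(section_id = "S1", marker = m,
#'                                n_cells = 100, pct_positive = p,
#'                                intensity_threshold = 1)
#' differenceMetric(s("CAV1", 80), s("SOX2", 10))  # +70 -> CR
#' @export
differenceMetric <- function(cav1, sox2, cutoff = 0) {
  if (!is.data.frame(cav1) || !is.data.frame(sox2) ||
      nrow(cav1) != 1 || nrow(sox2) != 1)
    inputError("'cav1' and 'sox2' must be single-row section scores")
  if (cav1$section_id != sox2$section_id)
    inputError("section scores come from different sections")
  value <- cav1$pct_positive - sox2$pct_positive
  data.frame(section_id = cav1$section_id,
             value = value,
             predicted_response = if (value > cutoff) "CR" else "PD",
             stringsAsFactors = FALSE)
}

#' Compare marker scores between response groups
#'
#' Summarizes per-section positivity (and the two-marker difference metric,
#' when both markers are present) by response group, and tests CR versus PD
#' with a two-sided Mann-Whitney (Wilcoxon rank-sum) test per marker.
#' Groups with fewer than 2 sections are summarized but excluded from
#' testing, with a warning. The expected direction under the biology —
#' higher caveolin-1 and lower Sox-2 in responders — is flagged per marker.
#'
#' @param scores data.frame of stacked [scoreSection()] rows plus a
#'   `response_group` column (`"CR"`, `"PD"`, `"control"`).
#' @return list with `summary` (per group x marker medians and ranges),
#'   `tests` (CR-vs-PD p-values and direction flags), and `difference`
#'   (per-section difference metric, when computable).
#' @export
compareGroups <- function(scores) {
  req <- c("section_id", "marker", "pct_positive", "response_group")
  if (!is.data.frame(scores) || !all(req %in% names(scores)))
    inputError(sprintf("'scores' must contain columns: %s",
                       paste(req, collapse = ", ")))
  summ <- do.call(rbind, lapply(
    split(scores, list(scores$response_group, scores$marker), drop = TRUE),
    function(d) data.frame(response_group = d$response_group[1],
                           marker = d$marker[1], n_sections = nrow(d),
                           median_pct = median(d$pct_positive),
                           min_pct = min(d$pct_positive),
                           max_pct = max(d$pct_positive),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL

  diff_df <- NULL
  wide <- scores[scores$marker %in% c("CAV1", "SOX2"), , drop = FALSE]
  if (length(unique(wide$marker)) == 2) {
    per_sec <- split(wide, wide$section_id)
    rows <- lapply(per_sec, function(d) {
      if (!all(c("CAV1", "SOX2") %in% d$marker)) return(NULL)
      dm <- differenceMetric(d[d$marker == "CAV1", ][1, ],
                             d[d$marker == "SOX2", ][1, ])
      dm$response_group <- d$response_group[1]
      dm
    })
    diff_df <- do.call(rbind, rows)
    if (!is.null(diff_df)) rownames(diff_df) <- NULL
  }

  test_one <- function(vals_cr, vals_pd, label, expect_higher_in_cr) {
    if (length(vals_cr) < 2 || length(vals_pd) < 2) {
      warning(sprintf("'%s': a group has fewer than 2 sections; p omitted",
                      label))
      p <- NA_real_
    } else {
      p <- suppressWarnings(wilcox.test(vals_cr, vals_pd)$p.value)
    }
    observed_higher_in_cr <- median(vals_cr) > median(vals_pd)
    data.frame(comparison = label, p_value = p,
               direction_expected = expect_higher_in_cr,
               direction_observed = observed_higher_in_cr,
               direction_consistent =
                 observed_higher_in_cr == expect_higher_in_cr,
               stringsAsFactors = FALSE)
  }
  tests <- list()
  for (mk in unique(scores$marker)) {
    cr <- scores$pct_positive[scores$marker == mk &
                                scores$response_group == "CR"]
    pd <- scores$pct_positive[scores$marker == mk &
                                scores$response_group == "PD"]
    if (!length(cr) || !length(pd)) next
    tests[[mk]] <- test_one(cr, pd, mk, expect_higher_in_cr = mk != "SOX2")
  }
  if (!is.null(diff_df)) {
    cr <- diff_df$value[diff_df$response_group == "CR"]
    pd <- diff_df$value[diff_df$response_group == "PD"]
    if (length(cr) && length(pd))
      tests$difference <- test_one(cr, pd, "CAV1-SOX2 difference", TRUE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(tests)) rownames(tests) <- NULL
  list(summary = summ, tests = tests, difference = diff_df)
}
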