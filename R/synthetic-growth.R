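#' Specify synthetic tumor-growth experiments
#'
#' Parameters of the simulated two-arm (vehicle vs drug) growth experiment
#' used to derive in-vivo response calls. Growth is exponential from a
#' common starting volume with lognormal caliper noise; the drug acts
#' multiplicatively on the growth rate, with separate multipliers for truly
#' sensitive and truly resistant tumors. The constructor validates that, in
#' expectation, sensitive tumors end at no more than half the vehicle
#' endpoint volume and resistant tumors above it, so the 50%-reduction
#' response rule is meaningful.
#'
#' @param initialVolume starting tumor volume in mm^3 (default 200, the
#'   volume at which treatment starts).
#' @param nAnimalsPerArm animals per arm (default 3; typically 2-3).
#' @param measurementDays days on which volumes are measured (default
#'   twice-weekly over a 21-day course).
#' @param vehicleGrowthRate per-day exponential growth rate under vehicle
#'   (default 0.08).
#' @param sensitiveEffect growth-rate multiplier under drug for sensitive
#'   tumors (default 0: stasis; negative values mean regression).
#' @param resistantEffect growth-rate multiplier under drug for resistant
#'   tumors (default 0.85: mild slowing).
#' @param measurementCv coefficient of variation of volume measurement
#'   noise (default 0.1).
#' @param seed integer seed.
#' @return A `GrowthSpec` object (validated list).
#' @seealso [generateGrowth()], [callResponse()]
#' @export
growthSpec <- function(initialVolume = 200, nAnimalsPerArm = 3L,
                       measurementDays = c(0, 4, 7, 11, 14, 18, 21),
                       vehicleGrowthRate = 0.08,
                       sensitiveEffect = 0, resistantEffect = 0.85,
                       measurementCv = 0.1, seed = 1L) {
  checkScalarNumber(initialVolume, "initialVolume", lower = 0,
                    strict_lower = TRUE)
  checkScalarNumber(nAnimalsPerArm, "nAnimalsPerArm", lower = 1)
  if (!is.numeric(measurementDays) || length(measurementDays) < 2 ||
      is.unsorted(measurementDays, strictly = TRUE))
    inputError("'measurementDays' must be >= 2 strictly increasing days")
  checkScalarNumber(vehicleGrowthRate, "vehicleGrowthRate")
  checkScalarNumber(sensitiveEffect, "sensitiveEffect")
  checkScalarNumber(resistantEffect, "resistantEffect")
  checkScalarNumber(measurementCv, "measurementCv", lower = 0)
  checkScalarNumber(seed, "seed")
  endpoint <- max(measurementDays) - min(measurementDays)
  ratio_sens <- exp(vehicleGrowthRate * (sensitiveEffect - 1) * endpoint)
  ratio_res <- exp(vehicleGrowthRate * (resistantEffect - 1) * endpoint)
  if (ratio_sens > 0.5)
    inputError(sprintf(
      "'sensitiveEffect' gives expected endpoint ratio %.2f > 0.5", ratio_sens))
  if (ratio_res <= 0.5)
    inputError(sprintf(
      "'resistantEffect' gives expected endpoint ratio %.2f <= 0.5", ratio_res))
  structure(list(initialVolume = initialVolume,
                 nAnimalsPerArm = as.integer(nAnimalsPerArm),
                 measurementDays = as.numeric(measurementDays),
                 vehicleGrowthRate = vehicleGrowthRate,
                 sensitiveEffect = sensitiveEffect,
                 resistantEffect = resistantEffect,
                 measurementCv = measurementCv,
                 seed = as.integer(seed)),
            class = "GrowthSpec")
}

#' Generate synthetic tumor-growth records
#'
#' Simulates per-animal volume trajectories for vehicle and drug arms of
#' each PDX, according to the planted sensitivity labels. The long-format
#' output feeds directly into [callResponse()].
#'
#' @param spec a [growthSpec()].
#' @param truth named character vector of per-PDX labels,
#'   `"sensitive"`/`"resistant"`.
#' @return data.frame with columns `pdx_id`, `arm` (`"vehicle"`/`"drug"`),
#'   `animal`, `day`, `volume_mm3`.
#' @examples
#' g <- generateGrowth(growthSpec(seed = 3),
#'                     c(P1 = "sensitive", P2 = "resistant"))
#' head(g)
#' @export
generateGrowth <- function(spec, truth) {
  if (!inherits(spec, "GrowthSpec"))
    inputError("'spec' must be created by growthSpec()")
  if (length(truth) == 0)
    inputError("'truth' labels must be nonempty")
  if (is.null(names(truth)) || anyDuplicated(names(truth)))
    inputError("'truth' must be uniquely named by PDX ID")
  if (!all(truth %in% c("sensitive", "resistant")))
    inputError("'truth' values must be 'sensitive' or 'resistant'")
  withSeed(spec$seed, {
    sdlog <- sqrt(log(1 + spec$measurementCv^2))
    days <- spec$measurementDays - min(spec$measurementDays)
    rows <- lapply(names(truth), function(pdx) {
      rates <- c(vehicle = spec$vehicleGrowthRate,
                 drug = spec$vehicleGrowthRate *
                   if (truth[[pdx]] == "sensitive") spec$sensitiveEffect
                   else spec$resistantEffect)
      do.call(rbind, lapply(names(rates), function(arm) {
        do.call(rbind, lapply(seq_len(spec$nAnimalsPerArm), function(a) {
          mu <- spec$initialVolume * exp(rates[[arm]] * days)
          noise <- if (spec$measurementCv > 0)
            rlnorm(length(days), meanlog = -sdlog^2 / 2, sdlog = sdlog)
          else rep(1, length(days))
          data.frame(pdx_id = pdx, arm = arm,
                     animal = sprintf("%s_%s_%d", pdx, arm, a),
                     day = spec$measurementDays,
                     volume_mm3 = mu * noise,
                     stringsAsFactors = FALSE)
        }))
      }))
    })
    do.call(rbind, rows)
  })
}
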