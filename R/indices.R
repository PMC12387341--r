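# Closed-form physiological stress indices.
#
# Electrolyte leakage (EL) expresses the conductivity of the bathing
# solution of leaf disks relative to a fully lysed (autoclaved) positive
# control; its heat-stress index ELI contrasts heat-stressed and unstressed
# leakage.  Relative water content (RWC) scales a leaf's fresh weight
# between its dry and fully turgid weights.  The Evans-blue inhibition
# index scales the 500 nm absorbance of extracted dye between an unstressed
# negative control and a boiled positive control.

#' Electrolyte leakage
#'
#' Fraction of total leachable electrolytes released by a leaf-disk sample:
#' the conductivity of its bathing solution divided by the conductivity
#' obtained from autoclaved (fully lysed) disks of the same sample.
#'
#' @param cond_treatment conductivity of the treated sample, uS/cm.
#' @param cond_positive_control conductivity of the autoclaved positive
#'   control, uS/cm; must be positive.
#' @return Leakage as a non-negative fraction (values above 1 are possible
#'   with measurement error and are returned as-is).
#' @export
#' @examples
#' electrolyte_leakage(50, 200)   # 0.25
electrolyte_leakage <- function(cond_treatment, cond_positive_control) {
  stopifnot(is.numeric(cond_treatment), is.numeric(cond_positive_control))
  if (any(!is.finite(cond_positive_control)) ||
      any(cond_positive_control <= 0))
    stopf("positive-control conductivity must be > 0")
  if (any(!is.finite(cond_treatment)) || any(cond_treatment < 0))
    stopf("treatment conductivity must be >= 0")
  cond_treatment / cond_positive_control
}

#' Electrolyte leakage index (ELI)
#'
#' Relative increase of electrolyte leakage under heat stress over the
#' unstressed control: \code{(el_h - el_c) / el_c}.  Low values indicate
#' heat-stable membranes.  The index can come out negative when the heated
#' sample leaks less than the control; such values are reported with a
#' warning rather than clamped, since zeroing them would bias the
#' downstream standardization.
#'
#' @param el_h electrolyte leakage under heat stress (fraction).
#' @param el_c electrolyte leakage of the negative control (fraction,
#'   positive).
#' @return The dimensionless index.
#' @export
#' @examples
#' eli(0.5, 0.1)   # 4
eli <- function(el_h, el_c) {
  stopifnot(is.numeric(el_h), is.numeric(el_c))
  if (any(!is.finite(el_c)) || any(el_c <= 0))
    stopf("control electrolyte leakage must be > 0")
  if (any(!is.finite(el_h)) || any(el_h < 0))
    stopf("heat-stress electrolyte leakage must be >= 0")
  out <- (el_h - el_c) / el_c
  if (any(out < 0))
    warnf("negative ELI: heat-stressed sample leaks less than control")
  out
}

#' Relative water content (RWC)
#'
#' \code{100 * (fresh - dry) / (turgid - dry)}, the standard water-retention
#' index of a detached leaf.  Values are not clamped to [0, 100]: readings
#' outside that range indicate weighing problems and are surfaced with a
#' data-quality warning instead of being hidden.
#'
#' @param fresh fresh weight, g.
#' @param turgid fully rehydrated (turgid) weight, g; must exceed
#'   \code{dry}.
#' @param dry oven-dry weight, g.
#' @return RWC in percent.
#' @export
#' @examples
#' rwc(0.80, 1.00, 0.30)   # 71.43
rwc <- function(fresh, turgid, dry) {
  stopifnot(is.numeric(fresh), is.numeric(turgid), is.numeric(dry))
  if (any(!is.finite(c(fresh, turgid, dry))))
    stopf("weights must be finite")
  if (any(turgid <= dry))
    stopf("turgid weight must exceed dry weight")
  if (any(fresh <= 0))
    stopf("fresh weight must be positive")
  out <- 100 * (fresh - dry) / (turgid - dry)
  if (any(out < 0 | out > 100))
    warnf("RWC outside [0, 100]: check fresh/turgid/dry weights")
  out
}

#' RWC over a dehydration time course
#'
#' Applies [rwc()] to each time point of a dehydration-shock series in which
#' the fresh weight of a detached leaf is followed over time (typically six
#' hours) against fixed turgid and dry weights.
#'
#' @param time_min sampling times in minutes, strictly increasing, starting
#'   at 0.
#' @param fresh fresh weights at each time, g.
#' @param turgid,dry turgid and dry weights, g.
#' @return A data frame with columns \code{time_min} and \code{rwc}.
#' @export
rwc_time_course <- function(time_min, fresh, turgid, dry) {
  stopifnot(length(time_min) == length(fresh), length(time_min) >= 1L)
  if (time_min[1] != 0) stopf("dehydration series must start at time 0")
  if (any(diff(time_min) <= 0)) stopf("times must be strictly increasing")
  vals <- vapply(seq_along(fresh), function(i) {
    tryCatch(rwc(fresh[i], turgid, dry),
             error = function(e)
               stopf("time point %g min: %s", time_min[i], conditionMessage(e)))
  }, numeric(1))
  data.frame(time_min = time_min, rwc = vals)
}

#' Evans-blue inhibition index
#'
#' Scales the 500 nm absorbance of Evans-blue dye extracted from a
#' heat-stressed sample between the negative control (intact tissue, no
#' uptake above baseline) and a boiled positive control (complete cell
#' death): \code{100 * (abs_h - abs_nc) / (abs_pc - abs_nc)}.
#'
#' @param abs_h absorbance of the heat-stressed sample.
#' @param abs_nc absorbance of the negative control.
#' @param abs_pc absorbance of the boiled positive control; must exceed
#'   \code{abs_nc}.
#' @return Percent cell death relative to the boiled control.
#' @export
#' @examples
#' inhibition_index(0.6, 0.2, 1.0)   # 50
inhibition_index <- function(abs_h, abs_nc, abs_pc) {
  stopifnot(is.numeric(abs_h), is.numeric(abs_nc), is.numeric(abs_pc))
  if (any(!is.finite(c(abs_h, abs_nc, abs_pc))))
    stopf("absorbances must be finite")
  if (any(abs_pc <= abs_nc))
    stopf("positive control absorbance must exceed negative control")
  100 * (abs_h - abs_nc) / (abs_pc - abs_nc)
}

#' Survival rate
#'
#' @param alive number of surviving plants.
#' @param total number of plants treated; must be positive.
#' @return Percent survival.
#' @export
#' @examples
#' survival_rate(1, 12)   # 8.33
survival_rate <- function(alive, total) {
  if (!is_count(alive) || !is_count(total))
    stopf("counts must be non-negative integers")
  if (total == 0) stopf("total count must be positive")
  if (alive > total) stopf("alive cannot exceed total")
  100 * alive / total
}

#' Aggregate per-replicate index values by species
#'
#' Computes each index per replicate first, then summarizes as mean and
#' sample standard deviation per species, matching the replicate convention
#' of the assays (n = 3).
#'
#' @param species character vector of species codes, one per replicate.
#' @param value numeric per-replicate index values.
#' @param index name of the index being summarized (stored in the output).
#' @return A tidy data frame with columns \code{species}, \code{index},
#'   \code{mean}, \code{sd}, \code{n}, ordered by first appearance.
#' @export
aggregate_replicates <- function(species, value, index = "index") {
  stopifnot(length(species) == length(value), is.numeric(value))
  codes <- unique(species)
  out <- do.call(rbind, lapply(codes, function(code) {
    v <- value[species == code]
    data.frame(species = code, index = index, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
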