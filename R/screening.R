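# Pre-screening of tolerance candidates from per-species (RWC, ELI) pairs.
#
# Both indices are z-standardized across the cohort and plotted with
# standardized ELI on the x axis and standardized RWC on the y axis.
# Quadrant II (low z-ELI, high z-RWC) is the tolerant corner; quadrant IV
# (high z-ELI, low z-RWC) the sensitive one.  Candidates are species lying
# close to the centroid of previously validated tolerant reference species.

#' Z-standardize per-species (RWC, ELI) pairs
#'
#' Standardizes each axis to mean 0 and sample (n-1) standard deviation 1
#' across the supplied cohort.  The cohort defines the standardization:
#' passing a different set of species changes every z-score.
#'
#' @param pairs data frame with columns \code{species}, \code{rwc},
#'   \code{eli}; at least two rows, finite values.
#' @return Data frame with columns \code{species}, \code{z_rwc},
#'   \code{z_eli}, in input order.
#' @export
standardize <- function(pairs) {
  need <- c("species", "rwc", "eli")
  if (!all(need %in% names(pairs)))
    stopf("pairs must have columns %s", paste(need, collapse = ", "))
  if (nrow(pairs) < 2L) stopf("need at least 2 species to standardize")
  if (any(!is.finite(pairs$rwc)) || any(!is.finite(pairs$eli)))
    stopf("RWC and ELI must be finite")
  sd_r <- stats::sd(pairs$rwc); sd_e <- stats::sd(pairs$eli)
  if (sd_r == 0 || sd_e == 0)
    stopf("degenerate cohort: zero standard deviation on an axis")
  data.frame(species = pairs$species,
             z_rwc = (pairs$rwc - mean(pairs$rwc)) / sd_r,
             z_eli = (pairs$eli - mean(pairs$eli)) / sd_e,
             stringsAsFactors = FALSE)
}

#' Quadrant of a standardized (ELI, RWC) point
#'
#' With z-ELI on the x axis and z-RWC on the y axis: quadrant II means
#' \code{z_eli < 0 & z_rwc > 0} (tolerant corner), quadrant IV means
#' \code{z_eli > 0 & z_rwc < 0} (sensitive corner), I both positive, III
#' both negative.  A coordinate exactly at 0 yields \code{"boundary"} —
#' the quadrant definitions use strict inequalities and exact zeros are
#' never silently binned.
#'
#' @param z_rwc,z_eli standardized coordinates (vectorized).
#' @return Character vector of \code{"I"}, \code{"II"}, \code{"III"},
#'   \code{"IV"} or \code{"boundary"}.
#' @export
quadrant <- function(z_rwc, z_eli) {
  stopifnot(length(z_rwc) == length(z_eli))
  out <- character(length(z_rwc))
  out[z_eli > 0 & z_rwc > 0] <- "I"
  out[z_eli < 0 & z_rwc > 0] <- "II"
  out[z_eli < 0 & z_rwc < 0] <- "III"
  out[z_eli > 0 & z_rwc < 0] <- "IV"
  out[z_eli == 0 | z_rwc == 0] <- "boundary"
  out
}

ref_centroid <- function(std, references) {
  miss <- setdiff(references, std$species)
  if (length(miss))
    stopf("reference species not in cohort: %s", paste(miss, collapse = ", "))
  i <- std$species %in% references
  c(z_rwc = mean(std$z_rwc[i]), z_eli = mean(std$z_eli[i]))
}

#' Select tolerance candidates near the reference centroid
#'
#' Computes the centroid of the validated tolerant reference species in
#' standardized coordinates and returns all non-reference species within
#' \code{radius} (Euclidean distance), sorted by distance; ties are broken
#' by species code.  An alternative k-nearest mode returns the \code{k}
#' nearest non-reference species regardless of distance.
#'
#' @param std standardized cohort from [standardize()].
#' @param references character vector of reference species codes; must be a
#'   non-empty subset of the cohort.
#' @param radius selection radius in standardized units (default 1).
#' @param k if non-NULL, select the k nearest species instead of using the
#'   radius.
#' @return Data frame with columns \code{species} and \code{distance}.
#' @export
select_candidates <- function(std, references, radius = 1.0, k = NULL) {
  if (!length(references)) stopf("reference set must be non-empty")
  cen <- ref_centroid(std, references)
  rest <- std[!(std$species %in% references), , drop = FALSE]
  d <- sqrt((rest$z_rwc - cen["z_rwc"])^2 + (rest$z_eli - cen["z_eli"])^2)
  ord <- order(d, rest$species)
  res <- data.frame(species = rest$species[ord], distance = d[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(k)) {
    if (!is_count(k)) stopf("k must be a non-negative integer")
    res[seq_len(min(k, nrow(res))), , drop = FALSE]
  } else {
    res[res$distance <= radius, , drop = FALSE]
  }
}

#' Classify a cohort for drought-heat tolerance
#'
#' Full pre-screening rule set: reference species are labelled
#' \code{tolerant}; quadrant IV species \code{sensitive}; quadrant II
#' species within \code{radius} of the reference centroid
#' \code{candidate}; everything else (including boundary points)
#' \code{unclassified}.
#'
#' @param pairs data frame with columns \code{species}, \code{rwc},
#'   \code{eli} (raw units; standardization happens internally).
#' @inheritParams select_candidates
#' @return An object of class \code{"tolerance_screen"}: a data frame with
#'   columns \code{species}, \code{rwc}, \code{eli}, \code{z_rwc},
#'   \code{z_eli}, \code{quadrant}, \code{class},
#'   \code{distance_to_reference}, plus attributes recording the cohort,
#'   references and radius used.
#' @export
#' @examples
#' pairs <- data.frame(
#'   species = c("Co", "Qm", "Qg", "Aj"),
#'   rwc = c(78.2, 76.8, 72.9, 35.6),
#'   eli = c(1.78, 2.94, 2.68, 8.00))
#' classify(pairs, references = c("Co", "Qm", "Qg"))
classify <- function(pairs, references, radius = 1.0, k = NULL) {
  std <- standardize(pairs)
  cen <- ref_centroid(std, references)
  quad <- quadrant(std$z_rwc, std$z_eli)
  dist <- sqrt((std$z_rwc - cen["z_rwc"])^2 + (std$z_eli - cen["z_eli"])^2)
  sel <- select_candidates(std, references, radius = radius, k = k)
  cls <- rep("unclassified", nrow(std))
  cls[quad == "IV"] <- "sensitive"
  cls[quad == "II" & std$species %in% sel$species] <- "candidate"
  cls[std$species %in% references] <- "tolerant"
  out <- data.frame(species = std$species, rwc = pairs$rwc, eli = pairs$eli,
                    z_rwc = std$z_rwc, z_eli = std$z_eli, quadrant = quad,
                    class = cls, distance_to_reference = dist,
                    stringsAsFactors = FALSE)
  structure(out, references = references, radius = radius,
            cohort = std$species, class = c("tolerance_screen", "data.frame"))
}

#' @export
print.tolerance_screen <- function(x, ...) {
  cat(sprintf("Tolerance screen: %d species, references %s, radius %.2f\n",
              nrow(x), paste(attr(x, "references"), collapse = ","),
              attr(x, "radius")))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Stage-response report
#'
#' Combines per-species drought (RWC), heat (ELI) and recovery summaries
#' into one qualitative stage-response table: each species gets one row per
#' stage with its indicator value and a tolerant/sensitive-style label
#' derived from configurable thresholds.  Species missing a stage are
#' flagged incomplete for that stage rather than dropped.
#'
#' @param rwc_summary data frame with columns \code{species}, \code{rwc}.
#' @param eli_summary data frame with columns \code{species}, \code{eli}.
#' @param recovery_summary data frame with columns \code{species},
#'   \code{recovery_class} (\code{"cleared"}, \code{"declining"} or
#'   \code{"persistent"}, see [recovery_summary()]).
#' @param rwc_min RWC (percent) at or above which drought response is
#'   labelled water-retaining (default 60).
#' @param eli_max ELI at or below which heat response is labelled
#'   membrane-stable (default 4).
#' @return Data frame with columns \code{species}, \code{stage},
#'   \code{indicator}, \code{value}, \code{label}, \code{incomplete}.
#' @export
stage_report <- function(rwc_summary, eli_summary, recovery_summary,
                         rwc_min = 60, eli_max = 4) {
  species <- unique(c(rwc_summary$species, eli_summary$species,
                      recovery_summary$species))
  row1 <- function(sp, stage, indicator, value, label) {
    data.frame(species = sp, stage = stage, indicator = indicator,
               value = value, label = label, incomplete = is.na(value) &
                 is.na(label), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(species, function(sp) {
    r <- rwc_summary$rwc[match(sp, rwc_summary$species)]
    e <- eli_summary$eli[match(sp, eli_summary$species)]
    rc <- recovery_summary$recovery_class[match(sp, recovery_summary$species)]
    rbind(
      row1(sp, "drought", "rwc", r,
           if (is.na(r)) NA_character_
           else if (r >= rwc_min) "high water retention (stable RWC)"
           else "rapid RWC decline"),
      row1(sp, "heat", "eli", e,
           if (is.na(e)) NA_character_
           else if (e <= eli_max) "low membrane damage"
           else "high electrolyte leakage"),
      row1(sp, "recovery", "recovery_class", NA_real_,
           if (is.na(rc)) NA_character_
           else if (rc %in% c("cleared", "declining"))
             "ROS scavenging, tissue restoration"
           else "persistent damage")
    )
  }))
  # recovery rows carry a categorical indicator; completeness follows label
  out$incomplete <- is.na(out$label)
  rownames(out) <- NULL
  out
}
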