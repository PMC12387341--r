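# Summaries of DAB (H2O2) time series over the 14-phase stress/recovery
# schedule: stress-phase peaks, sustained clearance of hydrogen peroxide
# during recovery, net recovery, species ranking and profile clustering.

#' The experimental phase schedule
#'
#' The 14 phases A-N: A = untreated control, B = hydrogen-peroxide staining
#' positive control, C = drought, D-G = 45 C heat for 30/60/90/120 min on
#' top of drought, H-N = recovery at 25 C for 15/30/60/90/120/240/480 min.
#' Phase B is a staining control, not part of the stress/recovery
#' trajectory, and is excluded from kinetics summaries.
#'
#' @return Data frame with columns \code{phase}, \code{condition},
#'   \code{minutes} (NA for A-C).
#' @export
phase_schedule <- function() {
  data.frame(
    phase = LETTERS[1:14],
    condition = c("control", "h2o2_control", "drought", rep("heat", 4),
                  rep("recovery", 7)),
    minutes = c(NA, NA, NA, 30, 60, 90, 120, 15, 30, 60, 90, 120, 240, 480),
    stringsAsFactors = FALSE
  )
}

recovery_phases <- function() LETTERS[8:14]  # H..N

# Pull one species' series from a long (species, phase, mean, sd) table.
series_of <- function(table, species) {
  s <- table[table$species == species, , drop = FALSE]
  if (!nrow(s)) stopf("species '%s' not in table", species)
  s[match(phase_schedule()$phase, s$phase), , drop = FALSE]
}

#' Extreme cell over selected phases
#'
#' Scans the requested (species x phase) cells of a long DAB table for the
#' maximal or minimal mean.  Ties are broken by table order, then phase
#' order.
#'
#' @param table long data frame with columns \code{species}, \code{phase},
#'   \code{mean} (e.g. [load_dab_table()] or [quantify_batch()] output).
#' @param phases character vector of phase labels to scan; non-empty.
#' @param mode \code{"max"} or \code{"min"}.
#' @return A list with \code{species}, \code{phase}, \code{value}.
#' @export
#' @examples
#' phase_extreme(load_dab_table(), "E", "max")   # Csin, 116.6
phase_extreme <- function(table, phases, mode = c("max", "min")) {
  mode <- match.arg(mode)
  if (!length(phases)) stopf("phase subset must be non-empty")
  if (!all(phases %in% phase_schedule()$phase))
    stopf("unknown phase label")
  sub <- table[table$phase %in% phases, , drop = FALSE]
  if (!nrow(sub)) stopf("no cells for the requested phases")
  # stable tie-break: keep table order, order phases within it
  sub <- sub[order(match(sub$phase, phase_schedule()$phase)), , drop = FALSE]
  sub <- sub[order(match(sub$species, unique(table$species))), , drop = FALSE]
  i <- if (mode == "max") which.max(sub$mean) else which.min(sub$mean)
  list(species = sub$species[i], phase = sub$phase[i], value = sub$mean[i])
}

#' Sustained clearance time of hydrogen peroxide
#'
#' First recovery phase (H..N) at which the series' mean falls to the
#' control baseline plus \code{margin} baseline SDs \emph{and stays there}
#' through all later phases.  The sustained requirement makes the rule
#' robust to the transient mid-recovery rises these series show.  Returns
#' \code{NA} if the series never clears.
#'
#' @param series data frame with columns \code{phase}, \code{mean},
#'   \code{sd} for one species (all 14 phases).
#' @param baseline_mean,baseline_sd clearance baseline; defaults to the
#'   series' own phase-A (control) cell.
#' @param margin baseline SD multiplier (default 2): "undetectable" is
#'   operationalized as within mean + margin * SD of the control.
#' @return A list with \code{phase} (label or NA), \code{minutes} (recovery
#'   minutes or NA) and \code{threshold}.
#' @export
clearance_time <- function(series, baseline_mean = NULL, baseline_sd = NULL,
                           margin = 2.0) {
  sched <- phase_schedule()
  if (is.null(baseline_mean))
    baseline_mean <- series$mean[match("A", series$phase)]
  if (is.null(baseline_sd))
    baseline_sd <- series$sd[match("A", series$phase)]
  if (is.na(baseline_mean) || baseline_mean < 0)
    stopf("baseline mean must be a non-negative number")
  if (is.null(baseline_sd) || is.na(baseline_sd)) baseline_sd <- 0
  thr <- baseline_mean + margin * baseline_sd
  rec <- recovery_phases()
  m <- series$mean[match(rec, series$phase)]
  if (any(is.na(m))) stopf("recovery phases H..N must all be present")
  ok <- m <= thr
  sustained <- rev(cumprod(rev(ok))) == 1  # ok from here to the end
  i <- which(sustained)[1]
  if (is.na(i))
    return(list(phase = NA_character_, minutes = NA_real_, threshold = thr))
  list(phase = rec[i],
       minutes = sched$minutes[match(rec[i], sched$phase)],
       threshold = thr)
}

#' Net recovery of a DAB series
#'
#' Mean at the first recovery phase (H) minus mean at the last (N);
#' positive values mean a net decline of H2O2 during recovery.
#'
#' @inheritParams clearance_time
#' @return Saturation units (0-255 scale).
#' @export
net_recovery <- function(series) {
  h <- series$mean[match("H", series$phase)]
  n <- series$mean[match("N", series$phase)]
  if (is.na(h) || is.na(n)) stopf("phases H and N must be present")
  h - n
}

#' Rank species by recovery endpoint
#'
#' Species with less residual H2O2 at the end of recovery (phase N) rank
#' first; ties are broken by larger net recovery, then species code.
#' Species with incomplete series are excluded with a warning.
#'
#' @inheritParams phase_extreme
#' @return Data frame with columns \code{species}, \code{endpoint_n},
#'   \code{net_recovery}, \code{rank}, ordered best first.
#' @export
rank_species <- function(table) {
  species <- unique(table$species)
  rows <- lapply(species, function(sp) {
    s <- series_of(table, sp)
    if (any(is.na(s$mean))) return(NULL)
    data.frame(species = sp,
               endpoint_n = s$mean[match("N", s$phase)],
               net_recovery = net_recovery(s), stringsAsFactors = FALSE)
  })
  dropped <- species[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warnf("excluding species with incomplete series: %s",
          paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no complete series to rank")
  out <- out[order(out$endpoint_n, -out$net_recovery, out$species), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize one species' recovery kinetics
#'
#' @inheritParams phase_extreme
#' @param species species code present in \code{table}.
#' @param margin clearance margin, see [clearance_time()].
#' @return A list with the peak stress phase/value (over C-G), the
#'   clearance phase and minutes (or NA), the net change H minus N, and a
#'   \code{recovery_class}: \code{"cleared"} (reaches baseline),
#'   \code{"declining"} (net decline without clearance) or
#'   \code{"persistent"}.
#' @export
recovery_summary <- function(table, species, margin = 2.0) {
  s <- series_of(table, species)
  stress <- c("C", "D", "E", "F", "G")
  pk <- phase_extreme(s, stress, "max")
  cl <- clearance_time(s, margin = margin)
  net <- net_recovery(s)
  cls <- if (!is.na(cl$phase)) "cleared" else if (net > 0) "declining"
         else "persistent"
  list(species = species, peak_phase = pk$phase, peak_value = pk$value,
       clearance_phase = cl$phase, clearance_minutes = cl$minutes,
       net_change_HN = net, recovery_class = cls)
}

#' Cluster species by recovery profile shape
#'
#' Agglomerative clustering (Euclidean distance, average linkage) on
#' per-series z-normalized phase vectors, so that profile \emph{shape}
#' rather than absolute staining level drives the grouping.  Phase B (the
#' staining control) is excluded.  Deterministic given input order.
#'
#' @inheritParams phase_extreme
#' @param k number of clusters (default 2: clearing vs persistent).
#' @return Named integer vector of cluster labels, one per species.
#' @export
cluster_profiles <- function(table, k = 2L) {
  species <- unique(table$species)
  if (!is_count(k) || k < 1 || k > length(species))
    stopf("k must be between 1 and the number of species")
  phases <- setdiff(phase_schedule()$phase, "B")
  mat <- t(vapply(species, function(sp) {
    s <- series_of(table, sp)
    v <- s$mean[match(phases, s$phase)]
    if (any(is.na(v))) stopf("species '%s' has an incomplete series", sp)
    sdv <- stats::sd(v)
    if (sdv == 0) v - mean(v) else (v - mean(v)) / sdv
  }, numeric(length(phases))))
  rownames(mat) <- species
  hc <- stats::hclust(stats::dist(mat), method = "average")
  stats::cutree(hc, k = k)
}

#' Export min-max normalized tolerance axes for radar plots
#'
#' Per-species summary axes rescaled to [0, 1] and oriented so that 1 is
#' always the more tolerant end.  Default axes: low recovery endpoint
#' (phase N), large net recovery, low stress peak, and fast clearance
#' (species that never clear get the slowest-possible time).  Constant
#' axes carry no contrast and are dropped with a warning.
#'
#' @inheritParams phase_extreme
#' @param margin clearance margin, see [clearance_time()].
#' @return Data frame with column \code{species} plus one column per
#'   retained axis, values in [0, 1].
#' @export
radar_export <- function(table, margin = 2.0) {
  species <- unique(table$species)
  summ <- lapply(species, function(sp) recovery_summary(table, sp, margin))
  worst_clear <- max(phase_schedule()$minutes, na.rm = TRUE) +
    1  # sentinel: slower than any real clearance
  raw <- data.frame(
    species = species,
    # orientation applied via sign so that larger = more tolerant
    low_endpoint = -vapply(species, function(sp)
      series_of(table, sp)$mean[14], numeric(1)),
    net_recovery = vapply(summ, `[[`, numeric(1), "net_change_HN"),
    low_peak = -vapply(summ, `[[`, numeric(1), "peak_value"),
    fast_clearance = -vapply(summ, function(s)
      if (is.na(s$clearance_minutes)) worst_clear else s$clearance_minutes,
      numeric(1)),
    stringsAsFactors = FALSE
  )
  axes <- setdiff(names(raw), "species")
  out <- data.frame(species = raw$species, stringsAsFactors = FALSE)
  for (ax in axes) {
    v <- raw[[ax]]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warnf("radar axis '%s' is constant and was dropped", ax)
      next
    }
    out[[ax]] <- (v - rng[1]) / (rng[2] - rng[1])
  }
  out
}
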