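# Generators producing every input class with known ground truth, so the
# whole pipeline is testable without laboratory data.  Each generator is a
# right inverse of its analysis at zero noise: the analysis applied to its
# output recovers the programmed target (to machine precision for the
# closed-form indices; within 8-bit quantization for images).  All
# randomness flows from the explicit seed argument.

#' Generate a synthetic DAB-stained leaf image
#'
#' Plants brown-toned stain blobs on an achromatic background.  The brown
#' is synthesized at hue 30 degrees with fixed value \code{V = 200} and the
#' HSV saturation (0-255 scale) as the controlled variable, so the image
#' quantifier's accuracy can be measured against a known truth; 8-bit
#' rounding is the only recovery error source at zero noise.  Blob centers
#' are snapped to the default ROI grid (multiples of 25) so the greedy ROI
#' search and the exhaustive one agree on these images.
#'
#' @param seed integer seed; the same seed reproduces the image exactly.
#' @param height,width image dimensions in pixels.
#' @param blob_count number of stain blobs (0 for an unstained image).
#' @param blob_radius blob radius in pixels; with the default ROI size 100,
#'   radius >= 75 guarantees each blob contains a fully stained window.
#' @param stain_saturation programmed blob saturation in [0, 255].
#' @param background_gray achromatic background level, 0..255 (default 255,
#'   white).
#' @param pixel_noise_sd SD of additive Gaussian pixel noise (per channel),
#'   truncated to [0, 255]; 0 for a noise-free image.
#' @param shape \code{"disc"} (default) or \code{"square"} blobs; square
#'   blobs of radius 50 are exactly one 100x100 window, giving a unique
#'   ROI optimum.
#' @return A list with \code{image} (integer H x W x 3 array), \code{mask}
#'   (logical stain mask), \code{saturation} (the programmed target) and
#'   \code{centers} (blob centers, one row each).
#' @export
gen_leaf_image <- function(seed = 1L, height = 512L, width = 512L,
                           blob_count = 3L, blob_radius = 75L,
                           stain_saturation = 120,
                           background_gray = 255L, pixel_noise_sd = 0,
                           shape = c("disc", "square")) {
  shape <- match.arg(shape)
  stopifnot(is_count(height), is_count(width), is_count(blob_count),
            is_number(stain_saturation), is_number(pixel_noise_sd),
            pixel_noise_sd >= 0)
  if (stain_saturation < 0 || stain_saturation > 255)
    stopf("stain_saturation must lie in [0, 255]")
  if (background_gray < 0 || background_gray > 255)
    stopf("background_gray must lie in [0, 255]")
  if (blob_count > 0 && (2 * blob_radius + 50 > min(height, width)))
    stopf("blobs of radius %d do not fit in a %d x %d image", blob_radius,
          height, width)

  with_seed(seed, {
    # candidate centers on the 25-px grid, blobs fully inside the image
    lo <- 25 * ceiling((blob_radius + 1) / 25)
    hi_r <- 25 * floor((height - blob_radius - 1) / 25)
    hi_c <- 25 * floor((width - blob_radius - 1) / 25)
    if (blob_count > 0 && (hi_r < lo || hi_c < lo))
      stopf("blobs of radius %d do not fit in a %d x %d image", blob_radius,
            height, width)
    grid_r <- seq(lo, hi_r, by = 25)
    grid_c <- seq(lo, hi_c, by = 25)
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0
    sep_needed <- 2 * blob_radius + 25
    while (nrow(centers) < blob_count) {
      cand <- c(grid_r[sample.int(length(grid_r), 1)],
                grid_c[sample.int(length(grid_c), 1)])
      if (!nrow(centers) ||
          all(pmax(abs(centers[, 1] - cand[1]),
                   abs(centers[, 2] - cand[2])) >= sep_needed)) {
        centers <- rbind(centers, cand)
      }
      tries <- tries + 1
      if (tries > 10000)
        stopf("could not place %d non-overlapping blobs", blob_count)
    }

    mask <- matrix(FALSE, height, width)
    if (blob_count > 0) {
      rows <- matrix(seq_len(height), height, width)
      cols <- matrix(seq_len(width), height, width, byrow = TRUE)
      for (i in seq_len(nrow(centers))) {
        if (shape == "disc") {
          mask <- mask | ((rows - centers[i, 1])^2 +
                            (cols - centers[i, 2])^2 <= blob_radius^2)
        } else {
          mask <- mask | (abs(rows - centers[i, 1]) < blob_radius &
                            abs(cols - centers[i, 2]) < blob_radius)
        }
      }
    }

    # hue 30 deg, value 200: R = V, B = V(1 - S/255), G = (R + B)/2
    v <- 200
    b_val <- v * (1 - stain_saturation / 255)
    g_val <- (v + b_val) / 2
    r_ch <- matrix(background_gray, height, width)
    g_ch <- matrix(background_gray, height, width)
    b_ch <- matrix(background_gray, height, width)
    r_ch[mask] <- v; g_ch[mask] <- g_val; b_ch[mask] <- b_val
    img <- array(0, dim = c(height, width, 3))
    img[, , 1] <- r_ch; img[, , 2] <- g_ch; img[, , 3] <- b_ch
    if (pixel_noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, pixel_noise_sd)
    img <- array(as.integer(pmin(255, pmax(0, round(img)))), dim = dim(img))
    list(image = img, mask = mask, saturation = stain_saturation,
         centers = unname(centers))
  })
}

#' Generate a dehydration weight series with a known final RWC
#'
#' Produces a (time, fresh weight) series against fixed turgid and dry
#' weights such that at zero noise the final time point's RWC equals
#' \code{rwc_target} exactly (and the initial point is fully turgid, RWC
#' 100).  Fresh weight declines linearly in RWC between the two.
#'
#' @param seed integer seed.
#' @param rwc_target target RWC (percent) at the final time point, in
#'   [0, 100].
#' @param n_points number of time points over the 6 h course (>= 2).
#' @param noise_sd SD of Gaussian noise added to the interior fresh
#'   weights, g.
#' @param turgid,dry turgid and dry weights, g.
#' @return A list with \code{time_min}, \code{fresh}, \code{turgid},
#'   \code{dry}, \code{rwc_target}.
#' @export
gen_weight_series <- function(seed = 1L, rwc_target = 70, n_points = 7L,
                              noise_sd = 0, turgid = 1.0, dry = 0.3) {
  stopifnot(is_number(rwc_target), is_count(n_points), n_points >= 2,
            is_number(noise_sd), noise_sd >= 0)
  if (rwc_target < 0 || rwc_target > 100)
    stopf("rwc_target must lie in [0, 100]")
  if (turgid <= dry) stopf("turgid weight must exceed dry weight")
  with_seed(seed, {
    time_min <- seq(0, 360, length.out = n_points)
    rwc_path <- seq(100, rwc_target, length.out = n_points)
    fresh <- dry + rwc_path / 100 * (turgid - dry)
    if (noise_sd > 0 && n_points > 2) {
      mid <- 2:(n_points - 1)
      fresh[mid] <- pmax(dry + 1e-6,
                         fresh[mid] + stats::rnorm(length(mid), 0, noise_sd))
    }
    list(time_min = time_min, fresh = fresh, turgid = turgid, dry = dry,
         rwc_target = rwc_target)
  })
}

#' Generate conductivity pairs with a known ELI
#'
#' Inverts the leakage formulas: given a target ELI and a control leakage
#' fraction, produces control and heat-stress conductivity sets whose
#' computed ELI equals the target exactly at zero noise.
#'
#' @param seed integer seed (reserved for future noise options; the
#'   inversion itself is deterministic).
#' @param eli_target target index, > -1.
#' @param el_c control leakage fraction, > 0 (default 0.1).
#' @param cond_positive positive-control conductivity, uS/cm.
#' @return A list with \code{control} and \code{heat}, each a list of
#'   \code{cond_treatment} and \code{cond_positive_control}, plus
#'   \code{el_h} and \code{el_c}.
#' @export
gen_conductivity <- function(seed = 1L, eli_target = 2, el_c = 0.1,
                             cond_positive = 200) {
  stopifnot(is_number(eli_target), is_number(el_c))
  if (el_c <= 0) stopf("el_c must be > 0")
  if (eli_target <= -1) stopf("eli_target must exceed -1")
  el_h <- el_c * (1 + eli_target)
  list(
    control = list(cond_treatment = el_c * cond_positive,
                   cond_positive_control = cond_positive),
    heat = list(cond_treatment = el_h * cond_positive,
                cond_positive_control = cond_positive),
    el_h = el_h, el_c = el_c
  )
}

#' Generate a DAB time series with programmed kinetics
#'
#' Two regimes: a \code{"tolerant"} profile rises over the heat phases D-G
#' to its peak and decays exponentially through recovery, crossing the
#' control baseline exactly at \code{clearance_phase} (so
#' [clearance_time()] returns that phase at zero noise); a
#' \code{"sensitive"} profile rises and then stays on a high,
#' non-decreasing plateau through recovery and never clears.
#'
#' @param seed integer seed.
#' @param profile \code{"tolerant"} or \code{"sensitive"}.
#' @param baseline control (phase A) level, saturation units.
#' @param peak maximal stress level, > baseline.
#' @param clearance_phase recovery phase (H..N) at which the tolerant
#'   profile reaches the baseline.
#' @param replicate_noise_sd SD of Gaussian replicate noise.
#' @param n_replicates replicates per phase (default 3).
#' @param species species code stored in the output tables.
#' @return A list with \code{series} (data frame: species, phase, mean,
#'   sd), \code{replicates} (long data frame in the \code{dab_series}
#'   schema) and the programmed parameters.
#' @export
gen_dab_series <- function(seed = 1L, profile = c("tolerant", "sensitive"),
                           baseline = 5, peak = 120, clearance_phase = "M",
                           replicate_noise_sd = 0, n_replicates = 3L,
                           species = "syn") {
  profile <- match.arg(profile)
  stopifnot(is_number(baseline), is_number(peak), baseline >= 0)
  if (peak < baseline) stopf("peak must be >= baseline")
  sched <- phase_schedule()
  rec <- recovery_phases()
  if (profile == "tolerant" && !(clearance_phase %in% rec))
    stopf("clearance_phase must be one of %s", paste(rec, collapse = ", "))

  means <- stats::setNames(numeric(14), sched$phase)
  means["A"] <- baseline
  means["B"] <- baseline + 0.25 * (peak - baseline)  # staining control
  means["C"] <- baseline + 0.5 * (peak - baseline)   # drought
  means[c("D", "E", "F", "G")] <-
    baseline + (peak - baseline) * c(0.7, 0.8, 0.9, 1.0)
  t_rec <- sched$minutes[match(rec, sched$phase)]
  if (profile == "tolerant") {
    if (peak == baseline) {
      means[rec] <- baseline
    } else {
      floor_v <- baseline / 2
      v_h0 <- baseline + 0.9 * (peak - baseline)  # level entering recovery
      t_cl <- t_rec[match(clearance_phase, rec)]
      if (clearance_phase == "H") {
        means[rec] <- baseline * (0.5 + 0.5 * exp(-(t_rec - t_rec[1]) / 200))
      } else {
        # exponential decay hitting the baseline exactly at t_cl
        lambda <- log((v_h0 - floor_v) / (baseline - floor_v)) /
          (t_cl - t_rec[1])
        means[rec] <- floor_v + (v_h0 - floor_v) *
          exp(-lambda * (t_rec - t_rec[1]))
        # pin the crossing phase to the baseline exactly (no FP slack)
        means[clearance_phase] <- baseline
      }
    }
  } else {
    # persistent plateau, mildly non-decreasing
    means[rec] <- baseline + (peak - baseline) *
      seq(0.9, 1.0, length.out = length(rec))
  }

  with_seed(seed, {
    reps <- do.call(rbind, lapply(sched$phase, function(ph) {
      vals <- means[ph] + if (replicate_noise_sd > 0)
        stats::rnorm(n_replicates, 0, replicate_noise_sd) else
          numeric(n_replicates)
      vals <- pmax(0, vals)
      data.frame(species = species, phase = ph,
                 replicate = seq_len(n_replicates), value = vals,
                 stringsAsFactors = FALSE)
    }))
    series <- do.call(rbind, lapply(sched$phase, function(ph) {
      v <- reps$value[reps$phase == ph]
      data.frame(species = species, phase = ph, mean = mean(v),
                 sd = if (length(v) > 1) stats::sd(v) else 0,
                 stringsAsFactors = FALSE)
    }))
    list(series = series, replicates = reps, profile = profile,
         baseline = baseline, peak = peak,
         clearance_phase = if (profile == "tolerant") clearance_phase
                           else NA_character_)
  })
}

#' Generate a screening cohort with planted tolerance classes
#'
#' Draws per-species (RWC, ELI) pairs from a tolerant and a sensitive
#' population whose means are \code{separation} within-class standard
#' deviations apart on both axes (tolerant: high RWC, low ELI).  For
#' \code{separation >= 2} the draws are additionally truncated to within
#' 3/4 of a class SD of their class mean and the cohort is redrawn until
#' both classes fall strictly on their own side of the cohort mean on both
#' axes — i.e. the planted separation is realized in the cohort actually
#' returned, not just in expectation — so that planted labels are
#' recoverable by construction.  At \code{separation = 0} both classes
#' coincide and recovery can only succeed at chance level.
#'
#' @param seed integer seed.
#' @param n_species cohort size (default 27).
#' @param tolerant_fraction fraction of tolerant species, in (0, 1).
#' @param separation class-mean separation in within-class SD units, >= 0.
#' @param rwc_center,eli_center cohort-center values of the two axes.
#' @param rwc_sd,eli_sd within-class SDs.
#' @return A list with \code{pairs} (data frame: species, rwc, eli) and
#'   \code{labels} (character vector, \code{"tolerant"}/\code{"sensitive"}).
#' @export
gen_cohort <- function(seed = 1L, n_species = 27L, tolerant_fraction = 0.5,
                       separation = 4, rwc_center = 60, eli_center = 5,
                       rwc_sd = 8, eli_sd = 1.5) {
  stopifnot(is_count(n_species), n_species >= 2, is_number(separation),
            separation >= 0)
  if (tolerant_fraction <= 0 || tolerant_fraction >= 1)
    stopf("tolerant_fraction must lie strictly between 0 and 1")
  n_tol <- max(1L, round(n_species * tolerant_fraction))
  n_sen <- n_species - n_tol
  if (n_sen < 1L) stopf("cohort needs at least one sensitive species")
  labels <- c(rep("tolerant", n_tol), rep("sensitive", n_sen))
  half <- separation / 2
  mu <- list(
    tolerant = c(rwc = rwc_center + half * rwc_sd,
                 eli = eli_center - half * eli_sd),
    sensitive = c(rwc = rwc_center - half * rwc_sd,
                  eli = eli_center + half * eli_sd)
  )
  enforce <- separation >= 2
  trunc_at <- 0.75  # class SDs, keeps classes disjoint at separation 2

  rtrunc <- function(n, mean, sd) {
    if (!enforce) return(stats::rnorm(n, mean, sd))
    v <- stats::rnorm(n, mean, sd)
    while (any(bad <- abs(v - mean) > trunc_at * sd))
      v[bad] <- stats::rnorm(sum(bad), mean, sd)
    v
  }

  with_seed(seed, {
    for (attempt in 1:1000) {
      rwc_v <- c(rtrunc(n_tol, mu$tolerant["rwc"], rwc_sd),
                 rtrunc(n_sen, mu$sensitive["rwc"], rwc_sd))
      eli_v <- c(rtrunc(n_tol, mu$tolerant["eli"], eli_sd),
                 rtrunc(n_sen, mu$sensitive["eli"], eli_sd))
      eli_v <- pmax(eli_v, 0.01)
      if (!enforce) break
      tol <- labels == "tolerant"
      split_ok <- min(rwc_v[tol]) > mean(rwc_v) &&
        max(rwc_v[!tol]) < mean(rwc_v) &&
        max(eli_v[tol]) < mean(eli_v) &&
        min(eli_v[!tol]) > mean(eli_v)
      if (split_ok) break
    }
    if (enforce && !split_ok)
      stopf("could not realize the planted separation; increase it")
    pairs <- data.frame(
      species = sprintf("sp%02d", seq_len(n_species)),
      rwc = rwc_v, eli = eli_v, stringsAsFactors = FALSE)
    list(pairs = pairs, labels = labels)
  })
}

#' Generate Gaussian replicate groups
#'
#' @param means named numeric vector of group means.
#' @param sd common replicate SD (>= 0).
#' @param n replicates per group (>= 2).
#' @param seed integer seed.
#' @return A named list of numeric replicate vectors, directly usable by
#'   [one_way_anova()] and [duncan_mrt()].
#' @export
gen_replicates <- function(means, sd = 1, n = 3L, seed = 1L) {
  stopifnot(is.numeric(means), !is.null(names(means)))
  if (!is_number(sd) || sd < 0) stopf("sd must be a non-negative number")
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  with_seed(seed, {
    out <- lapply(means, function(m) m + stats::rnorm(n, 0, sd))
    names(out) <- names(means)
    out
  })
}
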