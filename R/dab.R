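# Quantification of DAB-stained leaf images.
#
# DAB forms a brown precipitate where hydrogen peroxide accumulates; darker
# staining means more H2O2.  The protocol implemented here scores staining
# on the inverted red channel (which the DAB reaction darkens most), places
# k square regions of interest on the most prominently stained zones by a
# greedy grid search, measures the HSV saturation (0-255 scale) inside each
# ROI, and subtracts the saturation of the least-stained window of the same
# size as an image-specific background.  Stain *localization* therefore uses
# the inverted red channel while the reported *values* come from the
# saturation component; this split is part of the algorithm's contract.
#
# Coordinates are 1-based (R convention): a window at (row, col) of side s
# covers rows row..row+s-1 and columns col..col+s-1, origin top-left.

channel <- function(img, i) {
  matrix(img[, , i], nrow = dim(img)[1])
}

#' Red channel of an RGB image
#'
#' @param img integer H x W x 3 array, values 0..255 (see [read_image()]).
#' @return Numeric H x W matrix equal to the first channel.
#' @export
red_channel <- function(img) {
  assert_rgb_image(img)
  channel(img, 1L)
}

#' Stain score map
#'
#' Per-pixel staining intensity, defined as \code{255 - red}: dark (heavily
#' stained) pixels score high, white background scores 0.  The inversion is
#' always applied so that the score's orientation is fixed rather than an
#' operator choice.
#'
#' @inheritParams red_channel
#' @return Numeric H x W matrix in [0, 255]; higher = more stained.
#' @export
stain_score <- function(img) {
  255 - red_channel(img)
}

#' HSV saturation channel, 0-255 scale
#'
#' Per-pixel saturation \code{S = 255 * (max(R,G,B) - min(R,G,B)) /
#' max(R,G,B)}, with \code{S = 0} where \code{max = 0}.  The 0-255 scaling
#' matches the scale on which DAB intensities are reported.
#'
#' @inheritParams red_channel
#' @return Numeric H x W matrix in [0, 255].
#' @export
saturation_channel <- function(img) {
  assert_rgb_image(img)
  r <- channel(img, 1L); g <- channel(img, 2L); b <- channel(img, 3L)
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  s <- ifelse(mx == 0, 0, 255 * (mx - mn) / mx)
  matrix(s, nrow = nrow(r))
}

# Mean of every size x size window whose top-left corner lies on the
# stride grid, via a summed-area table.  Returns a data frame of candidate
# windows (row, col, mean) in row-major grid order.
window_means <- function(map, size, stride) {
  h <- nrow(map); w <- ncol(map)
  if (h < size || w < size)
    stopf("image (%d x %d) smaller than window size %d", h, w, size)
  sat <- rbind(0, cbind(0, apply(apply(map, 2, cumsum), 1, cumsum)))
  # note: apply(..., 1, cumsum) transposes; sat is (w+1) x (h+1) after the
  # second apply, so index as sat[col, row]
  sat <- t(sat)
  rows <- seq.int(1L, h - size + 1L, by = stride)
  cols <- seq.int(1L, w - size + 1L, by = stride)
  grid <- expand.grid(col = cols, row = rows)  # row-major order
  r <- grid$row; cl <- grid$col
  sums <- sat[cbind(r + size, cl + size)] - sat[cbind(r, cl + size)] -
    sat[cbind(r + size, cl)] + sat[cbind(r, cl)]
  data.frame(row = r, col = cl, mean = sums / (size * size))
}

windows_overlap <- function(r1, c1, r2, c2, size) {
  abs(r1 - r2) < size & abs(c1 - c2) < size
}

#' Select regions of interest on the most stained zones
#'
#' Greedy grid search: among all candidate windows on a stride grid, pick
#' the window with the highest mean stain score, then repeatedly the best
#' window not overlapping any previous pick, until \code{k} windows are
#' placed.  Ties are broken by (row, col) in lexicographic order, making
#' the selection fully deterministic.  \code{stride = 1} is an exhaustive
#' search over every window position.
#'
#' @param score stain score matrix from [stain_score()].
#' @param k number of ROIs (default 3).
#' @param size window side length in pixels (default 100).
#' @param stride candidate grid spacing in pixels (default 25).
#' @return Data frame with columns \code{row}, \code{col}, \code{size},
#'   \code{mean_score}, one row per ROI, in decreasing score order.
#' @export
select_rois <- function(score, k = 3L, size = 100L, stride = 25L) {
  stopifnot(is.matrix(score), is_count(k), k >= 1, is_count(size), size >= 1,
            is_count(stride), stride >= 1)
  cand <- window_means(score, size, stride)
  ord <- order(-cand$mean, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE]
  picked <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(picked) == k) break
    if (!length(picked) ||
        !any(windows_overlap(cand$row[i], cand$col[i],
                             cand$row[picked], cand$col[picked], size))) {
      picked <- c(picked, i)
    }
  }
  if (length(picked) < k)
    stopf("image too small: only %d non-overlapping %dx%d windows available (%d requested)",
          length(picked), size, size, k)
  out <- cand[picked, , drop = FALSE]
  data.frame(row = out$row, col = out$col, size = as.integer(size),
             mean_score = out$mean)
}

#' Background saturation of an image
#'
#' Mean HSV saturation over the candidate window with the \emph{lowest}
#' mean stain score — the deterministic analogue of manually sampling a
#' non-stained background area.  Ties are broken as in [select_rois()].
#'
#' @inheritParams red_channel
#' @param score optional precomputed stain score matrix.
#' @param size window side length in pixels.
#' @param stride candidate grid spacing in pixels.
#' @return Background saturation in 0-255 units.
#' @export
background_value <- function(img, score = stain_score(img), size = 100L,
                             stride = 25L) {
  assert_rgb_image(img)
  cand <- window_means(score, size, stride)
  i <- order(cand$mean, cand$row, cand$col)[1]
  sat <- saturation_channel(img)
  win <- sat[cand$row[i]:(cand$row[i] + size - 1),
             cand$col[i]:(cand$col[i] + size - 1)]
  mean(win)
}

#' Quantify DAB staining in one image
#'
#' Full single-image pipeline: stain scoring, ROI placement, saturation
#' readout and background correction.  Per ROI the corrected value is
#' \code{max(0, mean saturation - background)}; negative corrected
#' saturation is physically meaningless and floored at zero.  The result is
#' deterministic for a fixed image and parameters.
#'
#' @inheritParams red_channel
#' @inheritParams select_rois
#' @return An object of class \code{"dab_quant"}: a list with
#'   \code{rois} (the selected windows), \code{roi_raw_means},
#'   \code{background}, \code{roi_corrected}, \code{corrected_mean} and
#'   \code{corrected_sd} (sample SD across ROIs).
#' @export
quantify <- function(img, k = 3L, size = 100L, stride = 25L) {
  assert_rgb_image(img, min_dim = size)
  score <- stain_score(img)
  rois <- select_rois(score, k = k, size = size, stride = stride)
  sat <- saturation_channel(img)
  raw <- vapply(seq_len(nrow(rois)), function(i) {
    mean(sat[rois$row[i]:(rois$row[i] + size - 1),
             rois$col[i]:(rois$col[i] + size - 1)])
  }, numeric(1))
  bg <- background_value(img, score = score, size = size, stride = stride)
  corrected <- pmax(0, raw - bg)
  structure(list(
    rois = rois,
    roi_raw_means = raw,
    background = bg,
    roi_corrected = corrected,
    corrected_mean = mean(corrected),
    corrected_sd = if (length(corrected) > 1L) stats::sd(corrected)
                   else NA_real_,
    k = as.integer(k), size = as.integer(size), stride = as.integer(stride)
  ), class = "dab_quant")
}

#' @export
print.dab_quant <- function(x, ...) {
  cat(sprintf("DAB quantification: %d ROI(s) of %dx%d px (stride %d)\n",
              x$k, x$size, x$size, x$stride))
  cat(sprintf("  background saturation: %.2f\n", x$background))
  cat(sprintf("  corrected saturation:  %.2f +/- %s\n", x$corrected_mean,
              ifelse(is.na(x$corrected_sd), "NA",
                     sprintf("%.2f", x$corrected_sd))))
  invisible(x)
}

#' Quantify a batch of replicate images
#'
#' Runs [quantify()] on every image and summarizes the corrected mean per
#' (species, phase) as mean and sample SD across replicates, the layout of
#' the packaged DAB intensity table.  Combinations present for some species
#' but missing for another are emitted with \code{NA} values and flagged.
#'
#' @param images a list; each element a list with fields \code{species},
#'   \code{phase}, \code{replicate} and \code{image} (an RGB array).
#' @inheritParams select_rois
#' @return Data frame with columns \code{species}, \code{phase},
#'   \code{mean}, \code{sd}, \code{n}, \code{incomplete}.
#' @export
quantify_batch <- function(images, k = 3L, size = 100L, stride = 25L) {
  stopifnot(is.list(images), length(images) >= 1L)
  recs <- lapply(images, function(e) {
    q <- quantify(e$image, k = k, size = size, stride = stride)
    data.frame(species = e$species, phase = e$phase,
               replicate = e$replicate, value = q$corrected_mean,
               stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, recs)
  species <- unique(per_rep$species)
  phases <- unique(per_rep$phase)
  grid <- expand.grid(phase = phases, species = species,
                      stringsAsFactors = FALSE)[, c("species", "phase")]
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- per_rep$value[per_rep$species == grid$species[i] &
                         per_rep$phase == grid$phase[i]]
    data.frame(species = grid$species[i], phase = grid$phase[i],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), incomplete = length(v) == 0L,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
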