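# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: window means are computed by direct submatrix
# sums, ANOVA by definitional sums of squares, saturation pixel by pixel.

# Brute-force greedy ROI search over every grid position, means computed by
# direct submatrix averaging.
oracle_select_rois <- function(score, k = 3, size = 100, stride = 25) {
  h <- nrow(score); w <- ncol(score)
  rows <- seq(1, h - size + 1, by = stride)
  cols <- seq(1, w - size + 1, by = stride)
  cand <- do.call(rbind, lapply(rows, function(r) do.call(rbind,
    lapply(cols, function(c2) data.frame(
      row = r, col = c2,
      mean = mean(score[r:(r + size - 1), c2:(c2 + size - 1)]))))))
  cand <- cand[order(-cand$mean, cand$row, cand$col), ]
  picked <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(picked) == k) break
    ok <- TRUE
    for (j in seq_len(nrow(picked))) {
      if (abs(cand$row[i] - picked$row[j]) < size &&
          abs(cand$col[i] - picked$col[j]) < size) { ok <- FALSE; break }
    }
    if (ok) picked <- rbind(picked, cand[i, ])
  }
  rownames(picked) <- NULL
  picked
}

# Definitional one-way ANOVA: between/within sums of squares from scratch.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all_v) - length(groups)
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- ms_b / ms_w
  list(f = f, df_b = df_b, df_w = df_w, mse = ms_w,
       p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# HSV saturation of one pixel, 0-255 scale, straight from the definition.
oracle_saturation_px <- function(r, g, b) {
  mx <- max(r, g, b)
  if (mx == 0) return(0)
  255 * (mx - min(r, g, b)) / mx
}

# A solid-color image.
uniform_image <- function(h, w, rgb) {
  img <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

# The four-species index pairs printed for the pre-screening cohort.
prescreen_pairs <- function() {
  data.frame(species = c("Co", "Qm", "Qg", "Aj"),
             rwc = c(78.2, 76.8, 72.9, 35.6),
             eli = c(1.78, 2.94, 2.68, 8.00),
             stringsAsFactors = FALSE)
}
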