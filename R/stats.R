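# Inferential layer: one-way ANOVA followed by Duncan's multiple range
# test (DMRT) at alpha = 0.05, summarized as compact letter displays —
# the convention used for all replicate-group comparisons (n = 3).

as_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("label", "value") %in% names(groups)))
    groups <- split(groups$value, factor(groups$label,
                                         levels = unique(groups$label)))
  }
  if (!is.list(groups) || is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be a named list of replicate vectors or a data frame with columns label, value")
  if (length(groups) < 2L) stopf("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L))
    stopf("every group needs at least 2 replicates (group '%s' has %d)",
          names(groups)[which(sizes < 2L)[1]], min(sizes))
  lapply(groups, as.numeric)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA over named replicate groups,
#' fitted through \code{stats::lm}/\code{stats::anova}.
#'
#' @param groups a named list of numeric replicate vectors (>= 2 groups,
#'   each >= 2 replicates), or a data frame with columns \code{label} and
#'   \code{value}.
#' @return A list with \code{f_stat}, \code{df_between}, \code{df_within},
#'   \code{p_value}, \code{mse} (within-group mean square) and
#'   \code{group_means}.
#' @export
one_way_anova <- function(groups) {
  groups <- as_groups(groups)
  dat <- data.frame(
    value = unlist(groups, use.names = FALSE),
    label = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
  tab <- stats::anova(stats::lm(value ~ label, data = dat))
  list(f_stat = tab$`F value`[1],
       df_between = tab$Df[1],
       df_within = tab$Df[2],
       p_value = tab$`Pr(>F)`[1],
       mse = tab$`Mean Sq`[2],
       group_means = vapply(groups, mean, numeric(1)))
}

# Least-significant-range multiplier for a pair spanning p ranks: the
# studentized-range critical value at Duncan's protection level
# 1 - (1 - alpha)^(p - 1).
duncan_q <- function(p, df, alpha) {
  stats::qtukey((1 - alpha)^(p - 1), nmeans = p, df = df)
}

#' Duncan's multiple range test
#'
#' Step-down multiple comparison of group means using rank-dependent least
#' significant ranges.  Means are sorted; a pair spanning \code{p} ranks is
#' significant when its difference exceeds \code{r_p * sqrt(MSE / n)},
#' where \code{r_p} is the studentized-range critical value at protection
#' level \code{1 - (1 - alpha)^(p - 1)}.  The standard non-contradiction
#' rule applies: a pair enclosed by a non-significant pair is itself
#' declared non-significant.  With unequal group sizes \code{n} is the
#' harmonic mean.
#'
#' @inheritParams one_way_anova
#' @param alpha significance level (default 0.05).
#' @return A list with \code{significant} (symmetric logical matrix over
#'   groups), \code{means}, \code{mse}, \code{df_within}, \code{n},
#'   \code{alpha}.
#' @export
duncan_mrt <- function(groups, alpha = 0.05) {
  groups <- as_groups(groups)
  fit <- one_way_anova(groups)
  n_h <- length(groups) / sum(1 / lengths(groups))  # harmonic mean n
  duncan_core(fit$group_means, fit$mse, fit$df_within, n_h, alpha)
}

# Shared DMRT engine over summary statistics.
duncan_core <- function(means, mse, df_within, n, alpha) {
  k <- length(means)
  labs <- names(means)
  se <- sqrt(mse / n)
  ord <- order(means, decreasing = TRUE)
  sig <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  blocked <- matrix(FALSE, k, k)  # in sorted coordinates
  sorted <- means[ord]
  for (span in seq(k, 2)) {
    if (span < 2) break
    lsr <- if (se == 0) 0 else duncan_q(span, df_within, alpha) * se
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (blocked[i, j]) next
      diffed <- sorted[i] - sorted[j]
      if (se == 0) {
        is_sig <- diffed > 0
      } else {
        is_sig <- diffed > lsr
      }
      if (is_sig) {
        sig[ord[i], ord[j]] <- sig[ord[j], ord[i]] <- TRUE
      } else {
        # non-contradiction: everything enclosed is non-significant too
        for (a in i:j) for (b in a:j) blocked[a, b] <- TRUE
      }
    }
  }
  list(significant = sig, means = means, mse = mse, df_within = df_within,
       n = n, alpha = alpha)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb letter assignment: groups sharing a letter are not
#' significantly different.  Letters are assigned in order of descending
#' group mean, so \code{"a"} always contains the largest mean.
#'
#' @param significant symmetric logical matrix (TRUE = significantly
#'   different), with group names as dimnames.
#' @param means named numeric vector of group means, used to order the
#'   letters.
#' @return Named character vector: one letter string per group.
#' @export
compact_letters <- function(significant, means) {
  if (!is.matrix(significant) || !isSymmetric(unname(significant * 1)))
    stopf("significance matrix must be symmetric")
  labs <- rownames(significant)
  stopifnot(!is.null(labs), all(labs %in% names(means)))
  ord <- labs[order(-means[labs])]
  # a column is a subset of (or equal to) another column's member set
  absorbed_by <- function(a, b) all(a %in% b)
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) {
      for (b in seq_along(cols)) {
        if (a == b || !keep[a] || !keep[b]) next
        if (absorbed_by(cols[[a]], cols[[b]]) &&
            (length(cols[[a]]) < length(cols[[b]]) || a > b))
          keep[a] <- FALSE
      }
    }
    cols[keep]
  }
  # columns = letter sets, built over groups in descending-mean order
  cols <- list(ord)  # start: one letter containing everyone
  for (i in seq_along(ord)) {
    for (j in seq_len(i - 1L)) {
      if (!significant[ord[i], ord[j]]) next
      for (ci in seq_along(cols)) {
        if (all(c(ord[i], ord[j]) %in% cols[[ci]])) {
          # duplicate the offending column, removing one member from each copy
          c2 <- setdiff(cols[[ci]], ord[j])
          cols[[ci]] <- setdiff(cols[[ci]], ord[i])
          cols[[length(cols) + 1L]] <- c2
        }
      }
      cols <- absorb(cols[lengths(cols) > 0])
    }
  }
  # order letters by the best-ranked member of each column
  first_member <- vapply(cols, function(cc) min(match(cc, ord)), numeric(1))
  cols <- cols[order(first_member)]
  out <- vapply(labs, function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, logical(1)))],
          collapse = "")
  }, character(1))
  out
}

#' Duncan letters from raw replicate groups
#'
#' Convenience wrapper: [duncan_mrt()] then [compact_letters()].
#'
#' @inheritParams duncan_mrt
#' @return Named character vector of letters.
#' @export
duncan_letters <- function(groups, alpha = 0.05) {
  res <- duncan_mrt(groups, alpha = alpha)
  compact_letters(res$significant, res$means)
}

#' Duncan letters from mean/SD summaries
#'
#' Approximate DMRT when only per-group means and SDs are available (as in
#' published tables): the within-group mean square is estimated as the mean
#' of the group variances with \code{(n - 1) * k} error degrees of freedom.
#' This reconstruction is exact for balanced designs, since the pooled
#' within-group variance of the raw data is exactly the mean of the group
#' variances; it is labelled approximate because the published summaries
#' may hide tie-handling choices of the original software.
#'
#' @param means named numeric vector of group means.
#' @param sds numeric vector of group standard deviations.
#' @param n common number of replicates per group (>= 2).
#' @param alpha significance level.
#' @return A list as [duncan_mrt()], plus \code{letters} and
#'   \code{method = "dmrt_from_summary (approximate)"}.
#' @export
#' @examples
#' tab <- load_dab_table()
#' a_col <- tab[tab$phase == "A", ]
#' dmrt_from_summary(setNames(a_col$mean, a_col$species), a_col$sd, n = 3)$letters
dmrt_from_summary <- function(means, sds, n, alpha = 0.05) {
  if (!is_count(n) || n < 2) stopf("n must be an integer >= 2")
  stopifnot(length(means) == length(sds), !is.null(names(means)))
  if (any(sds < 0)) stopf("standard deviations must be non-negative")
  mse <- mean(sds^2)
  df_within <- (n - 1) * length(means)
  res <- duncan_core(means, mse, df_within, n, alpha)
  res$letters <- compact_letters(res$significant, means)
  res$method <- "dmrt_from_summary (approximate)"
  res
}
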