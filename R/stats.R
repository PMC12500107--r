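#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic two-sample K-S distribution.
#' This is the comparison behind the length-scaled-abundance violin plots.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return A `cr_ks` object with `D`, `p_value`, `n1`, `n2`; see
#'   [tidy.cr_ks()].
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  structure(
    list(D = unname(kt$statistic), p_value = kt$p.value,
         n1 = length(x), n2 = length(y)),
    class = "cr_ks"
  )
}

#' @export
print.cr_ks <- function(x, ...) {
  cat("<cr_ks> D = ", format(x$D, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (n = ", x$n1, ", ", x$n2, ")\n", sep = "")
  invisible(x)
}

#' @describeIn ks_two_sample One-row tibble of the test result.
#' @param x A `cr_ks` object.
#' @param ... Unused.
#' @export
#' @method tidy cr_ks
tidy.cr_ks <- function(x, ...) {
  tibble::tibble(D = x$D, p_value = x$p_value, n1 = x$n1, n2 = x$n2)
}

usable_bins <- function(track, blacklist = NULL, mask = NULL) {
  g <- genome_of(track)
  keep <- rep(TRUE, nrow(track))
  gr_bins <- NULL
  bins_gr <- function() {
    if (is.null(gr_bins)) {
      gr_bins <<- gr_make(track$chrom, track$start + 1,
                          pmin(track$start + g$bin_width, g$chroms[track$chrom]), g)
    }
    gr_bins
  }
  if (!is.null(blacklist) && nrow(blacklist)) {
    keep <- keep & GenomicRanges::countOverlaps(bins_gr(), regions_to_gr(blacklist)) == 0
  }
  if (!is.null(mask)) {
    if (!nrow(mask)) stop("region mask is empty")
    keep <- keep & GenomicRanges::countOverlaps(bins_gr(), regions_to_gr(mask)) > 0
  }
  keep
}

#' Blacklist-filtered Pearson correlation between two tracks
#'
#' Pearson r over bins outside the blacklist and (if given) inside the
#' region mask. Bins where both tracks are zero are retained: shared
#' absence of signal is information in binned coverage comparisons.
#'
#' @param a,b Track tibbles on the same genome.
#' @param blacklist Optional region tibble of artifact bins to exclude.
#' @param mask Optional region tibble restricting the comparison (e.g. a
#'   peak-region set).
#' @return A single Pearson r.
#' @export
pearson_tracks <- function(a, b, blacklist = NULL, mask = NULL) {
  check_same_genome(a, b, "tracks")
  keep <- usable_bins(a, blacklist, mask)
  x <- a$value[keep]; y <- b$value[keep]
  if (length(x) < 2) stop("fewer than 2 usable bins")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in usable bins")
  stats::cor(x, y)
}

#' Pairwise correlation matrix of tracks
#'
#' All pairwise [pearson_tracks()] values; symmetric with unit diagonal.
#'
#' @param tracks Named list of >= 2 track tibbles.
#' @inheritParams pearson_tracks
#' @return A `cr_cormat`: the correlation matrix with mask provenance
#'   attributes; see [tidy.cr_cormat()] and [autoplot.cr_cormat()].
#' @export
correlation_matrix <- function(tracks, blacklist = NULL, mask = NULL) {
  if (!is.list(tracks) || length(tracks) < 2) stop("need >= 2 tracks")
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  n <- length(tracks)
  m <- diag(1, n)
  dimnames(m) <- list(names(tracks), names(tracks))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- pearson_tracks(tracks[[i]], tracks[[j]], blacklist, mask)
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  structure(m, class = c("cr_cormat", "matrix", "array"),
            blacklisted = !is.null(blacklist) && nrow(blacklist) > 0,
            masked = !is.null(mask))
}

#' @describeIn correlation_matrix Long tibble (`sample_a`, `sample_b`, `r`).
#' @param x A `cr_cormat`.
#' @param ... Unused.
#' @export
#' @method tidy cr_cormat
tidy.cr_cormat <- function(x, ...) {
  nm <- rownames(x)
  tibble::tibble(
    sample_a = rep(nm, each = length(nm)),
    sample_b = rep(nm, length(nm)),
    r = as.vector(t(unclass(x)))
  )
}

# Newton solve of trigamma(y) = x (monotone decreasing), used by the
# empirical-Bayes prior fit.
trigamma_inverse <- function(x) {
  out <- x
  lo <- x < 1e-6
  hi <- x > 1e7
  out[lo] <- 1 / x[lo]
  out[hi] <- 1 / sqrt(x[hi])
  mid <- !lo & !hi
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

# Moment-matching fit of the scaled inverse-chi-square prior on observed
# sample variances: on the log scale, log s^2 ~ log s0^2 + log F(d, d0),
# and the mean/variance of log F involve digamma/trigamma functions.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(d0 = Inf, s0_2 = mean(s2[is.finite(s2)])))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(emean)
  }
  list(d0 = d0, s0_2 = s0_2)
}

#' Moderated t-statistics for two-condition differential abundance
#'
#' The empirical-Bayes route used for region-level differential CUT&RUN
#' abundance: per-region two-sample contrasts on log2 values with the
#' residual variance shrunk toward a fitted scaled inverse-chi-square
#' prior. The posterior variance is
#' `s_tilde^2 = (d0 * s0^2 + d * s^2) / (d0 + d)` with `d = n1 + n2 - 2`,
#' and `t = log2FC / (s_tilde * sqrt(1/n1 + 1/n2))` on `d0 + d` degrees of
#' freedom. `d0` and `s0` are fitted by moment matching on the log sample
#' variances; `prior_df = 0` recovers the ordinary equal-variance t, and a
#' large `prior_df` pools all regions to a common variance.
#'
#' @param matrix Numeric regions x samples matrix of log2 abundances with
#'   region ids as rownames.
#' @param condition Factor (2 levels) of length `ncol(matrix)`; the log2FC
#'   is level 2 minus level 1.
#' @param prior_df Optional override of the fitted prior degrees of
#'   freedom `d0` (with `prior_var` as `s0^2`).
#' @param prior_var Optional override of the prior variance.
#' @return Tibble with `id`, `mean_1`, `mean_2`, `log2fc`, `t`, `p_value`,
#'   plus the fit constants as attributes `d0` and `s0_2`.
#' @export
moderated_t <- function(matrix, condition, prior_df = NULL, prior_var = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("`condition` must have exactly 2 levels")
  if (length(condition) != ncol(matrix)) stop("`condition` length must match columns")
  if (nrow(matrix) < 2) stop("need >= 2 regions")
  i1 <- which(condition == levels(condition)[1])
  i2 <- which(condition == levels(condition)[2])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per condition")
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  d <- n1 + n2 - 2
  ss <- rowSums((matrix[, i1, drop = FALSE] - m1)^2) +
    rowSums((matrix[, i2, drop = FALSE] - m2)^2)
  s2 <- ss / d
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    prior <- list(
      d0 = prior_df,
      s0_2 = if (!is.null(prior_var)) prior_var else fit_variance_prior(s2, d)$s0_2
    )
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  s_tilde2 <- if (is.infinite(d0)) rep(s0_2, length(s2)) else (d0 * s0_2 + d * s2) / (d0 + d)
  lfc <- m2 - m1
  se <- sqrt(s_tilde2 * (1 / n1 + 1 / n2))
  t_stat <- lfc / se
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  # zero-variance, zero-difference regions: no evidence either way
  degenerate <- se == 0 & lfc == 0
  t_stat[degenerate] <- 0
  p[degenerate] <- 1
  p[se == 0 & lfc != 0] <- 0
  t_stat[se == 0 & lfc != 0] <- sign(lfc[se == 0 & lfc != 0]) * Inf
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- sprintf("region_%05d", seq_len(nrow(matrix)))
  out <- tibble::tibble(
    id = ids, mean_1 = unname(m1), mean_2 = unname(m2),
    log2fc = unname(lfc), t = unname(t_stat), p_value = unname(p)
  )
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "residual_df") <- d
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; never decreases a
#' p-value and preserves rank order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Three-class labelling of a differential table
#'
#' A region is `increased` iff its BH-adjusted p-value is below `alpha`
#' and its fold change is at least `fc_threshold`; `decreased`
#' symmetrically; otherwise `unchanged`.
#'
#' @param dt Output of [moderated_t()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 1.5).
#' @return `dt` with `adj_p` and `class` columns, class `cr_diff`; summary
#'   counts and percentages via [glance.cr_diff()].
#' @export
classify_differential <- function(dt, alpha = 0.05, fc_threshold = 1.5) {
  out <- dt
  out$adj_p <- bh_adjust(dt$p_value)
  lfc_thr <- log2(fc_threshold)
  out$class <- dplyr::case_when(
    out$adj_p < alpha & out$log2fc >= lfc_thr ~ "increased",
    out$adj_p < alpha & out$log2fc <= -lfc_thr ~ "decreased",
    TRUE ~ "unchanged"
  )
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "d0") <- attr(dt, "d0")
  attr(out, "s0_2") <- attr(dt, "s0_2")
  class(out) <- unique(c("cr_diff", class(out)))
  out
}

#' @describeIn classify_differential Summary counts and percentages per
#'   class, computed as `100 * count / total`.
#' @param x A `cr_diff` table.
#' @param ... Unused.
#' @export
#' @method glance cr_diff
glance.cr_diff <- function(x, ...) {
  n <- nrow(x)
  n_up <- sum(x$class == "increased")
  n_down <- sum(x$class == "decreased")
  tibble::tibble(
    n = n, increased = n_up, decreased = n_down,
    unchanged = n - n_up - n_down,
    pct_increased = class_percentage(n_up, n),
    pct_decreased = class_percentage(n_down, n),
    alpha = attr(x, "alpha"), fc_threshold = attr(x, "fc_threshold")
  )
}

#' Percentage of a class count over a total
#'
#' The report's percentage formula: `100 * count / total`, rounded to one
#' decimal place (so 6246 of 39358 regions is 15.9).
#'
#' @param count Class count(s).
#' @param total Total region count.
#' @param digits Decimal places (default 1).
#' @return Percentage(s).
#' @export
class_percentage <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be > 0")
  round(100 * count / total, digits)
}

#' Variance explained per principal component
#'
#' Fractions of total variance carried by each principal component of the
#' column-centered samples x features matrix, from its singular values.
#'
#' @param matrix Numeric samples x features matrix (>= 2 samples).
#' @return Tibble with `component` and `variance_fraction` (summing to 1
#'   over the non-degenerate components).
#' @export
pca_variance_explained <- function(matrix) {
  if (nrow(matrix) < 2) stop("need >= 2 samples")
  if (ncol(matrix) < 1) stop("need >= 1 feature")
  centered <- scale(matrix, center = TRUE, scale = FALSE)
  d <- svd(centered)$d
  k <- min(nrow(matrix) - 1, ncol(matrix))
  d <- d[seq_len(k)]
  frac <- d^2 / sum(d^2)
  tibble::tibble(component = seq_along(frac), variance_fraction = frac)
}
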