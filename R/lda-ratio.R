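#' Standard distance between two samples
#'
#' Absolute difference of the two sample means divided by the pooled
#' within-sample standard deviation, pooled by degrees of freedom:
#' sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)).
#'
#' @param a,b Numeric vectors (the two samples).
#' @return Non-negative scalar; `Inf` when the means differ but the pooled
#'   sd is zero, `0` when both are zero.
#' @export
#' @examples
#' standard_distance(c(-0.1, 0.1), c(0.9, 1.1))  # 7.071
standard_distance <- function(a, b) {
  ps <- pooled_sd(a, b)
  diff <- abs(mean(a) - mean(b))
  if (ps == 0) {
    if (diff == 0) 0 else Inf
  } else {
    diff / ps
  }
}

pooled_sd <- function(a, b) {
  na <- length(a); nb <- length(b)
  sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
}

# Pooled within-group covariance matrix, df-weighted.
pooled_cov <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  ((na - 1) * stats::cov(xa) + (nb - 1) * stats::cov(xb)) / (na + nb - 2)
}

#' Delta: the size share of group separation
#'
#' delta = D_size / (D_size + D_shape), the proportion of between-group
#' separation attributable to size. Values near 0 indicate shape-driven
#' separation; values near 1, size-driven.
#'
#' @param d_size Standard distance between the groups' log isosizes.
#' @param d_shape Mahalanobis distance between the group shape means under
#'   the pooled within-group shape covariance.
#' @return Scalar in `[0, 1]`; `NA` when both components are zero (no
#'   separation at all, delta undefined).
#' @export
#' @examples
#' delta_size_shape(0.295, 0.92)  # 0.243
delta_size_shape <- function(d_size, d_shape) {
  stopifnot(d_size >= 0, d_shape >= 0)
  total <- d_size + d_shape
  if (total == 0) NA_real_ else d_size / total
}

# Ratio orientations used in published identification keys for these
# variable sets; pairs not listed are oriented by the larger group-A mean log.
canonical_ratio_orders <- c(
  "AW/SH", "AH/LWaH", "LWmH/SD", "V/VA", "DBC/V", "E/VA", "F/V"
)

orient_pair <- function(i, j, mean_log_a) {
  if (paste0(i, "/", j) %in% canonical_ratio_orders) return(c(i, j))
  if (paste0(j, "/", i) %in% canonical_ratio_orders) return(c(j, i))
  if (mean_log_a[[i]] >= mean_log_a[[j]]) c(i, j) else c(j, i)
}

#' LDA ratio extractor for two groups
#'
#' Exhaustive search for the body ratio that best separates two groups.
#' For every unordered variable pair (i, j) the log-ratio
#' r = ln x_i - ln x_j is scored by its standard distance D between the
#' groups ([standard_distance()]); the best ratio maximises D. A second,
#' complementary ratio is the highest-D pair whose pooled within-group
#' correlation with the best log-ratio is below `decorrelation` in absolute
#' value; if no pair qualifies, the least-correlated pair is reported and
#' flagged (`second_flagged`).
#'
#' Group separation is decomposed into a size component (standard distance
#' of log isosize, `D_size`) and a shape component (`D_shape`, the
#' Mahalanobis distance between group shape means under the pooled
#' within-group shape covariance, inverted by eigendecomposition restricted
#' to directions with eigenvalue > 1e-12 of the largest — the clr subspace
#' is rank deficient by construction). Their ratio gives
#' delta = D_size / (D_size + D_shape) ([delta_size_shape()]).
#'
#' @param data A measurement table.
#' @param groups Character vector of the two group labels to compare;
#'   defaults to the two groups present (errors if there are not exactly 2).
#' @param vars Measurement variables to use; defaults to all.
#' @param decorrelation Absolute pooled-correlation threshold below which a
#'   pair may serve as the second ratio (default 0.5).
#' @return An object of class `lda_ratio`: list with `pairs` (per-pair
#'   tibble: `numerator`, `denominator`, `ratio`, `D`, `cor_with_best`,
#'   `eligible`), `best` and `second` (one-row tibbles), `second_flagged`,
#'   `D_size`, `D_shape`, `delta`, `ranges` (per-group min-max of the two
#'   reported ratios on the original scale, with overlap flags), `groups`,
#'   `decorrelation`.
#' @export
lda_ratio_extractor <- function(data, groups = NULL, vars = NULL,
                                decorrelation = 0.5) {
  vars <- vars %||% measurement_vars(data)
  groups <- groups %||% unique(data$group)
  if (length(groups) != 2) {
    stop("exactly two groups are required, got ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  data <- dplyr::filter(data, .data$group %in% groups)
  na <- sum(data$group == groups[1])
  nb <- sum(data$group == groups[2])
  if (na < 3 || nb < 3) {
    stop("each group needs at least 3 specimens (got ", na, " and ", nb, ")",
         call. = FALSE)
  }
  validate_measurements(data[c("specimen_id", "group", vars)])
  lm_ <- log_matrix(data, vars)
  in_a <- data$group == groups[1]
  mean_log_a <- colMeans(lm_[in_a, , drop = FALSE])

  pairs <- variable_pairs(vars)
  pairs <- purrr::pmap_dfr(pairs, function(i, j) {
    o <- orient_pair(i, j, mean_log_a)
    r <- lm_[, o[1]] - lm_[, o[2]]
    tibble::tibble(numerator = o[1], denominator = o[2],
                   ratio = paste0(o[1], "/", o[2]),
                   D = standard_distance(r[in_a], r[!in_a]))
  })
  # argmax with lexicographic tie-break on the sorted-name pair key
  key <- purrr::map2_chr(pairs$numerator, pairs$denominator,
                         ~paste(sort(c(.x, .y)), collapse = "/"))
  ord <- order(-pairs$D, key)
  pairs <- pairs[ord, ]
  best <- pairs[1, ]

  best_lr <- lm_[, best$numerator] - lm_[, best$denominator]
  pairs$cor_with_best <- purrr::map2_dbl(
    pairs$numerator, pairs$denominator,
    function(i, j) {
      r <- lm_[, i] - lm_[, j]
      abs(pooled_correlation(best_lr, r, in_a))
    }
  )
  candidates <- pairs[-1, ]
  eligible <- candidates$cor_with_best < decorrelation
  second_flagged <- !any(eligible)
  second <- if (second_flagged) {
    candidates[which.min(candidates$cor_with_best), ]
  } else {
    candidates[eligible, ][1, ]  # pairs already sorted by D
  }
  pairs$eligible <- c(TRUE, eligible)

  log_isosize <- rowMeans(lm_)
  D_size <- standard_distance(log_isosize[in_a], log_isosize[!in_a])
  D_shape <- shape_mahalanobis(sweep(lm_, 1, log_isosize), in_a)

  ranges <- dplyr::bind_rows(
    ratio_range_rows(data, groups, best$numerator, best$denominator,
                     which = "best"),
    ratio_range_rows(data, groups, second$numerator, second$denominator,
                     which = "second")
  )

  structure(
    list(pairs = pairs, best = best, second = second,
         second_flagged = second_flagged,
         D_size = D_size, D_shape = D_shape,
         delta = delta_size_shape(D_size, D_shape),
         ranges = ranges, groups = groups, decorrelation = decorrelation),
    class = "lda_ratio"
  )
}

# |correlation| between two variables under the pooled within-group covariance.
pooled_correlation <- function(x, y, in_a) {
  m <- cbind(x, y)
  s <- pooled_cov(m[in_a, , drop = FALSE], m[!in_a, , drop = FALSE])
  if (s[1, 1] == 0 || s[2, 2] == 0) return(0)
  s[1, 2] / sqrt(s[1, 1] * s[2, 2])
}

# Mahalanobis distance between group means of the clr shape matrix, using the
# pooled within-group covariance pseudoinverted over directions with
# eigenvalue > 1e-12 * lambda_max (the clr subspace has rank <= p - 1).
shape_mahalanobis <- function(shp, in_a) {
  xa <- shp[in_a, , drop = FALSE]
  xb <- shp[!in_a, , drop = FALSE]
  diff <- colMeans(xa) - colMeans(xb)
  s <- pooled_cov(xa, xb)
  eig <- eigen(s, symmetric = TRUE)
  keep <- eig$values > max(eig$values) * 1e-12
  if (!any(keep)) {
    if (sqrt(sum(diff^2)) < 1e-12) return(0)
    stop("pooled within-group shape covariance is singular after restriction",
         call. = FALSE)
  }
  z <- drop(crossprod(eig$vectors[, keep, drop = FALSE], diff))
  sqrt(sum(z^2 / eig$values[keep]))
}

ratio_range_rows <- function(data, groups, num, den, which) {
  purrr::map_dfr(groups, function(g) {
    rr <- ratio_range(data, group = g, pair = c(num, den))
    dplyr::mutate(rr, which = which, .before = 1)
  })
}

#' Range of a measurement ratio within a group
#'
#' @param data A measurement table.
#' @param group Group label.
#' @param pair Character vector `c(numerator, denominator)`.
#' @return One-row tibble: `group`, `ratio`, `min`, `max` (original
#'   measurement scale).
#' @export
ratio_range <- function(data, group, pair) {
  stopifnot(length(pair) == 2, all(pair %in% names(data)))
  sub <- data[data$group == group, ]
  if (nrow(sub) == 0) stop("group `", group, "` is empty", call. = FALSE)
  r <- sub[[pair[1]]] / sub[[pair[2]]]
  tibble::tibble(group = group, ratio = paste0(pair[1], "/", pair[2]),
                 min = min(r), max = max(r))
}

#' Do two groups' ratio ranges overlap?
#'
#' Non-overlapping (or barely overlapping) ranges make a ratio suitable for
#' an identification key.
#'
#' @param data A measurement table.
#' @param groups The two group labels.
#' @param pair Character vector `c(numerator, denominator)`.
#' @return Logical: `TRUE` when the two closed ranges intersect.
#' @export
ratio_overlap <- function(data, groups, pair) {
  stopifnot(length(groups) == 2)
  r1 <- ratio_range(data, groups[1], pair)
  r2 <- ratio_range(data, groups[2], pair)
  r1$min <= r2$max && r2$min <= r1$max
}

#' @export
print.lda_ratio <- function(x, ...) {
  cat("LDA ratio extractor:", x$groups[1], "vs", x$groups[2], "\n")
  cat(sprintf("  best ratio   %s  D = %.2f\n", x$best$ratio, x$best$D))
  cat(sprintf("  second ratio %s  D = %.2f  (|r| with best = %.2f%s)\n",
              x$second$ratio, x$second$D, x$second$cor_with_best,
              if (x$second_flagged) ", no pair under threshold" else ""))
  cat(sprintf("  D_size = %.3f  D_shape = %.3f  delta = %.3f\n",
              x$D_size, x$D_shape, x$delta))
  invisible(x)
}

#' Tidy the per-pair table of an LDA ratio extraction
#'
#' @param x An `lda_ratio` object.
#' @param ... Unused.
#' @return The per-pair tibble sorted by decreasing standard distance.
#' @export
tidy.lda_ratio <- function(x, ...) x$pairs

#' One-row summary of an LDA ratio extraction
#'
#' @param x An `lda_ratio` object.
#' @param ... Unused.
#' @return Tibble with the best/second ratios and distances, the size/shape
#'   decomposition and delta.
#' @export
glance.lda_ratio <- function(x, ...) {
  tibble::tibble(
    group_1 = x$groups[1], group_2 = x$groups[2],
    ratio_best = x$best$ratio, D_best = x$best$D,
    ratio_second = x$second$ratio, D_second = x$second$D,
    decorrelation = x$second$cor_with_best,
    second_flagged = x$second_flagged,
    D_size = x$D_size, D_shape = x$D_shape, delta = x$delta
  )
}
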