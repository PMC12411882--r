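#' PCA ratio spectrum
#'
#' Places each variable at its loading on shape component `component`. The
#' spectrum reads like a ruler: the ratio of two variables explains component
#' variance in proportion to the squared distance between their positions, so
#' the pair at opposite ends forms the ratio that best summarises that shape
#' component, while neighbouring variables form uninformative ratios.
#'
#' @param pca A [shape_pca()] result.
#' @param component Component index.
#' @return A `ratio_spectrum` tibble with columns `variable`, `position`
#'   (positions sum to zero) and attributes `axis_kind`
#'   (`"pca_component_<k>"`) describing the axis.
#' @seealso [ratio_importance()], [bootstrap_spectrum()]
#' @export
pca_ratio_spectrum <- function(pca, component = 1L) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component < 1 || component > pca$n_retained) {
    stop("component out of range (", pca$n_retained, " retained)",
         call. = FALSE)
  }
  new_ratio_spectrum(
    tibble::tibble(variable = pca$vars,
                   position = unname(pca$eigenvectors[, component])),
    axis_kind = paste0("pca_component_", component)
  )
}

new_ratio_spectrum <- function(tbl, axis_kind, n_boot = NULL,
                               level = NULL, n_skipped = NULL) {
  attr(tbl, "axis_kind") <- axis_kind
  if (!is.null(n_boot)) attr(tbl, "n_boot") <- n_boot
  if (!is.null(level)) attr(tbl, "level") <- level
  if (!is.null(n_skipped)) attr(tbl, "n_skipped") <- n_skipped
  class(tbl) <- c("ratio_spectrum", class(tbl))
  tbl
}

#' Allometry ratio spectrum
#'
#' Regresses each shape-space column on log isosize by ordinary least
#' squares; the per-variable slopes are the spectrum positions. They sum to
#' zero by construction (the clr rows do), and under isometry every slope is
#' zero. The ratio of the two variables furthest apart on this spectrum is
#' the most allometric: it changes fastest with size.
#'
#' @param data A measurement table.
#' @param vars Measurement variables to use; defaults to all.
#' @return A `ratio_spectrum` tibble (axis kind `"allometry"`).
#' @export
allometry_ratio_spectrum <- function(data, vars = NULL) {
  vars <- vars %||% measurement_vars(data)
  if (nrow(data) < 4) {
    stop("allometry spectrum needs at least 4 specimens", call. = FALSE)
  }
  shp <- shape_values(data, vars)
  ls <- rowMeans(log_matrix(data, vars))
  if (stats::sd(ls) == 0) {
    stop("log isosize is constant; allometric slopes are undefined",
         call. = FALSE)
  }
  slopes <- allometry_slopes(shp, ls)
  new_ratio_spectrum(
    tibble::tibble(variable = vars, position = slopes),
    axis_kind = "allometry"
  )
}

# OLS slope of every clr column on log isosize in one sweep.
allometry_slopes <- function(shp, log_isosize) {
  x <- log_isosize - mean(log_isosize)
  unname(drop(crossprod(x, sweep(shp, 2, colMeans(shp)))) / sum(x^2))
}

#' Rank variable ratios by their spread on a spectrum
#'
#' The importance of a ratio v_i / v_j on a spectrum is
#' |position_i - position_j|; it is invariant to translating all positions.
#'
#' @param spectrum A `ratio_spectrum` tibble.
#' @return Tibble of all unordered variable pairs with columns `numerator`,
#'   `denominator`, `ratio`, `importance`, sorted by decreasing importance
#'   (ties broken lexicographically by pair name).
#' @export
ratio_importance <- function(spectrum) {
  stopifnot(inherits(spectrum, "ratio_spectrum"))
  pos <- stats::setNames(spectrum$position, spectrum$variable)
  pairs <- variable_pairs(spectrum$variable)
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    # numerator = higher spectrum position, so the ratio grows along the axis
    num <- if (pos[[i]] >= pos[[j]]) i else j
    den <- setdiff(c(i, j), num)
    tibble::tibble(numerator = num, denominator = den,
                   importance = abs(pos[[i]] - pos[[j]]))
  })
  out$ratio <- paste0(out$numerator, "/", out$denominator)
  dplyr::arrange(out[c("numerator", "denominator", "ratio", "importance")],
                 dplyr::desc(.data$importance), .data$ratio)
}

# All unordered pairs in lexicographic order of sorted variable names.
variable_pairs <- function(vars) {
  sv <- sort(vars)
  idx <- utils::combn(length(sv), 2)
  tibble::tibble(i = sv[idx[1, ]], j = sv[idx[2, ]])
}

#' Bootstrap confidence intervals for spectrum positions
#'
#' Resamples specimens with replacement, recomputes the spectrum positions
#' for each replicate and attaches percentile confidence intervals. PCA
#' spectra are sign-aligned to the point estimate (a replicate eigenvector is
#' flipped when its dot product with the original is negative) before taking
#' quantiles. Replicates whose resample leaves some measurement variable
#' constant (or, for the allometry spectrum, constant log isosize) are
#' degenerate, skipped and counted.
#'
#' @param data A measurement table.
#' @param kind `"pca"` or `"allometry"`.
#' @param component Component index (PCA spectra only).
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param level Central coverage of the percentile interval (default 0.68).
#' @param seed Integer seed; required for a reproducible interval.
#' @param vars Measurement variables to use; defaults to all.
#' @param boot_indices Optional list of resample index vectors overriding the
#'   random resampling (one integer vector per replicate); intended for
#'   reproducibility checks.
#' @return A `ratio_spectrum` tibble with `ci_lo`/`ci_hi` columns and
#'   attributes `n_boot`, `level`, `n_skipped`.
#' @export
bootstrap_spectrum <- function(data, kind = c("pca", "allometry"),
                               component = 1L, n_boot = 999L, level = 0.68,
                               seed = NULL, vars = NULL, boot_indices = NULL) {
  kind <- match.arg(kind)
  vars <- vars %||% measurement_vars(data)
  stopifnot(n_boot >= 1, level > 0, level < 1)
  point <- switch(kind,
    pca = pca_ratio_spectrum(shape_pca(data, vars), component),
    allometry = allometry_ratio_spectrum(data, vars)
  )
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  if (is.null(boot_indices)) {
    boot_indices <- purrr::map(seq_len(n_boot),
                               ~sample.int(n, n, replace = TRUE))
  }
  ref <- point$position
  reps <- matrix(NA_real_, nrow = length(ref), ncol = length(boot_indices))
  skipped <- 0L
  for (b in seq_along(boot_indices)) {
    res <- data[boot_indices[[b]], , drop = FALSE]
    res$specimen_id <- paste0("b", seq_len(nrow(res)))
    lm_ <- log(as.matrix(res[vars]))
    degenerate <- any(apply(lm_, 2, stats::sd) == 0) ||
      (kind == "allometry" && stats::sd(rowMeans(lm_)) == 0)
    if (degenerate) {
      skipped <- skipped + 1L
      next
    }
    pos <- switch(kind,
      pca = {
        v <- shape_pca(res, vars)$eigenvectors[, component]
        if (sum(v * ref) < 0) -v else v
      },
      allometry = allometry_slopes(shape_values(res, vars),
                                   rowMeans(lm_))
    )
    reps[, b] <- pos
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  kept <- reps[, colSums(is.na(reps)) == 0, drop = FALSE]
  if (ncol(kept) == 0) {
    stop("all bootstrap replicates were degenerate", call. = FALSE)
  }
  ci <- apply(kept, 1, stats::quantile, probs = probs)
  point$ci_lo <- pmin(ci[1, ], point$position)
  point$ci_hi <- pmax(ci[2, ], point$position)
  new_ratio_spectrum(point, axis_kind = attr(point, "axis_kind"),
                     n_boot = length(boot_indices), level = level,
                     n_skipped = skipped)
}
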