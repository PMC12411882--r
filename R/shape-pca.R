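#' Principal component analysis in shape space
#'
#' Eigendecomposition of the sample covariance (divisor n - 1) of the
#' centered log-ratio shape matrix. Because every shape row sums to zero,
#' the analysis lives in a (p - 1)-dimensional subspace orthogonal to the
#' isometric direction: at most p - 1 eigenvalues are nonzero and every
#' eigenvector's components sum to zero. Working on the covariance (not
#' correlation) matrix is deliberate — the log-ratio transform already puts
#' all variables on a common dimensionless scale.
#'
#' Each eigenvector is oriented so its largest-magnitude loading is positive.
#'
#' @param data A measurement table (`specimen_id`, `group`, measurement
#'   columns); see [read_measurements()].
#' @param vars Measurement variables to use; defaults to all.
#' @return An object of class `shape_pca`: a list with `isosize`,
#'   `log_isosize`, `shape` (specimens x variables clr matrix),
#'   `eigenvectors` (variables x components), `eigenvalues`, `pct_variance`,
#'   `scores` (specimens x components), `n_retained` (components with
#'   nonzero variance), plus the `specimen_id`, `group` and `vars` used.
#' @seealso [pca_ratio_spectrum()], [size_shape_correlation()], [tidy.shape_pca()]
#' @export
shape_pca <- function(data, vars = NULL) {
  vars <- vars %||% measurement_vars(data)
  if (nrow(data) < 3) {
    stop("shape PCA needs at least 3 specimens", call. = FALSE)
  }
  shp <- shape_values(data, vars)
  centered <- sweep(shp, 2, colMeans(shp))
  eig <- eigen(stats::cov(shp), symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  nonzero <- vals > max(vals[1], .Machine$double.eps) * 1e-12
  vecs <- eig$vectors
  # retained components live in the zero-sum clr subspace; strip the tiny
  # numerical drift along the isometric direction before orienting
  for (k in which(nonzero)) {
    v <- vecs[, k] - mean(vecs[, k])
    vecs[, k] <- v / sqrt(sum(v^2))
  }
  vecs <- apply(vecs, 2, orient_vector)
  dimnames(vecs) <- list(vars, paste0("PC", seq_along(vals)))
  total <- sum(vals)
  pct <- if (total > 0) 100 * vals / total else rep(0, length(vals))
  scores <- centered %*% vecs
  structure(
    list(
      specimen_id = data$specimen_id,
      group = data$group,
      vars = vars,
      isosize = exp(unname(rowMeans(log_matrix(data, vars)))),
      log_isosize = unname(rowMeans(log_matrix(data, vars))),
      shape = shp,
      eigenvectors = vecs,
      eigenvalues = vals,
      pct_variance = pct,
      scores = scores,
      n_retained = sum(vals > max(vals[1], .Machine$double.eps) * 1e-12)
    ),
    class = "shape_pca"
  )
}

# Sign convention: the largest-|loading| entry of each eigenvector is positive.
orient_vector <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape-space PCA:", length(x$specimen_id), "specimens,",
      length(x$vars), "variables\n")
  k <- min(3, x$n_retained)
  cat("  % variance (first ", k, "): ",
      paste(sprintf("%.1f", x$pct_variance[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a shape PCA into a long loading table
#'
#' @param x A `shape_pca` object.
#' @param ... Unused.
#' @return Tibble with `variable`, `component`, `loading`.
#' @export
tidy.shape_pca <- function(x, ...) {
  tibble::as_tibble(x$eigenvectors, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' One-row summary of a shape PCA
#'
#' @param x A `shape_pca` object.
#' @param ... Unused.
#' @return Tibble with specimen/variable counts, the nonzero-component count
#'   and the variance shares of the first two components.
#' @export
glance.shape_pca <- function(x, ...) {
  tibble::tibble(
    n_specimens = length(x$specimen_id),
    n_variables = length(x$vars),
    n_retained = x$n_retained,
    pct_pc1 = x$pct_variance[1],
    pct_pc2 = if (length(x$pct_variance) > 1) x$pct_variance[2] else NA_real_
  )
}

#' Per-specimen scores and size for a shape PCA
#'
#' @param x A `shape_pca` object.
#' @param ... Unused.
#' @return Tibble with `specimen_id`, `group`, `isosize`, `log_isosize` and
#'   one column per component score.
#' @export
augment.shape_pca <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(specimen_id = x$specimen_id, group = x$group,
                   isosize = x$isosize, log_isosize = x$log_isosize),
    tibble::as_tibble(x$scores)
  )
}

#' Correlation between isometric size and a shape component
#'
#' Pearson correlation of log isosize with the scores of shape component
#' `component`, with the closed-form t statistic
#' t = r * sqrt(df / (1 - r^2)), df = n - 2, and a two-sided p-value from the
#' t distribution. A strong correlation signals allometry: that shape
#' component tracks size. Perfectly collinear scores give |r| = 1 and are
#' reported with an unbounded t (p = 0) and `degenerate = TRUE`.
#'
#' @param pca A `shape_pca` object.
#' @param component Component index (default 1).
#' @return One-row tibble: `component`, `r`, `t`, `df`, `p`, `degenerate`.
#' @export
size_shape_correlation <- function(pca, component = 1L) {
  stopifnot(inherits(pca, "shape_pca"))
  if (component < 1 || component > pca$n_retained) {
    stop("component out of range (", pca$n_retained, " retained)",
         call. = FALSE)
  }
  s <- pca$scores[, component]
  if (stats::sd(s) == 0) {
    stop("component scores have zero variance", call. = FALSE)
  }
  n <- length(s)
  r <- stats::cor(pca$log_isosize, s)
  df <- n - 2L
  degenerate <- abs(r) >= 1 - 1e-12
  t <- if (degenerate) sign(r) * Inf else r * sqrt(df / (1 - r^2))
  p <- if (degenerate) 0 else 2 * stats::pt(-abs(t), df)
  tibble::tibble(component = as.integer(component), r = r, t = t,
                 df = df, p = p, degenerate = degenerate)
}
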