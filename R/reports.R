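#' Identification-key style report of an LDA ratio extraction
#'
#' Formats the best and second ratios of an [lda_ratio_extractor()] result
#' as one row each, mirroring the comparison tables of taxonomic revisions:
#' per-group ratio ranges (2 decimals), standard distance and delta
#' (2 decimals), and a `key_suitable` flag set when the two groups' ranges
#' do not overlap.
#'
#' @param x An `lda_ratio` object.
#' @param comparison Label for the comparison column; defaults to
#'   `"<group1>-<group2>"`.
#' @param digits Decimals used for ranges, D and delta (default 2).
#' @return Tibble with `comparison`, `best_ratio`, `range_group1`,
#'   `range_group2`, `standard_distance`, `delta`, `key_suitable`.
#' @export
mra_report <- function(x, comparison = NULL, digits = 2) {
  stopifnot(inherits(x, "lda_ratio"))
  comparison <- comparison %||% paste(x$groups, collapse = "-")
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  row_for <- function(which, ratio_row) {
    rr <- x$ranges[x$ranges$which == which, ]
    r1 <- rr[rr$group == x$groups[1], ]
    r2 <- rr[rr$group == x$groups[2], ]
    overlap <- r1$min <= r2$max && r2$min <= r1$max
    tibble::tibble(
      comparison = comparison,
      best_ratio = ratio_row$ratio,
      range_group1 = sprintf("%s–%s", fmt(r1$min), fmt(r1$max)),
      range_group2 = sprintf("%s–%s", fmt(r2$min), fmt(r2$max)),
      standard_distance = round(ratio_row$D, digits),
      delta = round(x$delta, digits),
      key_suitable = !overlap
    )
  }
  dplyr::bind_rows(row_for("best", x$best), row_for("second", x$second))
}

#' Run the full morphometric ratio pipeline and write its reports
#'
#' Orchestrates shape PCA, both ratio spectra (with bootstrap confidence
#' intervals), size-shape correlations and the LDA ratio extractor for one
#' two-group comparison, and writes machine-readable reports to `out_dir`:
#' `mra_report.tsv` (the identification-key table), `shape_pca.json`,
#' `lda_ratio.json`, `spectra.json` (spectrum coordinates with confidence
#' bounds) and `manifest.json` (inputs, seed, parameters, package version).
#' Outputs are byte-reproducible for a given table, groups and seed; no
#' timestamps are written.
#'
#' @param data A measurement table.
#' @param groups The two group labels to compare; defaults to the two
#'   groups present.
#' @param vars Measurement variables; defaults to all.
#' @param n_boot Bootstrap replicates for the spectra (default 999).
#' @param level Bootstrap confidence level (default 0.68).
#' @param seed Integer seed for the bootstrap.
#' @param out_dir Output directory, created if missing; `NULL` skips
#'   writing.
#' @return Invisibly, a list with `pca`, `lda`, `spectra` (list of
#'   `ratio_spectrum` tibbles), `correlations`, `report`, `manifest`.
#' @export
run_mra <- function(data, groups = NULL, vars = NULL, n_boot = 999L,
                    level = 0.68, seed = 1L, out_dir = NULL) {
  vars <- vars %||% measurement_vars(data)
  groups <- groups %||% unique(data$group)
  if (length(groups) != 2) {
    stop("exactly two groups are required", call. = FALSE)
  }
  data <- dplyr::filter(data, .data$group %in% groups)
  validate_measurements(data[c("specimen_id", "group", vars)])

  pca <- shape_pca(data, vars)
  spectra <- list(
    pc1 = bootstrap_spectrum(data, "pca", component = 1L, n_boot = n_boot,
                             level = level, seed = seed, vars = vars),
    pc2 = if (pca$n_retained >= 2)
      bootstrap_spectrum(data, "pca", component = 2L, n_boot = n_boot,
                         level = level, seed = seed, vars = vars),
    allometry = bootstrap_spectrum(data, "allometry", n_boot = n_boot,
                                   level = level, seed = seed, vars = vars)
  )
  spectra <- purrr::compact(spectra)
  correlations <- purrr::map_dfr(seq_len(min(2L, pca$n_retained)),
                                 ~size_shape_correlation(pca, .x))
  lda <- lda_ratio_extractor(data, groups = groups, vars = vars)
  report <- mra_report(lda)
  manifest <- list(
    package = "ratiotax",
    version = as.character(utils::packageVersion("ratiotax")),
    n_specimens = nrow(data), groups = groups, variables = vars,
    n_boot = n_boot, level = level, seed = seed,
    data_hash = digest_table(data[c("specimen_id", "group", vars)])
  )
  result <- list(pca = pca, lda = lda, spectra = spectra,
                 correlations = correlations, report = report,
                 manifest = manifest)
  if (!is.null(out_dir)) write_mra_reports(result, out_dir)
  invisible(result)
}

# Seed-free content fingerprint so a manifest pins its inputs without
# binary serialisation.
digest_table <- function(data) {
  txt <- paste(utils::capture.output(
    utils::write.csv(as.data.frame(data), row.names = FALSE)),
    collapse = "\n")
  sprintf("crc32:%s", format(sum(utf8ToInt(txt) *
                                   (seq_along(utf8ToInt(txt)) %% 9973)),
                             scientific = FALSE))
}

write_mra_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(result$report, file.path(out_dir, "mra_report.tsv"))
  pca <- result$pca
  jsonlite::write_json(
    list(eigenvalues = pca$eigenvalues, pct_variance = pca$pct_variance,
         eigenvectors = as.data.frame(pca$eigenvectors),
         scores = as.data.frame(pca$scores),
         isosize = pca$isosize, specimen_id = pca$specimen_id,
         group = pca$group),
    file.path(out_dir, "shape_pca.json"), auto_unbox = TRUE, digits = NA
  )
  lda <- result$lda
  jsonlite::write_json(
    list(pairs = lda$pairs, best = lda$best, second = lda$second,
         second_flagged = lda$second_flagged, D_size = lda$D_size,
         D_shape = lda$D_shape, delta = lda$delta, ranges = lda$ranges),
    file.path(out_dir, "lda_ratio.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    purrr::map(result$spectra, function(s) {
      list(axis_kind = attr(s, "axis_kind"), n_boot = attr(s, "n_boot"),
           level = attr(s, "level"), n_skipped = attr(s, "n_skipped"),
           positions = as.data.frame(s))
    }),
    file.path(out_dir, "spectra.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
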