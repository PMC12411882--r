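#' Kimura two-parameter distance between two aligned sequences
#'
#' Over the compared columns (both characters unambiguous bases, optionally
#' restricted to `mask`), P is the proportion of transition-differing sites
#' (A<->G, C<->T), Q the proportion of transversion-differing sites, and
#' d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q)) substitutions per site. The
#' estimator is undefined at saturation (1 - 2P - Q <= 0 or 1 - 2Q <= 0);
#' such pairs are returned with `d = NA` and `saturated = TRUE` rather than
#' a non-number propagating silently. Rates are assumed uniform across sites
#' (no gamma correction).
#'
#' @param seq1,seq2 Aligned sequences of equal length (character strings).
#' @param mask Optional integer vector of 1-based columns to consider (e.g.
#'   a complete-deletion mask); by default all columns are candidates.
#' @return One-row tibble: `P`, `Q`, `n_sites` (compared columns), `d`,
#'   `pct` (100 d), `saturated`.
#' @export
#' @examples
#' k2p_pair("AAAAAAAAAA", "GAAAAAAAAC")$d  # one transition + one
#'                                         # transversion in 10 sites: 0.2341
k2p_pair <- function(seq1, seq2, mask = NULL) {
  stopifnot(nchar(seq1) == nchar(seq2))
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  if (!is.null(mask)) {
    a <- a[mask]
    b <- b[mask]
  }
  k2p_from_chars(a, b)
}

purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

k2p_from_chars <- function(a, b) {
  ok <- a %in% names(purine) & b %in% names(purine)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n == 0) {
    return(tibble::tibble(P = NA_real_, Q = NA_real_, n_sites = 0L,
                          d = NA_real_, pct = NA_real_, saturated = FALSE))
  }
  diff <- a != b
  ts <- diff & (purine[a] == purine[b])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(w1 * sqrt(w2)) + 0  # +0 clears IEEE -0
  tibble::tibble(P = P, Q = Q, n_sites = n, d = d, pct = 100 * d,
                 saturated = saturated)
}

#' All pairwise K2P distances of an alignment
#'
#' Computes [k2p_pair()] for every unordered sequence pair under the chosen
#' deletion policy. Complete deletion (the default) first removes every
#' column holding a gap or missing character in any sequence, so all pairs
#' share one site set; pairwise deletion masks each pair separately.
#'
#' @param aln A [locus_alignment()].
#' @param deletion `"complete"` or `"pairwise"`.
#' @return Long tibble with `id1`, `id2` (input order, `id1` before `id2`)
#'   and the [k2p_pair()] columns.
#' @export
k2p_distances <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "locus_alignment"))
  n <- length(aln$seqs)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  m <- alignment_matrix(aln)
  if (deletion == "complete") {
    m <- m[, deletion_mask(aln, "complete"), drop = FALSE]
  }
  idx <- utils::combn(n, 2)
  purrr::map_dfr(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    dplyr::bind_cols(
      tibble::tibble(id1 = names(aln$seqs)[i], id2 = names(aln$seqs)[j]),
      k2p_from_chars(m[i, ], m[j, ])
    )
  })
}

#' Square K2P distance matrix
#'
#' @param distances Long tibble from [k2p_distances()].
#' @param value Column to tabulate, `"d"` (default) or `"pct"`.
#' @return Symmetric numeric matrix with zero diagonal; saturated pairs are
#'   `NA`.
#' @export
k2p_matrix <- function(distances, value = c("d", "pct")) {
  value <- match.arg(value)
  ids <- unique(c(distances$id1, distances$id2))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(distances$id1, distances$id2)] <- distances[[value]]
  m[cbind(distances$id2, distances$id1)] <- distances[[value]]
  m
}

#' Within- and between-group K2P distance summaries
#'
#' Summarises pairwise distances per group comparison: within-group rows use
#' all unordered distinct pairs inside a group (groups with fewer than two
#' members are omitted with a message), between-group rows all cross pairs.
#' Saturated pairs are excluded from the statistics and counted.
#'
#' @param distances Long tibble from [k2p_distances()].
#' @param population_map Tibble with `specimen_id` and `group` columns
#'   assigning every sequence to exactly one group.
#' @return Tibble with `comparison`, `type` (`"within"`/`"between"`), `min`,
#'   `max`, `mean` (percent scale), `n_pairs`, `n_saturated`.
#' @export
group_distance_summary <- function(distances, population_map) {
  stopifnot(all(c("specimen_id", "group") %in% names(population_map)))
  ids <- unique(c(distances$id1, distances$id2))
  unmapped <- setdiff(ids, population_map$specimen_id)
  if (length(unmapped)) {
    stop("sequences without a group: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  grp <- stats::setNames(population_map$group, population_map$specimen_id)
  d <- dplyr::mutate(distances, g1 = unname(grp[.data$id1]),
                     g2 = unname(grp[.data$id2]))
  groups <- unique(unname(grp[ids]))

  summarise_pairs <- function(sub, comparison, type) {
    if (nrow(sub) == 0) return(NULL)
    ok <- sub[!sub$saturated & !is.na(sub$d), ]
    tibble::tibble(
      comparison = comparison, type = type,
      min = if (nrow(ok)) min(ok$pct) else NA_real_,
      max = if (nrow(ok)) max(ok$pct) else NA_real_,
      mean = if (nrow(ok)) mean(ok$pct) else NA_real_,
      n_pairs = nrow(ok), n_saturated = sum(sub$saturated)
    )
  }

  within <- purrr::map_dfr(groups, function(g) {
    sub <- d[d$g1 == g & d$g2 == g, ]
    if (nrow(sub) == 0) {
      message("group `", g, "` has < 2 members; within-group row omitted")
      return(NULL)
    }
    summarise_pairs(sub, paste("Within", g), "within")
  })
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else
    matrix(character(), 2, 0)
  between <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    sub <- d[(d$g1 == g1 & d$g2 == g2) | (d$g1 == g2 & d$g2 == g1), ]
    summarise_pairs(sub, paste("Between", g1, "and", g2), "between")
  })
  dplyr::bind_rows(within, between)
}

#' Format a distance summary like a published range table
#'
#' @param summary Tibble from [group_distance_summary()].
#' @param digits Decimals for the percent values (default 1).
#' @return Tibble with `comparison` and `range` strings of the form
#'   `"18.7-20.1 (19.4)"`.
#' @export
format_distance_summary <- function(summary, digits = 1) {
  fmt <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  tibble::tibble(
    comparison = summary$comparison,
    range = sprintf("%s–%s (%s)", fmt(summary$min), fmt(summary$max),
                    fmt(summary$mean))
  )
}
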