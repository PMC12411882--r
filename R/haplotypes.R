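#' Collapse an alignment to haplotypes
#'
#' Two specimens share a haplotype exactly when their aligned sequences are
#' identical strings after uppercasing. Gaps and `N` count as ordinary
#' characters: no IUPAC ambiguity subsumption is attempted, so sequences
#' differing only at an `N`-bearing column are distinct haplotypes (this can
#' diverge from ambiguity-aware collapsers). Labels are `<locus> <k>` with k
#' numbered by first occurrence in input order.
#'
#' @param aln A [locus_alignment()].
#' @return A `haplotype_table`: tibble with `specimen_id`, `haplotype`, plus
#'   a `haplotypes` attribute (tibble of `haplotype`, `sequence`, `count`)
#'   and a `locus` attribute.
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "locus_alignment"))
  canon <- unique(unname(aln$seqs))
  k <- match(unname(aln$seqs), canon)
  labels <- paste(aln$locus, seq_along(canon))
  out <- tibble::tibble(specimen_id = names(aln$seqs),
                        haplotype = labels[k])
  attr(out, "haplotypes") <- tibble::tibble(
    haplotype = labels,
    sequence = canon,
    count = as.integer(table(factor(k, levels = seq_along(canon))))
  )
  attr(out, "locus") <- aln$locus
  class(out) <- c("haplotype_table", class(out))
  out
}

#' Haplotype inventory of a collapse
#'
#' @param x A `haplotype_table` from [collapse_haplotypes()].
#' @return Tibble of `haplotype`, `sequence`, `count`.
#' @export
haplotype_counts <- function(x) {
  stopifnot(inherits(x, "haplotype_table"))
  attr(x, "haplotypes")
}

#' Concatenate loci into a multilocus alignment with a haplotype ledger
#'
#' Joins the per-locus sequences of every specimen present in all loci, in
#' the given locus order, and records a ledger mapping each specimen's tuple
#' of per-locus haplotype labels to its concatenated haplotype label. Because
#' haplotype identity is exact string identity, two specimens share a
#' concatenated label exactly when they share every per-locus label, and the
#' concatenated partition refines each single-locus partition.
#'
#' @param alns List of [locus_alignment()] objects in concatenation order.
#' @param strict If `TRUE`, a specimen missing from any locus is an error;
#'   by default such specimens are dropped with a warning (mirroring
#'   multilocus datasets where some loci failed to amplify).
#' @return An object of class `concatenation`: list with
#'   `alignment` (the concatenated [locus_alignment()]), `scheme` (tibble of
#'   `locus`, `length`, `start`, `end` — 0-based half-open column intervals)
#'   and `ledger` (tibble: `specimen_id`, one haplotype column per locus,
#'   `concatenated`).
#' @export
concatenate_loci <- function(alns, strict = FALSE) {
  stopifnot(length(alns) >= 2, all(purrr::map_lgl(alns, inherits,
                                                  "locus_alignment")))
  loci <- purrr::map_chr(alns, "locus")
  if (anyDuplicated(loci)) stop("duplicated locus names", call. = FALSE)
  ids <- purrr::map(alns, ~names(.x$seqs))
  shared <- purrr::reduce(ids, intersect)
  missing <- setdiff(purrr::reduce(ids, union), shared)
  if (length(missing)) {
    msg <- paste0("specimens missing from some locus: ",
                  paste(missing, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (length(shared) == 0) stop("no specimen present in all loci",
                                call. = FALSE)

  lengths <- purrr::map_int(alns, "length")
  scheme <- tibble::tibble(
    locus = loci,
    length = lengths,
    start = cumsum(c(0L, lengths[-length(lengths)])),
    end = cumsum(lengths)
  )

  parts <- purrr::map(alns, ~.x$seqs[shared])
  concat_name <- paste(loci, collapse = "+")
  concat <- locus_alignment(
    stats::setNames(do.call(paste0, parts), shared),
    locus = concat_name
  )

  per_locus <- purrr::map(alns, function(a) {
    sub <- locus_alignment(a$seqs[shared], locus = a$locus)
    h <- collapse_haplotypes(sub)
    stats::setNames(h$haplotype, h$specimen_id)
  })
  ledger <- tibble::tibble(specimen_id = shared)
  for (i in seq_along(loci)) ledger[[loci[i]]] <- unname(per_locus[[i]])
  ch <- collapse_haplotypes(concat)
  ledger$concatenated <- ch$haplotype[match(shared, ch$specimen_id)]

  structure(list(alignment = concat, scheme = scheme, ledger = ledger),
            class = "concatenation")
}

#' @export
print.concatenation <- function(x, ...) {
  cat("<concatenation> ", x$alignment$locus, ": ",
      length(x$alignment$seqs), " specimens x ", x$alignment$length,
      " columns (", paste(x$scheme$length, collapse = " + "), ")\n", sep = "")
  invisible(x)
}
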