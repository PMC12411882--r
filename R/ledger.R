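#' Read an accession/haplotype ledger
#'
#' Reads a long-format TSV listing, per specimen and locus, the sequence
#' accession and (for sequences newly generated by a study) the haplotype
#' label assigned at that locus. The packaged fixture
#' `monacha_table1.tsv` transcribes the specimen ledger of a *Monacha*
#' land-snail survey (Corfu and comparison populations): columns
#' `specimen_id`, `population`, `species_group`, `locus`, `haplotype`
#' (`NA` for sequences reused from public repositories), `accession`.
#'
#' @param path Path to a ledger TSV; default the packaged fixture.
#' @return A tibble with the columns above.
#' @export
read_accession_ledger <- function(path = NULL) {
  path <- path %||% system.file("extdata", "monacha_table1.tsv",
                                package = "ratiotax", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    specimen_id = readr::col_character(),
    population = readr::col_character(),
    species_group = readr::col_character(),
    locus = readr::col_character(),
    haplotype = readr::col_character(),
    accession = readr::col_character()
  ))
}

#' Number of accessions spanned by an inclusive accession range
#'
#' Accession ranges such as `"PP947873-PP947923"` are dense inclusive spans:
#' the count is last - first + 1 on the numeric suffix (51 here). A single
#' accession counts as 1. En dashes are accepted as separators.
#'
#' @param range Character vector of accession ranges (or single accessions).
#' @return Integer vector of span counts.
#' @export
accession_span <- function(range) {
  purrr::map_int(range, function(r) {
    parts <- stringr::str_split_1(r, "[-–]")
    parts <- parts[parts != ""]
    if (length(parts) == 1) return(1L)
    if (length(parts) != 2) {
      stop("malformed accession range: ", r, call. = FALSE)
    }
    nums <- stringr::str_match(parts, "^([A-Za-z]+)(\\d+)$")
    if (anyNA(nums[, 1]) || nums[1, 2] != nums[2, 2]) {
      stop("malformed accession range: ", r, call. = FALSE)
    }
    n <- as.integer(nums[2, 3]) - as.integer(nums[1, 3]) + 1L
    if (n < 1) stop("malformed accession range: ", r, call. = FALSE)
    n
  })
}

#' Per-locus sequence and haplotype counts of a ledger
#'
#' Counts, per locus, the newly generated sequences (rows carrying a
#' haplotype label) and the distinct haplotype labels among them. Accessions
#' must be unique across the ledger.
#'
#' @param ledger Tibble from [read_accession_ledger()].
#' @return Tibble with `locus`, `n_sequences`, `n_haplotypes`; zero-row
#'   ledgers give a zero-row result.
#' @export
ledger_stats <- function(ledger) {
  stopifnot(all(c("locus", "haplotype", "accession") %in% names(ledger)))
  acc <- ledger$accession[!is.na(ledger$accession)]
  if (anyDuplicated(acc)) {
    stop("duplicated accessions: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  ledger |>
    dplyr::filter(!is.na(.data$haplotype)) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(n_sequences = dplyr::n(),
                     n_haplotypes = dplyr::n_distinct(.data$haplotype),
                     .groups = "drop")
}
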