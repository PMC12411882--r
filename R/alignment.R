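#' Construct a locus alignment
#'
#' A light container for one pre-aligned locus: a named character vector of
#' equal-length, uppercased sequences over a configurable alphabet
#' (default `A C G T N -`). Sequences are assumed pre-oriented; no
#' reverse-complement detection is attempted.
#'
#' @param seqs Named character vector, one aligned sequence per specimen.
#' @param locus Locus name (e.g. `"COI"`, `"16S"`, `"ITS2"`).
#' @param alphabet Allowed characters after uppercasing.
#' @return An object of class `locus_alignment`: list with `locus`, `seqs`,
#'   `length` (alignment columns).
#' @export
locus_alignment <- function(seqs, locus = "locus",
                            alphabet = c("A", "C", "G", "T", "N", "-")) {
  if (length(seqs) == 0) stop("empty alignment", call. = FALSE)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named by specimen id", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicated specimen ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  }
  used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(used, alphabet)
  if (length(bad)) {
    stop("characters outside alphabet: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  structure(list(locus = locus, seqs = seqs, length = unname(lens[1])),
            class = "locus_alignment")
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("<locus_alignment> ", x$locus, ": ", length(x$seqs), " sequences x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param locus Locus name to record.
#' @param alphabet Allowed characters after uppercasing.
#' @return A [locus_alignment()].
#' @export
read_alignment <- function(path, locus = "locus",
                           alphabet = c("A", "C", "G", "T", "N", "-")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  locus_alignment(stats::setNames(as.character(set), names(set)),
                  locus = locus, alphabet = alphabet)
}

#' Write an alignment to FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param aln A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "locus_alignment"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path,
                              width = 70L)
  invisible(path)
}

#' Trim an alignment to a column interval
#'
#' Columns are addressed 0-based, half-open: `trim_alignment(aln, 40, 655)`
#' keeps 615 columns. `trim_alignment(aln, 0, aln$length)` is the identity.
#'
#' @param aln A [locus_alignment()].
#' @param start,end 0-based half-open column interval, `0 <= start < end <=
#'   length`.
#' @return The trimmed [locus_alignment()].
#' @export
trim_alignment <- function(aln, start, end) {
  stopifnot(inherits(aln, "locus_alignment"))
  if (!(start >= 0 && start < end && end <= aln$length)) {
    stop("invalid trim interval [", start, ", ", end, ") for length ",
         aln$length, call. = FALSE)
  }
  locus_alignment(substr(aln$seqs, start + 1L, end), locus = aln$locus)
}

# Character matrix view (sequences x columns), computed once per analysis.
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  m
}

#' Columns retained by a deletion policy
#'
#' Complete deletion drops every column in which any sequence carries a gap
#' or missing character, yielding a single mask shared by all pairs;
#' pairwise deletion defers masking to each pair (a column is used for a
#' pair when both of its characters are unambiguous bases).
#'
#' @param aln A [locus_alignment()].
#' @param policy `"complete"` or `"pairwise"`.
#' @return For `"complete"`, an integer vector of retained (1-based) column
#'   indices. For `"pairwise"`, a logical matrix (sequences x columns);
#'   the mask of a pair (i, j) is `which(m[i, ] & m[j, ])`.
#' @export
deletion_mask <- function(aln, policy = c("complete", "pairwise")) {
  policy <- match.arg(policy)
  good <- matrix(alignment_matrix(aln) %in% c("A", "C", "G", "T"),
                 nrow = length(aln$seqs),
                 dimnames = list(names(aln$seqs), NULL))
  if (policy == "complete") which(colSums(good) == nrow(good)) else good
}
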