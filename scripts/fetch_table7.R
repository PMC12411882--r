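#!/usr/bin/env Rscript
# OPTIONAL, NETWORK-DEPENDENT helper; not part of the test suite.
#
# Downloads the deposited COI sequences referenced by the packaged specimen
# ledger from GenBank, aligns nothing (sequences are used as deposited and
# must be pre-trimmed/aligned to a common 615-column frame before distance
# work; see the vignette), applies complete deletion and reproduces the
# within/between K2P distance summary table for the Monacha species groups.
#
# Usage: Rscript scripts/fetch_table7.R --out table7.tsv

suppressMessages({
  library(optparse)
  library(ratiotax)
  library(ape)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "table7.tsv"),
  make_option("--aligned-fasta", type = "character", default = NULL,
              help = "skip the download and use a pre-aligned COI FASTA")
)))

ledger <- read_accession_ledger()
coi <- dplyr::filter(ledger, locus == "COI")

if (is.null(opts$`aligned-fasta`)) {
  message("fetching ", nrow(coi), " COI accessions from GenBank ...")
  seqs <- ape::read.GenBank(coi$accession)
  mat <- as.character(seqs)
  # deposited COI fragments are of slightly different spans; align before
  # distance work (mafft is a common choice)
  tmp <- tempfile(fileext = ".fas")
  ape::write.dna(seqs, tmp, format = "fasta")
  aligned <- tempfile(fileext = ".fas")
  status <- system2("mafft", c("--auto", "--quiet", tmp), stdout = aligned)
  if (status != 0) stop("mafft failed; supply --aligned-fasta instead")
  aln <- read_alignment(aligned, locus = "COI")
  names(aln$seqs) <- coi$specimen_id[match(names(aln$seqs), coi$accession)]
} else {
  aln <- read_alignment(opts$`aligned-fasta`, locus = "COI")
}

map <- dplyr::distinct(coi[c("specimen_id", "species_group")])
names(map)[2] <- "group"
summary <- group_distance_summary(k2p_distances(aln, "complete"), map)
readr::write_tsv(format_distance_summary(summary), opts$out)
message("wrote ", opts$out)
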