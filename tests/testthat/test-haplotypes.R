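test_that("collapsing groups identical strings and numbers by first occurrence", {
  h <- collapse_haplotypes(aln_of(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"),
                                  locus = "L", ids = c("s1", "s2", "s3")))
  expect_equal(h$haplotype, c("L 1", "L 1", "L 2"))
  expect_equal(haplotype_counts(h)$count, c(2L, 1L))

  # the observed sharing pattern of a six-specimen population: 1,1,2,3,3,3
  seqs <- c("AAAA", "AAAA", "AAAT", "AATT", "AATT", "AATT")
  h <- collapse_haplotypes(aln_of(seqs, locus = "COI"))
  expect_equal(dplyr::n_distinct(h$haplotype), 3)
  expect_equal(as.integer(factor(h$haplotype, unique(h$haplotype))),
               c(1L, 1L, 2L, 3L, 3L, 3L))
})

test_that("gaps and N are ordinary characters for haplotype identity", {
  h <- collapse_haplotypes(aln_of(c("ACNT", "ACGT", "AC-T")))
  expect_equal(dplyr::n_distinct(h$haplotype), 3)
})

test_that("collapsing is a partition and idempotent on representatives", {
  a <- random_aln(12, 30, seed = 40)
  # duplicate a few sequences to create classes
  a$seqs[4] <- a$seqs[1]; a$seqs[9] <- a$seqs[1]; a$seqs[7] <- a$seqs[2]
  a <- locus_alignment(a$seqs, locus = a$locus)
  h <- collapse_haplotypes(a)
  counts <- haplotype_counts(h)
  expect_setequal(h$specimen_id, names(a$seqs))       # covers all specimens
  expect_equal(sum(counts$count), length(a$seqs))     # classes sum to n
  expect_false(anyDuplicated(counts$sequence) > 0)    # classes disjoint

  reps <- locus_alignment(setNames(counts$sequence, counts$haplotype),
                          locus = "L")
  h2 <- collapse_haplotypes(reps)
  expect_equal(dplyr::n_distinct(h2$haplotype), nrow(counts))
})

test_that("concatenation lengths are additive and the ledger tracks haplotypes", {
  coi <- random_aln(6, 615, seed = 1, locus = "COI")
  s16 <- random_aln(6, 871, seed = 2, locus = "16S")
  its <- random_aln(6, 778, seed = 3, locus = "ITS2")

  two <- concatenate_loci(list(coi, s16))
  expect_equal(two$alignment$length, 1486)
  expect_equal(two$scheme$start, c(0L, 615L))
  expect_equal(two$scheme$end, c(615L, 1486L))

  three <- concatenate_loci(list(coi, s16, its))
  expect_equal(three$alignment$length, 2264)
  expect_equal(unname(substr(three$alignment$seqs[1], 616, 1486)),
               unname(s16$seqs[1]))
})

test_that("specimens sharing all but one locus split only in the larger scheme", {
  # two specimens share COI and 16S haplotypes but differ at ITS2
  coi <- aln_of(rep("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC", 3),
                locus = "COI", ids = c("x", "y", "z"))
  s16 <- aln_of(rep("TTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCATTGCA", 3),
                locus = "16S", ids = c("x", "y", "z"))
  its <- aln_of(c("AAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAA",
                  "AAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAT",
                  "AAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAAAACCCCGGGGTTTTAA"),
                locus = "ITS2", ids = c("x", "y", "z"))
  two <- concatenate_loci(list(coi, s16))
  three <- concatenate_loci(list(coi, s16, its))
  l2 <- setNames(two$ledger$concatenated, two$ledger$specimen_id)
  l3 <- setNames(three$ledger$concatenated, three$ledger$specimen_id)
  expect_equal(unname(l2["x"]), unname(l2["y"]))
  expect_false(l3[["x"]] == l3[["y"]])
  expect_equal(l3[["x"]], l3[["z"]])

  # refinement: equal three-locus labels imply equal two-locus labels
  for (i in c("x", "y", "z")) for (j in c("x", "y", "z")) {
    if (l3[[i]] == l3[[j]]) expect_equal(l2[[i]], l2[[j]])
  }
  # ledger label equality == per-locus tuple equality
  ld <- three$ledger
  for (i in seq_len(nrow(ld))) for (j in seq_len(nrow(ld))) {
    same_tuple <- all(ld[i, c("COI", "16S", "ITS2")] ==
                        ld[j, c("COI", "16S", "ITS2")])
    expect_equal(ld$concatenated[i] == ld$concatenated[j], same_tuple)
  }
})

test_that("specimens missing a locus are dropped with a warning, or an error in strict mode", {
  coi <- random_aln(4, 60, seed = 4, locus = "COI")
  s16 <- random_aln(3, 80, seed = 5, locus = "16S")
  names(s16$seqs) <- names(coi$seqs)[1:3]
  expect_warning(out <- concatenate_loci(list(coi, s16)), "missing")
  expect_equal(sort(out$ledger$specimen_id), sort(names(s16$seqs)))
  expect_error(concatenate_loci(list(coi, s16), strict = TRUE), "missing")
})
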