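test_that("K2P distance matches hand computations and boundary behaviour", {
  ident <- k2p_pair(strrep("ACGT", 20), strrep("ACGT", 20))
  expect_equal(ident$P, 0)
  expect_equal(ident$Q, 0)
  expect_equal(ident$d, 0)

  # one transition + one transversion over 10 sites: -0.5 ln(0.7 sqrt(0.8))
  x <- k2p_pair("AAAAAAAAAA", "GAAAAAAAAC")
  expect_equal(x$P, 0.1)
  expect_equal(x$Q, 0.1)
  expect_equal(x$d, 0.2341234, tolerance = 1e-6)
  expect_equal(x$pct, 23.41234, tolerance = 1e-4)

  # P = 0.3, Q = 0.4 sits exactly on the saturation boundary
  s1 <- paste0(strrep("A", 10))
  s2 <- paste0(strrep("G", 3), strrep("C", 4), strrep("A", 3))
  sat <- k2p_pair(s1, s2)
  expect_equal(sat$P, 0.3)
  expect_equal(sat$Q, 0.4)
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))

  # no comparable sites
  none <- k2p_pair("NN--", "AC-G")
  expect_equal(none$n_sites, 0L)
  expect_true(is.na(none$d))
})

test_that("K2P agrees with a column-enumeration oracle and is symmetric", {
  set.seed(77)
  for (k in 1:25) {
    len <- sample(50:200, 1)
    a <- paste(sample(c("A", "C", "G", "T", "N", "-"), len, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-"), len, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    got <- k2p_pair(a, b)
    expect_equal(got$d, k2p_oracle(a, b), tolerance = 1e-12)
    expect_equal(k2p_pair(b, a)$d, got$d, tolerance = 1e-15)
  }
})

test_that("distance grows with either substitution proportion inside the domain", {
  seq_with <- function(ts, tv, len = 100) {
    # first ts columns transitions, next tv columns transversions
    ref <- strrep("A", len)
    alt <- paste0(strrep("G", ts), strrep("C", tv),
                  strrep("A", len - ts - tv))
    k2p_pair(ref, alt)$d
  }
  expect_true(all(diff(sapply(c(2, 6, 10, 14), seq_with, tv = 4)) > 0))
  expect_true(all(diff(sapply(c(2, 6, 10, 14), seq_with, ts = 4)) > 0))
})

test_that("deletion policies differ exactly at gapped columns", {
  a <- aln_of(c("AAGTA", "AA-TA", "ACGTA"))
  comp <- k2p_distances(a, deletion = "complete")
  pair <- function(d, i, j) d[d$id1 == i & d$id2 == j, ]
  expect_equal(pair(comp, "t1", "t2")$n_sites, 4L)
  expect_equal(pair(comp, "t1", "t3")$n_sites, 4L)  # shared mask
  pw <- k2p_distances(a, deletion = "pairwise")
  expect_equal(pair(pw, "t1", "t3")$n_sites, 5L)    # this pair has no gap
  expect_equal(pair(pw, "t1", "t2")$n_sites, 4L)
})

test_that("distances are equivariant under input reordering", {
  a <- random_aln(5, 120, seed = 55)
  d1 <- k2p_distances(a)
  b <- locus_alignment(a$seqs[c(3, 1, 5, 2, 4)], locus = a$locus)
  d2 <- k2p_distances(b)
  key <- function(d) {
    k <- purrr::map2_chr(d$id1, d$id2, ~paste(sort(c(.x, .y)), collapse = "|"))
    setNames(d$d, k)[order(k)]
  }
  expect_equal(key(d2), key(d1), tolerance = 1e-15)
})

test_that("K2P matches an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  a <- random_aln(8, 300, seed = 60)
  ours <- k2p_matrix(k2p_distances(a))
  mat <- do.call(rbind, strsplit(tolower(unname(a$seqs)), ""))
  rownames(mat) <- names(a$seqs)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(mat), model = "K80"))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-8)
})

test_that("group summaries split within and between comparisons", {
  a <- aln_of(c(rep("ACGTACGTAC", 2), "AGGTACGTAC", "AGGTACGTAT"),
              ids = c("a1", "a2", "b1", "b2"))
  map <- tibble::tibble(specimen_id = c("a1", "a2", "b1", "b2"),
                        group = c("G1", "G1", "G2", "G2"))
  sm <- group_distance_summary(k2p_distances(a), map)
  w1 <- sm[sm$comparison == "Within G1", ]
  expect_equal(c(w1$min, w1$max, w1$mean), c(0, 0, 0))
  expect_equal(sm$type, c("within", "within", "between"))
  expect_equal(sm$n_pairs, c(1L, 1L, 4L))
  expect_true(all(sm$min <= sm$mean & sm$mean <= sm$max))

  fmt <- format_distance_summary(w1)
  expect_equal(fmt$range, "0.0–0.0 (0.0)")

  bad_map <- map[1:3, ]
  expect_error(group_distance_summary(k2p_distances(a), bad_map),
               "without a group")
})

test_that("singleton groups are omitted from within-group rows with a note", {
  a <- aln_of(c("ACGTACGTAC", "AGGTACGTAC", "AGGTACGTAT"),
              ids = c("a1", "b1", "b2"))
  map <- tibble::tibble(specimen_id = c("a1", "b1", "b2"),
                        group = c("G1", "G2", "G2"))
  expect_message(sm <- group_distance_summary(k2p_distances(a), map),
                 "< 2 members")
  expect_false("Within G1" %in% sm$comparison)
  expect_true("Within G2" %in% sm$comparison)
})
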