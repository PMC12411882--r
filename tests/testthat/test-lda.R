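test_that("standard distance matches hand computation", {
  expect_equal(standard_distance(c(-0.1, 0.1), c(0.9, 1.1)),
               7.0710678, tolerance = 1e-6)
  expect_equal(standard_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(standard_distance(c(1, 1), c(2, 2)), Inf)
})

test_that("delta decomposes separation into size and shape shares", {
  expect_equal(round(delta_size_shape(0.295, 0.92), 3), 0.243)
  expect_equal(round(delta_size_shape(0.184, 0.997), 3), 0.156)
  expect_true(is.na(delta_size_shape(0, 0)))
  expect_error(delta_size_shape(-1, 1))
})

test_that("identical groups give zero distances and undefined delta", {
  half <- random_table(4, 3, seed = 6)
  tbl <- dplyr::bind_rows(
    dplyr::mutate(half, group = "A"),
    dplyr::mutate(half, specimen_id = paste0(specimen_id, "b"), group = "B")
  )
  x <- lda_ratio_extractor(tbl)
  expect_true(all(x$pairs$D < 1e-12))
  expect_equal(x$D_size, 0)
  expect_equal(x$D_shape, 0)
  expect_true(is.na(x$delta))
})

test_that("the extractor agrees with the brute-force pair search", {
  for (seed in c(2, 9, 14, 23)) {
    p <- sample(3:5, 1)
    tbl <- random_table(16, p, seed = seed,
                        groups = rep(c("A", "B"), each = 8))
    x <- lda_ratio_extractor(tbl)
    ref <- brute_best_pair(tbl, c("A", "B"))
    expect_setequal(c(x$best$numerator, x$best$denominator), ref$pair)
    expect_equal(x$best$D, ref$D, tolerance = 1e-12)
  }
})

test_that("results are invariant to a variable's unit", {
  tbl <- simulate_measurements(n_per_group = 10, seed = 44,
                               planted_pair = c("SD", "UD"),
                               offset_sd_units = 2)
  a <- lda_ratio_extractor(tbl)
  tbl$AW <- tbl$AW * 100
  b <- lda_ratio_extractor(tbl)
  # D per unordered pair is unit invariant (reported orientation may flip)
  key_d <- function(x) {
    k <- purrr::map2_chr(x$pairs$numerator, x$pairs$denominator,
                         ~paste(sort(c(.x, .y)), collapse = "|"))
    setNames(x$pairs$D, k)[order(k)]
  }
  expect_equal(key_d(b), key_d(a), tolerance = 1e-9)
  expect_equal(b$delta, a$delta, tolerance = 1e-9)
  expect_equal(b$D_shape, a$D_shape, tolerance = 1e-9)
})

test_that("the second ratio is decorrelated from the best or flagged", {
  tbl <- simulate_measurements(variables = genital_vars, seed = 3,
                               planted_pair = c("V", "VA"),
                               offset_sd_units = 4)
  x <- lda_ratio_extractor(tbl)
  expect_equal(x$best$ratio, "V/VA")  # canonical orientation
  if (!x$second_flagged) {
    expect_lt(x$second$cor_with_best, x$decorrelation)
    # highest-D pair among the eligible ones
    eligible <- x$pairs[-1, ][x$pairs$eligible[-1], ]
    expect_equal(x$second$D, max(eligible$D))
  }
  expect_error(lda_ratio_extractor(tbl, groups = c("A", "C")), "at least 3")
})

test_that("reported ranges bracket every specimen and flag overlap", {
  tbl <- simulate_measurements(variables = genital_vars, seed = 12,
                               planted_pair = c("V", "VA"),
                               offset_sd_units = 3)
  x <- lda_ratio_extractor(tbl)
  for (w in c("best", "second")) {
    rr <- x$ranges[x$ranges$which == w, ]
    pair <- strsplit(rr$ratio[1], "/")[[1]]
    for (g in x$groups) {
      vals <- tbl[tbl$group == g, ][[pair[1]]] /
        tbl[tbl$group == g, ][[pair[2]]]
      row <- rr[rr$group == g, ]
      expect_true(all(vals >= row$min & vals <= row$max))
    }
  }

  # ranges shaped like the published V/VA comparison overlap at the margin
  tbl2 <- dplyr::bind_rows(
    toy_table(cbind(seq(0.33, 0.50, length.out = 4), rep(1, 4)),
              groups = "CAR", vars = c("V", "VA")),
    toy_table(cbind(seq(0.47, 1.01, length.out = 4), rep(1, 4)),
              groups = "CLA", vars = c("V", "VA"))
  )
  tbl2$specimen_id <- paste0("s", 1:8)
  expect_true(ratio_overlap(tbl2, c("CAR", "CLA"), c("V", "VA")))
  tbl2$V[tbl2$group == "CLA"] <- tbl2$V[tbl2$group == "CLA"] + 1
  expect_false(ratio_overlap(tbl2, c("CAR", "CLA"), c("V", "VA")))
})

test_that("groups below the minimum size are rejected", {
  tbl <- random_table(5, 3, seed = 1, groups = c("A", "A", "A", "B", "B"))
  expect_error(lda_ratio_extractor(tbl), "at least 3")
})
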