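test_that("pure size variation gives zero shape variance", {
  base <- c(2, 5, 9)
  tbl <- toy_table(rbind(base, base * 1.4, base * 0.7, base * 2.2))
  pca <- shape_pca(tbl)
  expect_true(all(pca$eigenvalues < 1e-12))
  expect_equal(pca$n_retained, 0)
})

test_that("a hand-computed two-variable case recovers its eigenvalues", {
  # clr rows (a, -a) with a in {-0.1, 0, 0.1}: var(a) = 0.01, and the shape
  # direction (1, -1)/sqrt(2) carries variance 2 * 0.01 = 0.02
  a <- c(-0.1, 0, 0.1)
  tbl <- toy_table(cbind(exp(1 + a), exp(1 - a)))
  pca <- shape_pca(tbl)
  expect_equal(pca$eigenvalues[1], 0.02, tolerance = 1e-12)
  expect_equal(pca$eigenvalues[2], 0, tolerance = 1e-12)
  expect_equal(pca$pct_variance[1], 100)
})

test_that("eigenvectors live in the clr subspace and variance shares sum to 100", {
  for (seed in c(3, 17, 29)) {
    pca <- shape_pca(random_table(5, 4, seed = seed))
    retained <- pca$eigenvectors[, seq_len(pca$n_retained), drop = FALSE]
    expect_true(all(abs(colSums(retained)) < 1e-9))
    expect_equal(sum(pca$pct_variance), 100, tolerance = 1e-9)
    expect_true(all(diff(pca$eigenvalues) <= 1e-12))
    # sign convention: dominant loading positive
    expect_true(all(apply(pca$eigenvectors, 2,
                          function(v) v[which.max(abs(v))] >= 0)))
    # scores are projections of the centered shape rows
    shp <- pca$shape
    centered <- sweep(shp, 2, colMeans(shp))
    expect_equal(pca$scores, centered %*% pca$eigenvectors,
                 tolerance = 1e-12)
  }
})

test_that("eigenvalues are invariant to a variable's unit", {
  tbl <- random_table(8, 5, seed = 11)
  e1 <- shape_pca(tbl)$eigenvalues
  tbl$v3 <- tbl$v3 * 250
  expect_equal(shape_pca(tbl)$eigenvalues, e1, tolerance = 1e-9)
})

test_that("shape PCA needs at least 3 specimens", {
  expect_error(shape_pca(toy_table(rbind(c(1, 2), c(2, 3)))), "at least 3")
})

test_that("size-shape correlation matches the t-test machinery", {
  tbl <- simulate_measurements(n_per_group = 15, seed = 5,
                               beta = c(1.4, 1.2, 1, 1, 0.8, 0.8, 0.8))
  pca <- shape_pca(tbl)
  got <- size_shape_correlation(pca, 1)
  ref <- cor.test(pca$log_isosize, pca$scores[, 1])
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # closed-form identity at reported precision
  expect_equal(got$t, got$r * sqrt(got$df / (1 - got$r^2)), tolerance = 1e-12)
})

test_that("closed-form t reproduces frozen reference values", {
  t_of <- function(r, df) r * sqrt(df / (1 - r^2))
  expect_equal(t_of(0.49, 28), 2.974383, tolerance = 1e-6)
  expect_equal(t_of(-0.37, 28), -2.107416, tolerance = 1e-6)
})

test_that("perfectly size-aligned shape is flagged as degenerate", {
  s <- seq(-0.3, 0.3, length.out = 8)
  tbl <- toy_table(cbind(exp(s * 1.2), exp(s * 0.8)))
  pca <- shape_pca(tbl)
  got <- size_shape_correlation(pca, 1)
  expect_true(got$degenerate)
  expect_equal(abs(got$r), 1, tolerance = 1e-9)
  expect_equal(got$p, 0)
})

test_that("tidy, glance and augment return well-formed tibbles", {
  pca <- shape_pca(random_table(6, 4, seed = 2, groups = rep(c("A", "B"), 3)))
  td <- generics::tidy(pca)
  expect_named(td, c("variable", "component", "loading"))
  expect_equal(nrow(td), 16)
  gl <- generics::glance(pca)
  expect_equal(gl$n_specimens, 6)
  expect_equal(gl$n_retained, 3)
  au <- generics::augment(pca)
  expect_true(all(c("specimen_id", "isosize", "PC1") %in% names(au)))
})
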