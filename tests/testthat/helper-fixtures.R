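# Shared builders and independent oracles for the test suite.

# Tiny measurement table with explicit values.
toy_table <- function(values, groups = NULL, vars = NULL) {
  values <- as.matrix(values)
  vars <- vars %||% paste0("v", seq_len(ncol(values)))
  colnames(values) <- vars
  tibble::as_tibble(values) |>
    dplyr::mutate(specimen_id = paste0("s", dplyr::row_number()),
                  group = groups %||% "A", .before = 1)
}

# Random strictly positive measurement table.
random_table <- function(n, p, seed, groups = NULL) {
  set.seed(seed)
  toy_table(matrix(exp(rnorm(n * p, mean = 1, sd = 0.4)), n, p),
            groups = groups)
}

# Alignment from a character vector, auto-named.
aln_of <- function(seqs, locus = "L", ids = NULL) {
  names(seqs) <- ids %||% paste0("t", seq_along(seqs))
  locus_alignment(seqs, locus = locus)
}

random_aln <- function(n, len, seed, locus = "L") {
  set.seed(seed)
  aln_of(replicate(n, paste(sample(c("A", "C", "G", "T"), len,
                                   replace = TRUE), collapse = "")),
         locus = locus)
}

# Independent K2P oracle: walk the columns one by one, classify each
# substitution, then apply the closed form.
k2p_oracle <- function(seq1, seq2) {
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  pur <- c("A", "G")
  for (k in seq_along(a)) {
    if (!(a[k] %in% c("A", "C", "G", "T"))) next
    if (!(b[k] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (a[k] == b[k]) next
    same_class <- (a[k] %in% pur) == (b[k] %in% pur)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Independent LDA-ratio oracle: enumerate every unordered variable pair and
# maximise the standardized mean difference of the log-ratio, all arithmetic
# written out.
brute_best_pair <- function(data, groups) {
  vars <- setdiff(names(data), c("specimen_id", "group"))
  best <- NULL; best_D <- -Inf
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (j <= i) next
    r <- log(data[[vars[i]]]) - log(data[[vars[j]]])
    ra <- r[data$group == groups[1]]
    rb <- r[data$group == groups[2]]
    va <- sum((ra - mean(ra))^2) / (length(ra) - 1)
    vb <- sum((rb - mean(rb))^2) / (length(rb) - 1)
    sp <- sqrt(((length(ra) - 1) * va + (length(rb) - 1) * vb) /
                 (length(ra) + length(rb) - 2))
    D <- abs(mean(ra) - mean(rb)) / sp
    if (D > best_D) {
      best_D <- D
      best <- sort(c(vars[i], vars[j]))
    }
  }
  list(pair = best, D = best_D)
}

alignment_matrix_for_tests <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

`%||%` <- rlang::`%||%`
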