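#' Simulate a two-clade haplotype alignment
#'
#' Generates aligned sequences from a star-shaped two-clade model calibrated
#' in expected Kimura two-parameter distance. A random ancestral sequence
#' spawns two clade founders along branches of (d_between - d_within) / 2
#' expected substitutions per site each; every specimen then diverges from
#' its founder along a branch of d_within / 2. Expected pairwise distances
#' are therefore d_within inside a clade and d_between across clades, and
#' the K2P estimator is unbiased for them to first order.
#'
#' Substitutions follow a two-parameter transition/transversion process with
#' rate ratio `kappa` = alpha/beta: a branch of length d has transition
#' exposure alpha t = kappa d / (kappa + 2) and per-transversion exposure
#' beta t = d / (kappa + 2), and sites mutate independently with the
#' closed-form substitution probabilities of that process. No indels are
#' simulated; `gap_prob` optionally converts random ancestral columns to
#' gaps in one clade so deletion masks can be exercised.
#'
#' With probability `shared_haplotype_prob` a specimen copies a previously
#' generated haplotype of its own clade instead of mutating afresh,
#' emulating shared haplotypes within populations.
#'
#' @param n_per_clade Specimens per clade (default 10).
#' @param length Alignment columns (default 615, >= 50).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param d_within,d_between Target expected K2P distances in substitutions
#'   per site (defaults 0.005 and 0.19; `0 <= d_within < d_between`).
#' @param shared_haplotype_prob Probability a specimen copies an existing
#'   clade haplotype (default 0).
#' @param gap_prob Per-column probability of a planted gap in clade B
#'   (default 0).
#' @param clades Labels of the two clades.
#' @param locus Locus name of the simulated alignment.
#' @param seed Integer seed; fully reproducible given the seed.
#' @return List with `alignment` (a [locus_alignment()]) and
#'   `population_map` (tibble: `specimen_id`, `population`, `group`).
#' @export
simulate_sequences <- function(n_per_clade = 10L, length = 615L, kappa = 2,
                               d_within = 0.005, d_between = 0.19,
                               shared_haplotype_prob = 0, gap_prob = 0,
                               clades = c("cladeA", "cladeB"),
                               locus = "sim", seed = NULL) {
  stopifnot(length >= 50, n_per_clade >= 1, kappa > 0,
            d_within >= 0, d_between > d_within,
            shared_haplotype_prob >= 0, shared_haplotype_prob <= 1,
            length(clades) == 2)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, length, replace = TRUE)
  founder_branch <- (d_between - d_within) / 2

  seqs <- character(0)
  map <- list()
  for (ci in 1:2) {
    founder <- evolve_k2p(ancestor, founder_branch, kappa)
    clade_seqs <- list()
    for (k in seq_len(n_per_clade)) {
      copy <- k > 1 && stats::runif(1) < shared_haplotype_prob
      clade_seqs[[k]] <- if (copy) {
        clade_seqs[[sample.int(k - 1L, 1)]]
      } else {
        evolve_k2p(founder, d_within / 2, kappa)
      }
    }
    ids <- sprintf("%s_%02d", clades[ci], seq_len(n_per_clade))
    seqs <- c(seqs, stats::setNames(
      purrr::map_chr(clade_seqs, paste, collapse = ""), ids))
    map[[ci]] <- tibble::tibble(specimen_id = ids,
                                population = clades[ci], group = clades[ci])
  }
  if (gap_prob > 0) {
    gap_cols <- which(stats::runif(length) < gap_prob)
    if (base::length(gap_cols)) {
      in_b <- startsWith(names(seqs), clades[2])
      for (i in which(in_b)) {
        ch <- strsplit(seqs[[i]], "")[[1]]
        ch[gap_cols] <- "-"
        seqs[[i]] <- paste(ch, collapse = "")
      }
    }
  }
  list(alignment = locus_alignment(seqs, locus = locus),
       population_map = dplyr::bind_rows(map))
}

# Per-site substitution probabilities of the two-parameter process after a
# branch of d expected substitutions/site with ts/tv rate ratio kappa:
#   p_transversion(each) = (1 - e^(-4 bt)) / 4
#   p_transition         = 1/4 + e^(-4 bt)/4 - e^(-2 (at + bt))/2
# where at = kappa d / (kappa + 2), bt = d / (kappa + 2). Plugging the
# expected P and Q back into the K2P formula returns exactly d.
k2p_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  e1 <- exp(-2 * (at + bt))
  e2 <- exp(-4 * bt)
  p_ts <- 0.25 + 0.25 * e2 - 0.5 * e1
  p_tv <- 0.25 * (1 - e2)
  c(same = 1 - p_ts - 2 * p_tv, ts = p_ts, tv = 2 * p_tv)
}

transition_partner <- c(A = "G", G = "A", C = "T", T = "C")
transversion_partners <- list(A = c("C", "T"), G = c("C", "T"),
                              C = c("A", "G"), T = c("A", "G"))

evolve_k2p <- function(parent, d, kappa) {
  if (d <= 0) return(parent)
  pr <- k2p_site_probs(d, kappa)
  u <- stats::runif(length(parent))
  out <- parent
  is_ts <- u >= pr["same"] & u < pr["same"] + pr["ts"]
  is_tv <- u >= pr["same"] + pr["ts"]
  out[is_ts] <- transition_partner[parent[is_ts]]
  if (any(is_tv)) {
    pick <- stats::runif(sum(is_tv)) < 0.5
    out[is_tv] <- purrr::map2_chr(parent[is_tv], pick, function(b, first) {
      transversion_partners[[b]][if (first) 1 else 2]
    })
  }
  out
}
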