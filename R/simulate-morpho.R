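#' Default morphometric variable sets
#'
#' `shell_vars`: aperture height/width, adapical and medial last-whorl
#' heights, shell diameter, shell height, umbilicus diameter.
#' `genital_vars`: lengths of the bursa copulatrix duct, epiphallus,
#' flagellum, penis, vagina and vaginal appendix.
#'
#' @format Character vectors of variable names.
#' @name variable_sets
NULL

#' @rdname variable_sets
#' @export
shell_vars <- c("AH", "AW", "LWaH", "LWmH", "SD", "SH", "UD")

#' @rdname variable_sets
#' @export
genital_vars <- c("DBC", "E", "F", "P", "V", "VA")

# Plausible mean sizes (mm) for the default variable sets; only the log-mean
# structure matters to the analyses, not the absolute scale.
default_mu <- function(variables) {
  known <- c(AH = 6.3, AW = 6.7, LWaH = 3.6, LWmH = 2.2, SD = 14, SH = 9.5,
             UD = 1.1, DBC = 4, E = 4.5, F = 3, P = 3.5, V = 2, VA = 1.5)
  mu <- known[variables]
  mu[is.na(mu)] <- 5
  log(stats::setNames(as.numeric(mu), variables))
}

#' Simulate a two-group morphometric measurement table
#'
#' Generates log-normal measurements from the size/shape model the ratio
#' analyses assume: ln x_sv = mu_v + beta_v s_s + shape/size offsets + eps,
#' with latent log size s ~ N(0, sigma_size^2) and residual noise
#' eps ~ N(0, sigma_noise^2). Under the default beta (all ones) the data are
#' isometric; deviations of beta from 1 create allometry.
#'
#' Two planted group contrasts are available. A *shape* contrast adds
#' +delta/2 to one variable of `planted_pair` and -delta/2 to the other in
#' group B, where delta = `offset_sd_units` * sqrt(2) * `sigma_noise` — the
#' pooled sd of a log-ratio of two independent variables is
#' sqrt(2) sigma_noise, so `offset_sd_units` is the planted effect in pooled
#' log-ratio sd units. The opposite signs leave every specimen's isosize
#' untouched (a pure shape effect). A *size* contrast (`size_offset`) shifts
#' all log variables of group B equally, moving isosize without moving
#' shape.
#'
#' @param n_per_group Specimens per group (default 30).
#' @param variables Variable names; default the 7-variable shell set
#'   (`AH, AW, LWaH, LWmH, SD, SH, UD`); `genital_vars` gives the 6-variable
#'   genital set (`DBC, E, F, P, V, VA`).
#' @param groups Labels of the two groups.
#' @param mu Named baseline log-mean vector; defaults to realistic shell or
#'   genital sizes in mm.
#' @param beta Allometry coefficients (default all 1: isometry).
#' @param sigma_size Sd of the latent log size (default 0.1).
#' @param sigma_noise Residual sd of each log measurement (default 0.05).
#' @param planted_pair Two distinct variable names carrying the shape
#'   contrast, or `NULL` for none.
#' @param offset_sd_units Shape effect size in pooled log-ratio sd units.
#' @param size_offset Log-size shift of group B (pure size effect).
#' @param seed Integer seed; the table is reproducible given the seed.
#' @return A measurement table tibble (`specimen_id`, `group`, one column
#'   per variable, mm scale).
#' @export
simulate_measurements <- function(n_per_group = 30L,
                                  variables = shell_vars,
                                  groups = c("A", "B"),
                                  mu = NULL,
                                  beta = NULL,
                                  sigma_size = 0.1,
                                  sigma_noise = 0.05,
                                  planted_pair = NULL,
                                  offset_sd_units = 0,
                                  size_offset = 0,
                                  seed = NULL) {
  p <- length(variables)
  stopifnot(p >= 2, length(groups) == 2, n_per_group >= 1,
            sigma_size >= 0, sigma_noise >= 0)
  mu <- mu %||% default_mu(variables)
  beta <- beta %||% rep(1, p)
  stopifnot(length(mu) == p, length(beta) == p)
  if (!is.null(planted_pair)) {
    stopifnot(length(planted_pair) == 2,
              planted_pair[1] != planted_pair[2],
              all(planted_pair %in% variables))
  }
  if (!is.null(seed)) set.seed(seed)

  n <- 2L * n_per_group
  group <- rep(groups, each = n_per_group)
  s <- stats::rnorm(n, 0, sigma_size)
  eps <- matrix(stats::rnorm(n * p, 0, sigma_noise), n, p)
  loga <- matrix(mu, n, p, byrow = TRUE) + outer(s, beta) + eps

  in_b <- group == groups[2]
  if (size_offset != 0) loga[in_b, ] <- loga[in_b, ] + size_offset
  if (!is.null(planted_pair) && offset_sd_units != 0) {
    delta <- offset_sd_units * sqrt(2) * sigma_noise
    i <- match(planted_pair[1], variables)
    j <- match(planted_pair[2], variables)
    loga[in_b, i] <- loga[in_b, i] + delta / 2
    loga[in_b, j] <- loga[in_b, j] - delta / 2
  }

  out <- tibble::as_tibble(exp(loga), .name_repair = "minimal")
  names(out) <- variables
  dplyr::bind_cols(
    tibble::tibble(specimen_id = sprintf("s%03d", seq_len(n)), group = group),
    out
  )
}
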