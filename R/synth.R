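#' Ground truth for a synthetic consumer mixture
#'
#' Bundles the known diet proportions and residual noise used by
#' [gen_mixture_consumers()], so parameter-recovery tests can compare
#' posterior estimates against truth.
#'
#' @param proportions Numeric simplex vector over the sources (each >= 0,
#'   summing to 1 within 1e-12).
#' @param residual_sd_d13C,residual_sd_d15N Residual process SD per tracer
#'   (per mil), on top of source + discrimination variance.
#' @param n_consumers Number of consumers to generate.
#' @param seed Integer seed; generation is a pure function of inputs + seed.
#' @return An object of class `mixture_truth`.
#' @export
mixture_truth <- function(proportions, residual_sd_d13C = 0,
                          residual_sd_d15N = 0, n_consumers = 10, seed = 1L) {
  p <- as.numeric(proportions)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
    stop("invalid truth: proportions must be >= 0 and sum to 1")
  if (residual_sd_d13C < 0 || residual_sd_d15N < 0)
    stop("residual SDs must be non-negative")
  structure(list(proportions = p,
                 residual_sd_d13C = residual_sd_d13C,
                 residual_sd_d15N = residual_sd_d15N,
                 n_consumers = as.integer(n_consumers),
                 seed = as.integer(seed)),
            class = "mixture_truth")
}

#' Generate per-individual samples for one source group
#'
#' Draws independent normal values per tracer from a source-summary row. With
#' `moment_match = TRUE` (the default) the draws are affinely rescaled so that
#' the realized sample mean and sample SD (n-1 denominator) equal the summary
#' exactly — the device used throughout to stand in for unpublished
#' per-individual data, exploiting the fact that a Gaussian likelihood sees
#' the data only through these moments.
#'
#' @param summary One-row source-summary data frame (see [validate_sources()]).
#' @param n Number of individuals; must be >= 2 when `moment_match` is on.
#' @param seed Integer seed.
#' @param moment_match Rescale draws to the exact summary moments?
#' @param rho Optional target cross-tracer correlation in (-1, 1); draws are
#'   generated from a bivariate normal with this correlation (the realized
#'   correlation is only approximate unless moment matching is off and n is
#'   large). Used by niche-model tests; the mixing likelihood ignores it.
#' @return Sample data frame (`sample_id`, `group`, `d13C`, `d15N`).
#' @export
gen_source_samples <- function(summary, n, seed = 1L, moment_match = TRUE,
                               rho = 0) {
  summary <- validate_sources(summary)
  if (nrow(summary) != 1L) stop("summary must be a single source row")
  if (moment_match && n < 2)
    stop("insufficient n: moment matching needs n >= 2")
  if (abs(rho) >= 1) stop("rho must be in (-1, 1)")
  set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  scale_to <- function(z, m, s) {
    if (s == 0) return(rep(m, n))
    if (moment_match) {
      zs <- stats::sd(z)
      if (zs == 0) stop("degenerate draws; cannot moment-match")
      m + s * (z - mean(z)) / zs
    } else m + s * z
  }
  data.frame(
    sample_id = sprintf("%s_%03d", gsub("\\s+", "_", summary$name), seq_len(n)),
    group = summary$name,
    d13C = scale_to(z1, summary$mean_d13C, summary$sd_d13C),
    d15N = scale_to(z2, summary$mean_d15N, summary$sd_d15N),
    stringsAsFactors = FALSE)
}

#' Mixture moments implied by sources, discrimination and diet proportions
#'
#' Closed-form mean and SD of a consumer tracer under the mixing-model
#' likelihood: mean `sum_k p_k (mu_k + mu_TEF)` and variance
#' `sum_k p_k^2 (sigma_k^2 + sigma_TEF^2) + sigma_resid^2`, per tracer.
#'
#' @param sources Source-summary table (K rows).
#' @param tef A [tef_spec()].
#' @param proportions Simplex vector of length K.
#' @param residual_sd Length-2 residual SD `c(d13C, d15N)`.
#' @return List with numeric length-2 vectors `mean` and `sd`, named
#'   `d13C`/`d15N`.
#' @export
mixture_moments <- function(sources, tef, proportions, residual_sd = c(0, 0)) {
  sources <- validate_sources(sources)
  p <- as.numeric(proportions)
  if (length(p) != nrow(sources)) stop("proportions must match source count")
  mu <- cbind(sources$mean_d13C + tef$mean_d13C,
              sources$mean_d15N + tef$mean_d15N)
  v <- cbind(sources$sd_d13C^2 + tef$sd_d13C^2,
             sources$sd_d15N^2 + tef$sd_d15N^2)
  m <- as.numeric(p %*% mu)
  s <- sqrt(as.numeric(p^2 %*% v) + residual_sd^2)
  list(mean = stats::setNames(m, c("d13C", "d15N")),
       sd = stats::setNames(s, c("d13C", "d15N")))
}

#' Generate consumers as a known Dirichlet mixture of TEF-shifted sources
#'
#' Each consumer tracer value is drawn independently from the normal
#' distribution implied by [mixture_moments()] — exactly the mixing-model
#' likelihood — so fits to these data are calibrated by construction.
#'
#' @param sources Source-summary table (K >= 1 rows).
#' @param tef A [tef_spec()].
#' @param truth A [mixture_truth()].
#' @param group Group label for the generated consumers.
#' @return Sample data frame of `truth$n_consumers` individuals.
#' @export
gen_mixture_consumers <- function(sources, tef, truth, group = "consumer") {
  sources <- validate_sources(sources)
  if (!inherits(truth, "mixture_truth")) stop("truth must be a mixture_truth")
  if (length(truth$proportions) != nrow(sources))
    stop("invalid truth: proportions length != number of sources")
  mom <- mixture_moments(sources, tef, truth$proportions,
                         c(truth$residual_sd_d13C, truth$residual_sd_d15N))
  n <- truth$n_consumers
  set.seed(truth$seed)
  data.frame(
    sample_id = sprintf("%s_%03d", group, seq_len(n)),
    group = group,
    d13C = stats::rnorm(n, mom$mean["d13C"], mom$sd["d13C"]),
    d15N = stats::rnorm(n, mom$mean["d15N"], mom$sd["d15N"]),
    stringsAsFactors = FALSE)
}
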