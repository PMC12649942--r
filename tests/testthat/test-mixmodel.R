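two_sources <- function() {
  data.frame(name = c("left", "right"), n = c(10, 10),
             mean_d13C = c(-24, -16), sd_d13C = c(0.3, 0.3),
             mean_d15N = c(6, 10), sd_d15N = c(0.3, 0.3))
}
no_tef <- function() tef_spec(0, 0, 0, 0)

small_fit <- function(consumers, sources, tef, seed = 1, ...) {
  fit_mixing(consumers, sources, tef, chains = 2, iterations = 3000,
             burn_in = 500, seed = seed, ...)
}

test_that("every retained draw lies on the simplex with positive sigmas", {
  cons <- gen_mixture_consumers(toy_sources(), default_tef(),
                                mixture_truth(c(0.5, 0.3, 0.2), 0.3, 0.3,
                                              10, seed = 3))
  fit <- small_fit(cons, toy_sources(), default_tef())
  expect_true(all(fit$p >= 0))
  expect_equal(unname(rowSums(fit$p)), rep(1, nrow(fit$p)), tolerance = 1e-10)
  expect_true(all(fit$sigma > 0))
  sm <- mixing_summary(fit)
  expect_true(all(sm$ci_2.5[sm$unit == "%"] >= 0 &
                  sm$ci_97.5[sm$unit == "%"] <= 100))
})

test_that("a consumer at the midpoint of a symmetric pair splits 50/50", {
  mid <- data.frame(sample_id = sprintf("m%d", 1:8), group = "mid",
                    d13C = rep(-20, 8), d15N = rep(8, 8))  # exact midpoint
  fit <- small_fit(mid, two_sources(), no_tef())
  expect_equal(unname(colMeans(fit$p)), c(0.5, 0.5), tolerance = 0.05)
  # two-source closure forces correlation exactly -1
  expect_equal(posterior_correlation(fit)[1, 2], -1, tolerance = 1e-9)
})

test_that("consumers at one source's corrected mean are attributed to it", {
  src <- two_sources()
  tef <- default_tef()
  cons <- gen_mixture_consumers(src, tef,
                                mixture_truth(c(1, 0), 0.1, 0.1, 12, seed = 9))
  fit <- small_fit(cons, src, tef)
  expect_gt(mean(fit$p[, "left"]), 0.9)
})

test_that("refitting with an identical seed reproduces the fit exactly", {
  cons <- anemone_consumers()
  f1 <- small_fit(cons, table7_sources(), default_tef(), seed = 11)
  f2 <- small_fit(cons, table7_sources(), default_tef(), seed = 11)
  expect_identical(f1$p, f2$p)
  expect_identical(deviance(f1), deviance(f2))
})

test_that("permuting source order permutes the posterior accordingly", {
  src <- toy_sources()
  cons <- gen_mixture_consumers(src, default_tef(),
                                mixture_truth(c(0.6, 0.25, 0.15), 0.2, 0.2,
                                              15, seed = 5))
  f1 <- small_fit(cons, src, default_tef(), seed = 3)
  perm <- c(3, 1, 2)
  f2 <- small_fit(cons, src[perm, ], default_tef(), seed = 3)
  expect_equal(colMeans(f2$p)[src$name], colMeans(f1$p)[src$name],
               tolerance = 0.04)
})

test_that("combined contributions respect simplex closure", {
  cons <- anemone_consumers()
  fit <- small_fit(cons, table7_sources(), default_tef())
  all5 <- combined_contribution(fit, fit$source_names)
  expect_equal(all5$mean, 1, tolerance = 1e-12)
  expect_equal(all5$sd, 0, tolerance = 1e-12)
  a <- combined_contribution(fit, c("Small-Sized Fishes", "Shrimps"))
  b <- combined_contribution(fit, c("Zooplankton", "POM", "SOM"))
  expect_equal(a$mean + b$mean, 1, tolerance = 1e-12)
  expect_error(combined_contribution(fit, "Krill"), "unknown source")
  expect_error(combined_contribution(fit, character(0)), "non-empty")
})

test_that("collinear sources induce strong negative posterior correlation", {
  # two sources nearly collinear with the consumer, one orthogonal
  near <- data.frame(name = c("f1", "f2", "far"), n = c(10, 10, 10),
                     mean_d13C = c(-19.0, -18.0, -24), sd_d13C = rep(0.4, 3),
                     mean_d15N = c(11.0, 10.7, 5), sd_d15N = rep(0.4, 3))
  cons <- gen_mixture_consumers(near, no_tef(),
                                mixture_truth(c(0.4, 0.4, 0.2), 0.2, 0.2,
                                              10, seed = 21))
  fit <- small_fit(cons, near, no_tef())
  cm <- posterior_correlation(fit)
  expect_lt(cm["f1", "f2"], -0.5)
  # an orthogonal geometry decorrelates the pair
  ortho <- near
  ortho$mean_d13C <- c(-24, -16, -20)
  ortho$mean_d15N <- c(6, 6, 14)
  cons2 <- gen_mixture_consumers(ortho, no_tef(),
                                 mixture_truth(c(0.4, 0.4, 0.2), 0.2, 0.2,
                                               10, seed = 22))
  fit2 <- small_fit(cons2, ortho, no_tef())
  cm2 <- posterior_correlation(fit2)
  expect_gt(cm2["f1", "f2"], cm["f1", "f2"] + 0.2)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), c(1, 1, 1))
})

test_that("posterior predictive replicates cover data generated by the model", {
  src <- toy_sources()
  cons <- gen_mixture_consumers(src, default_tef(),
                                mixture_truth(c(0.5, 0.3, 0.2), 0.3, 0.3,
                                              15, seed = 31))
  fit <- small_fit(cons, src, default_tef())
  ppc <- posterior_predictive(fit, seed = 4)
  expect_gte(ppc$coverage["cov95"], 0.8)   # 30 obs, binomial slack
  expect_true(all(ppc$table$lo95 <= ppc$table$lo50))
  expect_true(all(ppc$table$hi50 <= ppc$table$hi95))
})

test_that("posteriors concentrate relative to the flat Dirichlet prior", {
  cons <- anemone_consumers()
  fit <- small_fit(cons, table7_sources(), default_tef())
  pp <- prior_vs_posterior(fit)
  expect_equal(pp$prior_mean, rep(0.2, 5))  # Dirichlet symmetry, K = 5
  expect_true(all(pp$overlap_coef < 0.95))
  # weak-data limit: huge residual-SD prior swamps the likelihood
  one <- cons[1, , drop = FALSE]
  weak <- fit_mixing(one, table7_sources(), default_tef(), chains = 2,
                     iterations = 4000, burn_in = 1000, seed = 2,
                     sigma_prior_sd = 500)
  expect_equal(unname(colMeans(weak$p)), rep(0.2, 5), tolerance = 0.06)
})

test_that("adding a duplicate source mainly dilutes the pair's shares", {
  src <- toy_sources()
  cons <- gen_mixture_consumers(src, default_tef(),
                                mixture_truth(c(0.5, 0.3, 0.2), 0.2, 0.2,
                                              12, seed = 41))
  clone <- src[1, ]; clone$name <- "algae2"
  sens <- sensitivity_mode(cons, src, clone, default_tef(),
                           combined_subset = "algae",
                           chains = 2, iterations = 3000, burn_in = 500,
                           seed = 6)
  base_algae <- sens$combined$mean[sens$combined$model == "base"]
  ext_pair <- combined_contribution(sens$extended_fit, c("algae", "algae2"))
  expect_equal(ext_pair$mean, base_algae, tolerance = 0.1)
  expect_equal(length(sens$deviance), 2L)
  # deviance changes little when the duplicate adds no information
  expect_lt(abs(diff(sens$deviance)), 5)
})

test_that("the sampler agrees with an independent JAGS oracle", {
  src <- toy_sources()
  tef <- default_tef()
  cons <- gen_mixture_consumers(src, tef,
                                mixture_truth(c(0.5, 0.3, 0.2), 0.3, 0.3,
                                              12, seed = 51))
  fit <- fit_mixing(cons, src, tef, chains = 2, iterations = 6000,
                    burn_in = 1000, seed = 7)
  library(rjags)
  ms <- "model{
    for (i in 1:N) { for (j in 1:2) {
      y[i, j] ~ dnorm(inprod(p, s_mean[, j] + c_mean[j]), 1 / var_y[j]) } }
    for (j in 1:2) {
      var_y[j] <- inprod(p * p, pow(s_sd[, j], 2) + pow(c_sd[j], 2)) +
        pow(sigma[j], 2)
      sigma[j] ~ dnorm(0, 1 / 25) T(0,)
    }
    p ~ ddirch(alpha)
  }"
  dat <- list(y = cbind(cons$d13C, cons$d15N), N = nrow(cons),
              s_mean = cbind(src$mean_d13C, src$mean_d15N),
              s_sd = cbind(src$sd_d13C, src$sd_d15N),
              c_mean = c(1, 3.4), c_sd = c(0.2, 0.2), alpha = rep(1, 3))
  jm <- rjags::jags.model(textConnection(ms), data = dat, n.chains = 2,
                          quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("p", "sigma"), 8000, progress.bar = "none")
  P <- do.call(rbind, lapply(sm, function(x) as.matrix(x)[, 1:3]))
  expect_equal(unname(colMeans(fit$p)), unname(colMeans(P)), tolerance = 0.03)
  SG <- do.call(rbind, lapply(sm, function(x) as.matrix(x)[, 4:5]))
  expect_equal(unname(colMeans(fit$sigma)), unname(colMeans(SG)),
               tolerance = 0.1)
})

test_that("credible intervals cover the generating proportions at ~95%", {
  src <- toy_sources()
  tef <- default_tef()
  p_star <- c(0.5, 0.3, 0.2)
  covered <- 0L; total <- 0L
  for (r in 1:50) {
    cons <- gen_mixture_consumers(src, tef,
                                  mixture_truth(p_star, 0.3, 0.3, 10,
                                                seed = 700 + r))
    fit <- fit_mixing(cons, src, tef, chains = 2, iterations = 2500,
                      burn_in = 500, seed = 800 + r)
    ci <- apply(fit$p, 2, quantile, c(0.025, 0.975))
    covered <- covered + sum(ci[1, ] <= p_star & p_star <= ci[2, ])
    total <- total + 3L
  }
  coverage <- covered / total
  expect_gte(coverage, 0.88)   # ~3 binomial SEs below 0.95 at 150 checks
  expect_lte(coverage, 1.0)
})
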