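mvn_group <- function(n, mu, Sigma, label, seed) {
  set.seed(seed)
  X <- MASS::mvrnorm(n, mu, Sigma)     # (d15N, d13C) order
  data.frame(sample_id = sprintf("%s%03d", label, seq_len(n)), group = label,
             d13C = X[, 2], d15N = X[, 1])
}

test_that("niche fit recovers known bivariate-normal parameters", {
  mu <- c(11, -19); Sigma <- matrix(c(1.2, 0.4, 0.4, 0.8), 2)
  g <- mvn_group(600, mu, Sigma, "big", seed = 21)
  fit <- fit_niche(g, n_draws = 500, seed = 3)
  expect_equal(unname(colMeans(fit$mu)), mu, tolerance = 0.15)
  Sig_mean <- apply(fit$Sigma, c(1, 2), mean)
  expect_equal(Sig_mean, Sigma, tolerance = 0.15)
  # niche sizes strictly positive
  expect_true(all(fit$niche_size > 0))
  expect_error(fit_niche(g[1:2, ]), "insufficient")
})

test_that("anemone-like group centres on its published d15N mean", {
  fit <- fit_niche(anemone_consumers(), n_draws = 500, seed = 8)
  expect_equal(mean(fit$mu[, "d15N"]), 12.45, tolerance = 0.15)
  expect_equal(mean(fit$mu[, "d13C"]), -20.16, tolerance = 0.15)
})

test_that("identical observations trigger the jitter path with tiny niches", {
  g <- data.frame(sample_id = c("a", "b", "c", "d"), group = "flat",
                  d13C = rep(-20, 4), d15N = rep(10, 4))
  expect_warning(fit <- fit_niche(g, n_draws = 200, seed = 2), "singular")
  expect_lt(mean(fit$niche_size), 1e-4)
})

test_that("scaling the data by c scales niche size draws by c^2", {
  g <- mvn_group(40, c(10, -20), diag(c(1, 0.5)), "s", seed = 5)
  g2 <- g; g2$d13C <- 2 * g$d13C; g2$d15N <- 2 * g$d15N
  f1 <- fit_niche(g, n_draws = 100, seed = 7)
  f2 <- fit_niche(g2, n_draws = 100, seed = 7)
  expect_equal(f2$niche_size, 4 * f1$niche_size, tolerance = 1e-9)
})

test_that("directional overlap matches a brute-force Monte-Carlo oracle", {
  mu_a <- c(10, -20); Sig_a <- matrix(c(1.0, 0.3, 0.3, 0.6), 2)
  mu_b <- c(11, -19); Sig_b <- matrix(c(0.8, -0.2, -0.2, 1.1), 2)
  set.seed(31)
  est <- ellipse_overlap_prob(mu_a, Sig_a, mu_b, Sig_b, 0.95, n_mc = 1e5)
  # brute force: direct draws, explicit quadratic-form ellipse test
  set.seed(99)
  X <- MASS::mvrnorm(1e6, mu_a, Sig_a)
  Sb_inv <- solve(Sig_b)
  dev <- sweep(X, 2, mu_b)
  q <- rowSums((dev %*% Sb_inv) * dev)
  oracle <- mean(q <= qchisq(0.95, 2))
  se <- sqrt(oracle * (1 - oracle) * (1 / 1e6 + 1 / 1e5))
  expect_lt(abs(est - oracle), 3 * se + 1e-12)
})

test_that("self-overlap at alpha converges to alpha", {
  mu <- c(10, -20); Sigma <- matrix(c(1, 0.5, 0.5, 1.5), 2)
  a <- fit_niche(mvn_group(500, mu, Sigma, "a", seed = 41),
                 n_draws = 300, seed = 1)
  b <- fit_niche(mvn_group(500, mu, Sigma, "b", seed = 42),
                 n_draws = 300, seed = 2)
  ov <- directional_overlap(a, b, n_mc = 2000, seed = 5)
  expect_equal(attr(ov, "mean"), 0.95, tolerance = 0.03)
})

test_that("widely separated groups do not overlap", {
  a <- fit_niche(mvn_group(50, c(5, -28), diag(2) * 0.25, "a", seed = 51),
                 n_draws = 200, seed = 1)
  b <- fit_niche(mvn_group(50, c(15, -15), diag(2) * 0.25, "b", seed = 52),
                 n_draws = 200, seed = 2)
  ov <- directional_overlap(a, b, n_mc = 2000, seed = 6)
  expect_lt(attr(ov, "mean"), 0.01)
})

test_that("overlap tables are asymmetric: narrow sits inside wide", {
  mu <- c(10, -20)
  wide <- fit_niche(mvn_group(80, mu, diag(2) * 4, "wide", seed = 61),
                    n_draws = 200, seed = 1)
  narrow <- fit_niche(mvn_group(80, mu, diag(2) * 0.05, "narrow", seed = 62),
                      n_draws = 200, seed = 2)
  third <- fit_niche(mvn_group(80, c(12, -18), diag(2) * 0.5, "third", seed = 63),
                     n_draws = 200, seed = 3)
  tab <- overlap_table(list(wide, narrow, third), n_mc = 2000, seed = 9)
  expect_true(all(is.na(diag(tab$mean))))
  off <- tab$mean[!is.na(tab$mean)]
  expect_true(all(off >= 0 & off <= 100))
  expect_gt(tab$mean["narrow", "wide"], 90)
  expect_lt(tab$mean["wide", "narrow"], 15)
  expect_error(overlap_table(list(wide, wide)), "duplicate")
})

test_that("overlap requires matching alpha levels", {
  g <- mvn_group(20, c(10, -20), diag(2), "g", seed = 71)
  a <- fit_niche(g, n_draws = 50, seed = 1, alpha_level = 0.95)
  b <- fit_niche(g, n_draws = 50, seed = 2, alpha_level = 0.90)
  b$group <- "h"
  expect_error(directional_overlap(a, b, alpha_level = 0.95), "mismatch")
})
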