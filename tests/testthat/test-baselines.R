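pair_t7 <- function() {
  # zooplankton vs gastropods/bivalves group means
  baseline_pair("Zooplankton", "Gastropods and Bivalves",
                -24.11, -18.39, 7.58, 9.24)
}

test_that("two-source apportionment evaluates the mixing ratio", {
  p <- pair_t7()
  expect_equal(alpha_base1(-24.11, p)$alpha_base1, 1)
  expect_equal(alpha_base1(-18.39, p)$alpha_base1, 0)
  expect_equal(alpha_base1((-24.11 - 18.39) / 2, p)$alpha_base1, 0.5)
  # anemone mean d13C against the two baselines
  a <- alpha_base1(-20.16, p)
  expect_equal(a$alpha_base1, (-20.16 + 18.39) / (-24.11 + 18.39))
  expect_equal(a$alpha_base1, 0.309, tolerance = 2e-3)
  expect_false(a$clamped)
  expect_error(baseline_pair("a", "b", -20, -20, 5, 6), "degenerate")
})

test_that("out-of-bracket consumers are clamped with the raw value kept", {
  p <- pair_t7()
  a <- alpha_base1(c(-26, -15), p)
  expect_equal(a$alpha_base1, c(1, 0))
  expect_true(all(a$clamped))
  expect_gt(a$raw_alpha[1], 1)
  expect_lt(a$raw_alpha[2], 0)
  # alpha_base1 + alpha_base2 is identically 1
  many <- alpha_base1(seq(-30, -10, by = 0.25), p)
  expect_equal(many$alpha_base1 + many$alpha_base2, rep(1, nrow(many)))
})

test_that("trophic position follows the dual-baseline equation", {
  p <- pair_t7()
  expect_equal(trophic_position(7.58, 1, p), 2)          # at base1
  expect_equal(trophic_position(7.58 + 3.4, 1, p), 3)    # one step up
  expect_equal(trophic_position(12.45, 0, p), 2 + (12.45 - 9.24) / 3.4)
  expect_equal(trophic_position(12.45, 0, p), 2.944, tolerance = 1e-3)
  expect_error(trophic_position(10, 1.2, p), "0, 1")
})

test_that("TP is invariant to swapping baseline labels with alpha -> 1 - alpha", {
  p <- pair_t7()
  swapped <- baseline_pair("Gastropods and Bivalves", "Zooplankton",
                           -18.39, -24.11, 9.24, 7.58)
  d15N <- c(6, 9, 12.45, 14)
  alpha <- c(0.2, 0.5, 0.31, 0.9)
  expect_equal(trophic_position(d15N, alpha, p),
               trophic_position(d15N, 1 - alpha, swapped))
})

test_that("exact baseline mixtures plus m enrichment steps recover TP = 2 + m", {
  p <- pair_t7()
  set.seed(42)
  for (m in c(0, 0.5, 1, 2, 3.3)) {
    alpha <- runif(20)
    d13C <- alpha * p$base1_mean_d13C + (1 - alpha) * p$base2_mean_d13C
    d15N <- alpha * p$base1_mean_d15N + (1 - alpha) * p$base2_mean_d15N +
      m * p$delta15N_per_level
    cons <- data.frame(sample_id = sprintf("c%02d", 1:20), group = "mix",
                       d13C = d13C, d15N = d15N)
    tab <- tp_table(cons, p)
    expect_equal(tab$alpha_base1, alpha, tolerance = 1e-12)
    expect_equal(tab$tp, rep(2 + m, 20), tolerance = 1e-12)
  }
})

test_that("groups are assigned to the baseline their median reliance favours", {
  p <- pair_t7()
  near1 <- data.frame(sample_id = sprintf("j%d", 1:5), group = "jelly",
                      d13C = rnorm(5, -23.9, 0.1), d15N = rnorm(5, 8, 0.3))
  near2 <- data.frame(sample_id = sprintf("b%d", 1:5), group = "benthic",
                      d13C = rnorm(5, -18.6, 0.1), d15N = rnorm(5, 10, 0.3))
  asg <- assign_baseline_by_group(rbind(near1, near2), p)
  expect_equal(asg$baseline[asg$group == "jelly"], "Zooplankton")
  expect_equal(asg$baseline[asg$group == "benthic"], "Gastropods and Bivalves")
  # exact tie goes to the benthic baseline (base2); integer-valued pair so
  # the midpoint ratio is exactly 0.5 in floating point
  pe <- baseline_pair("pelagic", "benthic", -24, -18, 7, 9)
  tie <- data.frame(sample_id = "t1", group = "tie", d13C = -21, d15N = 9)
  expect_equal(assign_baseline_by_group(tie, pe)$median_alpha_base1, 0.5)
  expect_equal(assign_baseline_by_group(tie, pe)$baseline, "benthic")
  expect_error(assign_baseline_by_group(near1, p, groups = "ghost"),
               "missing group")
})

test_that("trophic-level bins are half-open and right-inclusive", {
  expect_equal(tl_bin(3.09), "3")
  expect_equal(tl_bin(c(2.5, 2.5000001)), c("2", "3"))
  expect_equal(tl_bin(c(1.5, 3.5, 4.5)), c("1", "3", "4"))
  expect_equal(tl_bin(0.13), "below TL1")
  expect_equal(tl_bin(0.5), "below TL1")
  expect_equal(tl_bin(0.50001), "1")
  expect_equal(tl_bin(5.2), "5")   # extrapolation above TL 4, same width
  expect_error(tl_bin(NaN), "finite")
})
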