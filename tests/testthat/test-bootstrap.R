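test_that("degenerate residuals collapse the bootstrap to the point estimate", {
  d <- c(10, 30, 50, 80)
  h <- data.frame(top_cm = d - 5, bottom_cm = d + 5, soc_gkg = 5 + 0.1 * d)
  bt <- residual_bootstrap(h, "soc", B = 50, seed = 1)
  expect_false(bt$skipped)
  expect_equal(unname(apply(bt$replicates, 2, sd)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(bt$replicates[1, ]), unname(bt$point), tolerance = 1e-9)
})

test_that("the replicate matrix is deterministic given the seed", {
  set.seed(3)
  h <- make_profile(c(0, 20, 45, 70, 100), function(d) 15 - 0.1 * d,
                    noise_sd = 0.8)
  b1 <- residual_bootstrap(h, "soc", B = 200, seed = 42)
  b2 <- residual_bootstrap(h, "soc", B = 200, seed = 42)
  expect_identical(b1$replicates, b2$replicates)
  b3 <- residual_bootstrap(h, "soc", B = 200, seed = 43)
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("bootstrap is skipped with a warning below 3 horizons", {
  h <- data.frame(top_cm = c(0, 50), bottom_cm = c(50, 100),
                  soc_gkg = c(10, 5))
  expect_warning(bt <- residual_bootstrap(h, "soc", B = 10, seed = 1),
                 "skipped")
  expect_true(bt$skipped)
  expect_null(bt$replicates)
})

test_that("site change replicates reproduce hand-computed changes", {
  # replicate equal to the point estimate -> change equals point change;
  # modern equal to legacy -> all zero
  leg <- list(soc = matrix(rep(c(12, 8, 5, 3), each = 3), 3, byrow = FALSE),
              tn = matrix(rep(c(1.2, 0.9, 0.6, 0.4), each = 3), 3),
              tp = matrix(rep(c(0.7, 0.6, 0.55, 0.5), each = 3), 3))
  modern_same <- list(soc = c(12, 8, 5, 3), tn = c(1.2, 0.9, 0.6, 0.4),
                      tp = c(0.7, 0.6, 0.55, 0.5))
  ch0 <- site_change_replicates(leg, modern_same)
  for (r in c("cn", "cp", "np")) expect_equal(max(abs(ch0[[r]])), 0, tolerance = 1e-12)

  modern <- list(soc = c(15, 8, 5, 3), tn = c(1.2, 0.9, 0.6, 0.4),
                 tp = c(0.7, 0.6, 0.55, 0.5))
  ch <- site_change_replicates(leg, modern)
  expect_equal(ch$cn[1, 1], 100 * (15 / 12 - 1), tolerance = 1e-12)
  expect_equal(ch$cp[2, 1], 25, tolerance = 1e-12)
  expect_equal(max(abs(ch$np)), 0, tolerance = 1e-12)

  # 2-site toy: cross-site mean equals arithmetic mean of the site changes
  ch_site2 <- site_change_replicates(
    lapply(leg, function(m) m * 0.8), modern)
  cross <- (ch$cp[1, ] + ch_site2$cp[1, ]) / 2
  expect_equal(cross, colMeans(rbind(ch$cp[1, ], ch_site2$cp[1, ])),
               tolerance = 1e-12)
})

test_that("directional stability counts sign agreement with the point estimate", {
  expect_equal(directional_stability(c(1, 2, 3), 0.5), 100)
  expect_equal(directional_stability(c(-1, 1, 2, 3), 2), 75)
  expect_equal(directional_stability(c(0, 1), 0), 50) # zero matches zero only
  # replicates symmetric around 0, point estimate +eps -> about 50%
  set.seed(11)
  reps <- rnorm(1000)
  expect_lt(abs(directional_stability(reps, 1e-9) - 50), 5)
})

test_that("bootstrap_summary CI brackets the mean and respects ordering", {
  set.seed(5)
  reps <- rnorm(2000, 10, 2)
  bs <- bootstrap_summary(reps, 10)
  expect_lte(bs$ci_lo, bs$mean)
  expect_gte(bs$ci_hi, bs$mean)
  expect_equal(bs$mean, mean(reps))
  expect_equal(bs$dir_stability_pct, 100)
})

test_that("boundary perturbation: no effect on constant profiles, hand-checkable on linear", {
  # constant concentration -> any boundary shift changes nothing
  h <- data.frame(top_cm = c(0, 30, 60), bottom_cm = c(30, 60, 100),
                  soc_gkg = rep(6, 3))
  bs <- boundary_sensitivity(h, "soc", delta_cm = 2, half_ci = 1)
  expect_equal(bs$boundary_delta, 0, tolerance = 1e-12)
  expect_identical(bs$impact_flag, "negligible")

  # 3-horizon linear toy: oracle recomputed with lm on the shifted midpoints
  f <- function(d) 12 - 0.08 * d
  h$soc_gkg <- f(c(15, 45, 80))
  bs <- boundary_sensitivity(h, "soc", delta_cm = 2)
  for (delta in c(-2, 2)) {
    mids <- (c(0, 30 + delta, 60 + delta) + c(30 + delta, 60 + delta, 100)) / 2
    ab <- oracle_fit(mids, h$soc_gkg, "linear")
    pred <- ab[1] + ab[2] * c(10, 30, 50, 80)
    got <- if (delta < 0) bs$per_scenario$minus else bs$per_scenario$plus
    expect_equal(got, pred, tolerance = 1e-9)
  }
  expect_gt(bs$boundary_delta, 0)
})

test_that("boundary delta grows with the shift size on linear-truth profiles", {
  set.seed(9)
  h <- make_profile(c(0, 25, 55, 100), function(d) 14 - 0.09 * d,
                    noise_sd = 0.5)
  deltas <- vapply(c(1, 2, 4), function(dc) {
    boundary_sensitivity(h, "soc", delta_cm = dc)$boundary_delta
  }, numeric(1))
  expect_true(all(diff(deltas) >= -1e-12))
})

test_that("impact flag thresholds are 0.5 and 1.0 on the boundary ratio", {
  expect_identical(impact_flag(0.3), "negligible")
  expect_identical(impact_flag(0.7), "moderate")
  expect_identical(impact_flag(1.4), "substantial")
})
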