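test_that("VIF screening matches brute-force regressions and removes collinear columns", {
  set.seed(51)
  n <- 120
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  rep <- vif_screen(X)
  expect_length(rep$removed, 0)
  expect_true(all(rep$vif_final < 1.5)) # near-orthogonal draws

  # brute-force oracle on a random correlated table
  S <- matrix(rnorm(n * 4), n, 4)
  Xc <- data.frame(a = S[, 1], b = S[, 1] * 0.8 + S[, 2] * 0.6,
                   c = S[, 3], d = S[, 4])
  got <- vif_screen(Xc, threshold = 1e9)$vif_initial
  brute <- vapply(names(Xc), function(j) {
    r2 <- summary(lm(Xc[[j]] ~ ., data = Xc[setdiff(names(Xc), j)]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  expect_equal(got, brute, tolerance = 1e-8)

  # near-sum column exceeds 5 and is removed
  Xs <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Xs$x3 <- Xs$x1 + Xs$x2 + rnorm(n, 0, 0.05)
  scr <- vif_screen(Xs, threshold = 5)
  expect_true("x3" %in% scr$removed)
  expect_true(all(scr$vif_final <= 5))

  # duplicated column -> infinite VIF, one copy removed
  Xd <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  Xd$x1dup <- Xd$x1
  scr2 <- vif_screen(Xd)
  expect_length(scr2$removed, 1)
  expect_true(scr2$removed %in% c("x1", "x1dup"))
})

test_that("partial correlation reduces to Pearson and recovers a planted partial rho", {
  set.seed(52)
  x <- rnorm(50); y <- 0.5 * x + rnorm(50)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r_partial, cor(x, y), tolerance = 1e-12)
  expect_equal(pc$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(partial_correlation(x, x)$r_partial, 1, tolerance = 1e-12)

  # trivariate Gaussian with partial correlation 0.5 given z:
  # x = z + e1, y = z + e2, corr(e1, e2) = 0.5
  n <- 10000
  z <- rnorm(n)
  e1 <- rnorm(n)
  e2 <- 0.5 * e1 + sqrt(1 - 0.25) * rnorm(n)
  pcz <- partial_correlation(z + e1, z + e2, z)
  expect_lt(abs(pcz$r_partial - 0.5), 0.03)
  expect_equal(pcz$k, 1L)

  # adding an irrelevant confounder barely moves the estimate
  w <- rnorm(50)
  pc2 <- partial_correlation(x, y, w)
  expect_lt(abs(pc2$r_partial - pc$r_partial), 0.1)
})

test_that("forest importance finds a planted signal and is seed-deterministic", {
  set.seed(53)
  n <- 120
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- paste0("x", 1:6)
  X$y <- 3 * X$x1 + rnorm(n, 0, 0.3)
  r <- rf_permutation_importance(X, "y", n_trees = 500, n_perm = 30, seed = 7)
  imp <- r$importance
  expect_identical(imp$predictor[which.max(imp$perm_imp)], "x1")
  expect_identical(imp$predictor[which.max(imp$mdi)], "x1")
  expect_lte(imp$p_value[imp$predictor == "x1"], 1 / 31 + 1e-12)
  expect_gt(r$metrics$oob_r2, 80)
  expect_equal(sum(imp$norm_imp), 1, tolerance = 1e-12)
  # definitional relations among the error metrics
  expect_equal(r$metrics$nrmse_range, r$metrics$rmse / diff(range(X$y)))
  expect_equal(r$metrics$cv_rmse, r$metrics$rmse / sd(X$y))
  # determinism under the same seed
  r2 <- rf_permutation_importance(X, "y", n_trees = 500, n_perm = 30, seed = 7)
  expect_identical(r$importance, r2$importance)
  expect_error(rf_permutation_importance(transform(X, y = 1), "y"), "constant")
})

test_that("log-threshold fitting recovers planted zero crossings", {
  set.seed(54)
  x <- exp(runif(100, log(2), log(20)))
  th <- log_threshold(x, 10 - 5 * log(x))
  expect_equal(th$a, 10, tolerance = 1e-9)
  expect_equal(th$b, -5, tolerance = 1e-9)
  expect_equal(th$r2, 1, tolerance = 1e-9)
  expect_equal(th$x_star, exp(2), tolerance = 1e-9)
  expect_true(th$in_range_flag)

  # scale equivariance: scaling x by c scales the threshold by c
  th3 <- log_threshold(3 * x, 10 - 5 * log(x))
  expect_equal(th3$x_star / th$x_star, 3, tolerance = 1e-6)

  # flat response -> no threshold
  thf <- log_threshold(x, rep(1, 100))
  expect_true(is.na(thf$x_star))
  expect_false(thf$in_range_flag)
  expect_error(log_threshold(c(-1, 2, 3, 4, 5), 1:5), "> 0")
})

test_that("layer ANOVA separates distinct groups and letters shared nulls", {
  set.seed(55)
  # high-power case: means 0 vs 10, sd 1 -> distinct letters
  v <- c(rnorm(30, 0), rnorm(30, 10))
  g <- rep(c("deep", "top"), each = 30)
  an <- layer_anova(v, g)
  expect_lt(an$p, 1e-10)
  expect_false(an$letters[["top"]] == an$letters[["deep"]])
  expect_identical(an$letters[[names(an$group_means)[1]]], "a")

  # single group -> one letter, no F test
  an1 <- suppressWarnings(layer_anova(rnorm(10), rep("only", 10)))
  expect_identical(unname(an1$letters), "a")

  # identical distributions share a letter in most simulated datasets
  share <- vapply(1:20, function(i) {
    vv <- rnorm(80)
    gg <- rep(letters[1:4], each = 20)
    all(layer_anova(vv, gg)$letters == "a")
  }, logical(1))
  expect_gte(sum(share), 17)

  # tiny group excluded with warning
  expect_warning(layer_anova(c(rnorm(20), 1), c(rep("a", 20), "b")),
                 "excluding")
})
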