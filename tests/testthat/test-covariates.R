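test_that("correlation pruning drops planted collinear diet columns, in order", {
  cv <- sim_covariates(150, seed = 91)
  diet <- attr(cv, "diet_cols")
  kept <- prune_correlated(cv[, diet])
  # milk (declared after dairy? order: ssb, milk, dairy, ...) — milk comes
  # first, so dairy is the dropped partner of the pair; either way exactly
  # one of each planted pair survives
  expect_equal(sum(c("milk", "dairy") %in% kept), 1L)
  expect_equal(sum(c("vegetables", "vegetables_no_potato") %in% kept), 1L)
  expect_length(kept, 8L)
  dropped <- attr(kept, "dropped")
  expect_equal(nrow(dropped), 2L)
  expect_true(all(abs(dropped$r) > 0.7))

  # cutoff 1 keeps everything
  expect_length(prune_correlated(cv[, diet], cutoff = 1), 10L)
  # a duplicated column is dropped (r = 1)
  dup <- cv[, diet]
  dup$fruit2 <- dup$fruit
  expect_false("fruit2" %in% prune_correlated(dup))
  # idempotence
  kept2 <- prune_correlated(cv[, kept])
  expect_equal(as.character(kept2), as.character(kept))
  # constant column retained and logged
  cc <- cv[, diet]; cc$constant <- 5
  k3 <- prune_correlated(cc)
  expect_true("constant" %in% k3)
  expect_equal(attr(k3, "constant"), "constant")
})

test_that("multiple regression reproduces closed-form slopes and identities", {
  # hand-computable 5-point bivariate fit
  x <- c(1, 2, 3, 4, 5); y <- c(2.1, 3.9, 6.2, 8.1, 9.8)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  fit <- multi_regression(y, data.frame(x = x))
  expect_equal(fit$coefficients["x", "estimate"], slope, tolerance = 1e-12)
  # exact linear response: adjusted R^2 = 1, residuals 0
  fit_ex <- suppressWarnings(multi_regression(2 * x + 1, data.frame(x = x)))
  expect_equal(fit_ex$adj_r_squared, 1)
  expect_lt(max(abs(residuals(fit_ex$fit))), 1e-12)
  # adjusted R^2 identity
  set.seed(92)
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  yy <- rnorm(40)
  f <- multi_regression(yy, X)
  n <- 40; p <- 2
  expect_equal(f$adj_r_squared,
               1 - (1 - f$r_squared) * (n - 1) / (n - p - 1), tolerance = 1e-12)
  # rank-deficient design errors
  expect_error(multi_regression(yy, data.frame(a = X$a, b = X$a)), "singular")
})

test_that("overall-F p-values are uniform under the null", {
  set.seed(93)
  ps <- vapply(1:300, function(i) {
    X <- data.frame(a = rnorm(30), b = rnorm(30))
    multi_regression(rnorm(30), X)$overall_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("best subset selects the planted predictor and matches brute-force BIC", {
  set.seed(94)
  X <- as.data.frame(matrix(rnorm(300 * 10), 300, 10))
  names(X) <- paste0("x", 1:10)
  y <- 2 * X$x3 + rnorm(300)
  bs <- best_subset(y, X)
  expect_true("x3" %in% bs$selected)
  expect_equal(bs$n_subsets, 1024L)

  # independent brute-force recomputation on p <= 8 via lm + BIC
  set.seed(95)
  X8 <- as.data.frame(matrix(rnorm(80 * 5), 80, 5))
  names(X8) <- paste0("x", 1:5)
  y8 <- 1.5 * X8$x2 - X8$x4 + rnorm(80)
  bs8 <- best_subset(y8, X8)
  combos <- unlist(lapply(0:5, function(k) combn(5, k, simplify = FALSE)),
                   recursive = FALSE)
  bics <- vapply(combos, function(s) {
    d <- if (length(s)) X8[, s, drop = FALSE] else X8[, 0, drop = FALSE]
    d$.y <- y8
    stats::BIC(lm(.y ~ ., data = d))
  }, numeric(1))
  best_combo <- combos[[which.min(bics)]]
  expect_setequal(bs8$selected, names(X8)[best_combo])
  # p = 2 visits exactly 4 subsets
  expect_equal(best_subset(rnorm(30), X8[1:30, 1:2])$n_subsets, 4L)
  expect_error(best_subset(y8, cbind(X8, X8, X8, X8, X8)), "20")
})

test_that("pure-noise responses usually select the intercept-only model under BIC", {
  set.seed(96)
  empty <- vapply(1:40, function(i) {
    X <- as.data.frame(matrix(rnorm(100 * 5), 100, 5))
    length(best_subset(rnorm(100), X)$selected) == 0L
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("joint functional regression handles confounding, suppression and id mismatch", {
  n <- 250
  set.seed(97)
  diet <- rnorm(n)
  # confounding: diet drives both the microbiota summary and the curves
  micro_conf <- 0.8 * diet + 0.6 * rnorm(n)
  beta_d <- function(gr) 0.05 * sin(pi * gr / 730)
  cm <- make_curves(n, seed = 97, effects = list(beta_d), X = cbind(diet))
  ids <- rownames(cm$curves$coefs)
  ms <- data.frame(child_id = ids, micro = micro_conf)
  dt <- data.frame(child_id = ids, diet = diet)
  p_marg <- test_coefficient(fit_fosr(cm$curves, ms["micro"]), 2, "PCA")
  p_joint <- test_coefficient(joint_fosr(cm$curves, ms, dt), "micro", "PCA")
  expect_gt(p_joint, p_marg)   # microbiota signal attenuates given diet

  # suppression: diet masks a real microbiota effect
  set.seed(98)
  micro_real <- rnorm(n)
  diet2 <- 0.9 * micro_real + 0.45 * rnorm(n)
  beta_m <- function(gr) 0.03 * sin(pi * gr / 730)
  beta_d2 <- function(gr) -0.03 * sin(pi * gr / 730) / 0.9
  cm2 <- make_curves(n, seed = 98, effects = list(beta_m, beta_d2),
                     X = cbind(micro_real, diet2))
  ids2 <- rownames(cm2$curves$coefs)
  ms2 <- data.frame(child_id = ids2, micro = micro_real)
  dt2 <- data.frame(child_id = ids2, diet = diet2)
  p_marg2 <- test_coefficient(fit_fosr(cm2$curves, ms2["micro"]), 2, "PCA")
  p_joint2 <- test_coefficient(joint_fosr(cm2$curves, ms2, dt2), "micro", "PCA")
  expect_lt(p_joint2, p_marg2)  # effect emerges once diet enters

  # an all-zero diet column leaves the microbiota curve unchanged
  dt0 <- data.frame(child_id = ids, flat = 0)
  f_base <- fit_fosr(cm$curves, ms["micro"])
  f_flat <- joint_fosr(cm$curves, ms, dt0)
  expect_lt(max(abs(f_flat$coef_curves["micro", ] -
                      f_base$coef_curves["micro", ])), 1e-8)

  # orphan ids are named in the join error
  bad <- data.frame(child_id = c(ids[-1], "GHOST"), diet = diet)
  expect_error(joint_fosr(cm$curves, ms, bad), "GHOST")
})

test_that("Kruskal-Wallis wrapper matches the base test for multi-level factors", {
  set.seed(99)
  v <- rnorm(60)
  g <- rep(c("low", "mid", "high"), each = 20)
  expect_equal(kruskal_factor_test(v, g), kruskal.test(v, factor(g))$p.value)
})
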