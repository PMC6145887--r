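test_that("FPCA recovers a known two-component model from dense noisy data", {
  cfg <- synthetic_config(n_children = 150, visit_ages = seq(0, 730, by = 30),
                          missing_rate = 0, noise_sd = 0.004, seed = 21)
  g <- sim_growth(cfg)
  m <- fit_fpca(g$records)
  tr <- g$truth
  rng <- diff(range(tr$true_curves))
  mu_true <- colMeans(tr$true_curves) - colMeans(tr$scores %*% t(tr$phi))
  expect_lt(sqrt(mean((m$mu - mu_true)^2)) / rng, 0.05)
  expect_gte(m$K, 2L)
  expect_gt(abs(cor(m$phi[, 1], tr$phi[, 1])), 0.95)
  expect_gt(abs(cor(m$phi[, 2], tr$phi[, 2])), 0.95)
  # noise variance estimated near truth
  expect_lt(abs(sqrt(m$sigma2) - 0.004), 0.002)
})

test_that("FPCA eigenfunctions are orthonormal with ordered eigenvalues", {
  cfg <- synthetic_config(n_children = 60, seed = 22)
  g <- sim_growth(cfg)
  m <- fit_fpca(g$records)
  w <- growthmicro:::trapez_weights(m$grid)
  G <- t(m$phi) %*% (m$phi * w)
  expect_equal(G, diag(m$K), tolerance = 1e-6)
  expect_true(all(diff(m$lambda) <= 1e-12))
  expect_true(all(m$lambda >= 0))
  expect_gte(m$sigma2, 0)
})

test_that("degenerate case: one common curve gives zero variance and zero scores", {
  ages <- c(0, 100, 250, 400, 600, 730)
  common <- 0.07 + 0.0001 * ages
  recs <- lapply(1:25, function(i) {
    anthro_record(paste0("c", i), "female",
                  data.frame(age_days = ages, weight_kg = common * 50,
                             length_cm = 50))
  })
  m <- fit_fpca(recs)
  expect_equal(m$K, 0L)
  expect_equal(ncol(m$scores), 0L)
  cs <- predict_curves(m)
  vals <- eval_curves(cs, m$grid)
  # every curve equals the mean
  expect_lt(max(abs(sweep(vals, 2, m$mu))), 1e-8)
})

test_that("conditional-expectation scores agree with inner-product scores on dense noiseless data", {
  cfg <- synthetic_config(n_children = 80, visit_ages = seq(0, 730, by = 10),
                          missing_rate = 0, noise_sd = 0, seed = 23)
  g <- sim_growth(cfg)
  m <- fit_fpca(g$records)
  # ordinary FPCA scores: quadrature inner products of centered obs curves
  ages <- seq(0, 730, by = 10)
  idx <- match(ages, g$truth$grid)
  w <- growthmicro:::trapez_weights(ages)
  mu_at <- approx(m$grid, m$mu, ages)$y
  phi_at <- apply(m$phi, 2, function(p) approx(m$grid, p, ages)$y)
  cent <- sweep(g$truth$true_curves[, idx], 2, mu_at)
  ip_scores <- cent %*% (phi_at * w)
  keep <- seq_len(min(2L, m$K))
  scale_k <- apply(ip_scores[, keep, drop = FALSE], 2, sd)
  for (k in keep) {
    expect_lt(max(abs(m$scores[, k] - ip_scores[, k])) / scale_k[k], 0.05)
  }
})

test_that("predicted curves reconstruct dense observations and project cleanly", {
  cfg <- synthetic_config(n_children = 40, visit_ages = seq(0, 730, by = 15),
                          missing_rate = 0, noise_sd = 0, seed = 24)
  g <- sim_growth(cfg)
  m <- fit_fpca(g$records)
  cs <- predict_curves(m)
  expect_s3_class(cs, "curve_set")
  expect_equal(ncol(cs$coefs), 102L)
  vals <- eval_curves(cs, m$grid)
  model_vals <- matrix(rep(m$mu, 40), 40, byrow = TRUE)
  if (m$K > 0) model_vals <- model_vals + m$scores %*% t(m$phi)
  # 102-function basis is rich: projection residual tiny vs curve range
  expect_lt(max(abs(vals - model_vals)),
            1e-3 * diff(range(model_vals)))
  # reconstruction matches the noiseless observations reasonably
  obs_idx <- match(seq(0, 730, by = 15), m$grid)
  err <- abs(vals[, obs_idx] - g$truth$true_curves[, obs_idx])
  expect_lt(median(err), 0.01)
})

test_that("scores all zero reproduce the mean curve exactly", {
  cfg <- synthetic_config(n_children = 30, seed = 25)
  g <- sim_growth(cfg)
  m <- fit_fpca(g$records)
  m$scores[] <- 0
  vals <- eval_curves(predict_curves(m), m$grid)
  # equal to mu up to the (tiny) 102-spline projection residual
  expect_lt(max(abs(sweep(vals, 2, m$mu))), 1e-4)
})

test_that("curve sets round-trip through CSV plus basis JSON", {
  cm <- make_curves(8, seed = 31)
  dir <- withr::local_tempdir()
  write_curves(cm$curves, file.path(dir, "c.csv"), file.path(dir, "b.json"))
  back <- read_curves(file.path(dir, "c.csv"), file.path(dir, "b.json"))
  expect_equal(back$coefs, cm$curves$coefs, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$basis$knots, cm$curves$basis$knots)
})

test_that("registration leaves identical curves alone and collapses warped copies", {
  b <- spline_basis(40)
  gr <- seq(0, 730, length.out = 500)
  template <- 0.07 + 0.07 * (gr / 730)^0.7
  # identical curves: warps stay within a day of the identity
  cs_id <- project_curves(matrix(rep(template, 6), 6, byrow = TRUE), gr, b)
  reg_id <- register_curves(cs_id, max_iter = 1)
  dev <- max(vapply(reg_id$warps, function(h) max(abs(h(gr) - gr)), numeric(1)))
  expect_lt(dev, 1)
  # endpoints fixed
  ends <- vapply(reg_id$warps, function(h) h(c(0, 730)), numeric(2))
  expect_equal(as.vector(ends), rep(c(0, 730), 6))

  # warped copies of one template collapse (>= 50% variance reduction)
  set.seed(32)
  vals <- t(vapply(1:10, function(i) {
    h <- function(t) 730 * ((t / 730)^(runif(1, 0.8, 1.25)))
    approx(gr, template, h(gr))$y
  }, numeric(length(gr))))
  cs <- project_curves(vals, gr, b)
  reg <- register_curves(cs, max_iter = 2)
  v0 <- mean(apply(eval_curves(cs, gr), 2, var))
  v1 <- mean(apply(eval_curves(reg, gr), 2, var))
  expect_lt(v1 / v0, 0.5)
  # warps strictly increasing
  for (h in reg$warps) expect_true(all(diff(h(gr)) > 0))
})
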