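test_that("simulated taxonomic trees are bifurcating, phylum-complete and deterministic", {
  tr <- sim_tax_tree(4, seed = 1)
  expect_equal(length(tr$tip.label), 4L)
  expect_equal(tr$Nnode, 3L)          # rooted bifurcating: n - 1 internal nodes
  expect_true(ape::is.binary(tr))

  tr75 <- sim_tax_tree(75, seed = 7)
  ph <- genus_phyla(tr75)
  expect_equal(length(ph), 75L)
  expect_false(anyNA(ph))
  expect_true(all(c("Firmicutes", "Bacteroidetes") %in% ph))
  expect_equal(anyDuplicated(tr75$tip.label), 0L)

  expect_identical(ape::write.tree(sim_tax_tree(75, seed = 7)),
                   ape::write.tree(tr75))
  expect_error(sim_tax_tree(3), "n_genera")
})

test_that("simulated abundances respect depth, sparsity and sibling correlation", {
  tr <- sim_tax_tree(4, seed = 1)
  tb <- sim_abundances(tr, 50, 10000, sparsity_frac = 0.5, seed = 2)
  expect_true(all(rowSums(tb$counts) == 10000))
  rare <- colSums(tb$counts < 5) > 0.9 * 50
  expect_equal(sum(rare), 2L)         # round(0.5 * 4) planted rare genera

  tb0 <- sim_abundances(tr, 50, 10000, sparsity_frac = 0, seed = 2)
  expect_equal(sum(colSums(tb0$counts < 5) > 0.9 * 50), 0L)

  # correlated sibling pair survives the multinomial layer (expectation
  # over seeds > 0.8)
  tr20 <- sim_tax_tree(20, seed = 3)
  pair <- growthmicro:::sibling_pair(tr20)
  rs <- vapply(1:5, function(s) {
    t2 <- sim_abundances(tr20, 100, 20000, 0.3, list(pair), seed = s)
    cor(t2$counts[, pair[1]], t2$counts[, pair[2]])
  }, numeric(1))
  expect_gt(mean(rs), 0.8)

  # non-sibling pair rejected
  ph <- genus_phyla(tr20)
  far <- c(names(ph)[ph == "Firmicutes"][1], names(ph)[ph == "Bacteroidetes"][1])
  expect_error(sim_abundances(tr20, 10, 1000, 0, list(far), seed = 1),
               "sibling")
})

test_that("emitted rare-genus fraction tracks sparsity_frac", {
  tr <- sim_tax_tree(40, seed = 5)
  tb <- sim_abundances(tr, 120, 20000, sparsity_frac = 0.4, seed = 6)
  rare_frac <- mean(colSums(tb$counts < 5) > 0.9 * 120)
  expect_lt(abs(rare_frac - 0.4), 0.1)
})

test_that("growth generator honors missingness, noise and effect configuration", {
  cfg0 <- synthetic_config(n_children = 20, missing_rate = 0, noise_sd = 0,
                           seed = 4)
  g0 <- sim_growth(cfg0)
  expect_true(all(vapply(g0$records, function(r) nrow(r$visits), 1L) == 7L))
  # zero noise, zero effects: observed index equals the true curve at visits
  r1 <- g0$records[[1]]
  gi <- growth_index(r1)
  idx <- match(gi$age_days, g0$truth$grid)
  expect_equal(gi$index, g0$truth$true_curves[1, idx], tolerance = 1e-10)

  # birth visit never missing under heavy missingness
  cfg_m <- synthetic_config(n_children = 50, missing_rate = 0.6, seed = 4)
  gm <- sim_growth(cfg_m)
  expect_true(all(vapply(gm$records, function(r) r$visits$age_days[1], 1) == 0))

  # truth eigenfunctions orthonormal, eigenvalues nonincreasing
  w <- growthmicro:::trapez_weights(g0$truth$grid)
  G <- t(g0$truth$phi) %*% (g0$truth$phi * w)
  expect_equal(G, diag(2), tolerance = 1e-4)
  expect_true(all(diff(g0$truth$lambda) <= 0))

  # unknown predictor in effect_map errors
  cfg_e <- synthetic_config(n_children = 20,
                            effect_map = list(list(predictor = "nope",
                                                   shape = "sin",
                                                   amplitude = 0.01)))
  expect_error(sim_growth(cfg_e, data.frame(x = rnorm(20))), "unknown predictor")
})

test_that("planted effects are recoverable from noiseless dense truth curves", {
  n <- 200
  x <- rnorm(n)
  cfg <- synthetic_config(n_children = n, missing_rate = 0, noise_sd = 0,
                          effect_map = list(list(predictor = "oral_div",
                                                 shape = "sin",
                                                 amplitude = 0.05)),
                          seed = 8)
  g <- sim_growth(cfg, data.frame(oral_div = x))
  cs <- project_curves(g$truth$true_curves, g$truth$grid, spline_basis(30))
  fit <- fit_fosr(cs, data.frame(oral_div = x), lambda_s = 0)
  # positive planted effect -> positive estimated coefficient curve
  expect_true(all(fit$coef_curves["oral_div",
                                  fit$grid > 30 & fit$grid < 700] > 0))
})

test_that("growth reference behaves like an LMS standard", {
  ref <- sim_reference(measure = "weight")
  expect_true(all(ref$S > 0 & ref$S < 0.3))
  expect_true(all(ref$L >= -2 & ref$L <= 2))
  for (sx in c("male", "female")) {
    expect_true(all(diff(ref$M[ref$sex == sx]) > 0))
  }
  # value at the median is z = 0
  m100 <- ref$M[ref$sex == "male" & ref$age_days == 100]
  expect_equal(lms_zscore(m100, 100, "male", ref), 0)
})

test_that("covariate table plants collinear diet columns and valid frequencies", {
  cv <- sim_covariates(100, seed = 6)
  diet <- attr(cv, "diet_cols")
  expect_length(diet, 10L)
  expect_true(all(as.matrix(cv[, diet]) >= 0))
  expect_true(all(as.matrix(cv[, diet]) <= 42))
  expect_gt(cor(cv$milk, cv$dairy), 0.7)
  expect_gt(cor(cv$vegetables, cv$vegetables_no_potato), 0.7)
  expect_identical(cv, sim_covariates(100, seed = 6))
  expect_equal(ncol(cv) - 1L, 19L)    # 9 factors + 10 diet frequencies
})

test_that("cohort artifacts round-trip through the file readers", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_children = 15, n_genera = 10, seed = 9)
  co <- sim_cohort(cfg, depth = 2000, dir = dir)

  tb <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(tb$counts, co$counts$counts)
  expect_equal(tb$taxonomy, co$counts$taxonomy)

  recs <- read_anthro(file.path(dir, "anthro.csv"))
  expect_equal(length(recs), 15L)
  expect_equal(recs[[1]]$visits$weight_kg, co$records[[1]]$visits$weight_kg)

  ref <- read_reference(file.path(dir, "reference_weight.csv"))
  expect_s3_class(ref, "growth_reference")

  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, colnames(tb$counts))
})
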