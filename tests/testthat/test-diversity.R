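test_that("counts TSV round-trips with taxonomy, and malformed tables error", {
  tb <- toy_rare_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(tb, path)
  back <- read_counts(path)
  expect_equal(back$counts, tb$counts)
  expect_equal(back$taxonomy, tb$taxonomy)

  # duplicate taxon column
  bad <- tb$counts; colnames(bad) <- c("A", "A", "C", "D")
  expect_error(abundance_table(bad, toy_taxonomy), "duplicate")
  # empty table
  expect_error(abundance_table(tb$counts[0, , drop = FALSE], toy_taxonomy),
               "0 samples")
  # non-integer cell
  writeLines(c("sample_id\tk__Bacteria;p__F;g__A", "S1\t1.5"), path)
  expect_error(read_counts(path), "non-integer")
})

test_that("rarefaction subsamples to exact depth, deterministically, dropping shallow samples", {
  set.seed(41)
  counts <- matrix(rpois(80, 120), 20, 4,
                   dimnames = list(paste0("S", 1:20), c("A", "B", "C", "D")))
  counts[1, ] <- c(3, 2, 1, 0)    # shallow sample
  tb <- abundance_table(counts, toy_taxonomy)
  expect_warning(r <- rarefy_counts(tb, 200, seed = 1), "dropping")
  expect_true(all(rowSums(r$counts) == 200))
  expect_equal(attr(r, "dropped"), "S1")
  # depth equal to a sample total leaves it unchanged
  tot2 <- sum(counts[2, ])
  r2 <- suppressWarnings(rarefy_counts(tb, tot2, seed = 1))
  expect_equal(r2$counts["S2", ], counts[2, ])
  # determinism
  ra <- suppressWarnings(rarefy_counts(tb, 200, seed = 7))
  rb <- suppressWarnings(rarefy_counts(tb, 200, seed = 7))
  expect_identical(ra$counts, rb$counts)
  expect_error(rarefy_counts(tb, 0), "positive")
})

test_that("rarefaction preserves expected proportions", {
  counts <- matrix(c(600, 300, 100, 0), 1, 4,
                   dimnames = list("S1", c("A", "B", "C", "D")))
  tb <- abundance_table(counts, toy_taxonomy)
  props <- rowMeans(vapply(1:200, function(s) {
    rarefy_counts(tb, 100, seed = s)$counts[1, ] / 100
  }, numeric(4)))
  # binomial 99% CI half-width at n = 200*100 draws is ~ 0.009
  expect_lt(max(abs(props - c(0.6, 0.3, 0.1, 0))), 0.015)
})

test_that("alpha diversity matches hand-computed identities", {
  counts <- rbind(S1 = c(25, 25, 25, 25),   # uniform over 4 phyla-mapped taxa
                  S2 = c(100, 0, 0, 0),     # single taxon
                  S3 = c(50, 25, 25, 0))    # p = (0.5, 0.25, 0.25)
  tax <- c(A = "P1", B = "P2", C = "P3", D = "P4")
  colnames(counts) <- names(tax)
  tb <- abundance_table(counts, tax)
  d <- alpha_diversity(tb, level = "phylum")
  expect_equal(d$inverse_simpson[1], 4)
  expect_equal(d$inverse_simpson[2], 1)
  expect_equal(d$shannon[2], 0)
  expect_equal(d$inverse_simpson[3], 8 / 3)
  expect_equal(1 / d$inverse_simpson[3], 0.375)
  expect_true(all(d$inverse_simpson >= 1))

  counts0 <- rbind(S1 = c(0, 0, 0, 0)); colnames(counts0) <- names(tax)
  expect_error(alpha_diversity(abundance_table(counts0, tax)), "all-zero")
})

test_that("inverse Simpson is maximized by the uniform composition", {
  # enumeration over small compositional grids of 3 phyla
  tax <- c(A = "P1", B = "P2", C = "P3")
  best <- -Inf; best_comp <- NULL
  for (a in 1:8) for (b in 1:8) for (cc in 1:8) {
    m <- matrix(c(a, b, cc), 1, dimnames = list("S", names(tax)))
    iv <- alpha_diversity(abundance_table(m, tax))$inverse_simpson
    if (iv > best + 1e-12) { best <- iv; best_comp <- c(a, b, cc) }
  }
  expect_equal(best, 3)
  expect_true(length(unique(best_comp)) == 1L)
})

test_that("F:B ratio sums phylum reads and flags zero Bacteroidetes as undefined", {
  counts <- rbind(S1 = c(120, 80, 100, 0),  # F = 200, B = 100
                  S2 = c(0, 0, 50, 50),     # F = 0 -> ratio 0
                  S3 = c(10, 10, 0, 0))     # B = 0 -> undefined
  colnames(counts) <- names(toy_taxonomy)
  tb <- abundance_table(counts, toy_taxonomy)
  fb <- suppressMessages(fb_ratio(tb))
  expect_equal(fb$ratio[1], 2.0)
  expect_equal(fb$ratio[2], 0.0)
  expect_true(is.na(fb$ratio[3]))
  expect_false(fb$defined[3])

  tax2 <- c(A = "P1", B = "P1", C = "P2", D = "P2")
  expect_error(fb_ratio(abundance_table(counts, tax2)), "Firmicutes")
})

test_that("phylum proportion tests reproduce the chi-squared construction", {
  mk <- function(p_f, n) {
    counts <- cbind(A = round(1000 * p_f), B = 0, C = round(1000 * (1 - p_f)),
                    D = 0)
    counts <- counts[rep(1, n), ]
    rownames(counts) <- paste0("S", 1:n)
    abundance_table(counts, toy_taxonomy)
  }
  # identical groups: p = 1 after correction
  res_eq <- phylum_proportion_tests(list(g1 = mk(0.5, 40), g2 = mk(0.5, 40)),
                                    phyla = "Firmicutes", m_tests = 24)
  expect_equal(res_eq$p_bonferroni, 1)
  # 0.9 vs 0.1 with N = 100: corrected p far below 0.001
  res_d <- phylum_proportion_tests(list(g1 = mk(0.9, 100), g2 = mk(0.1, 100)),
                                   phyla = "Firmicutes", m_tests = 24)
  expect_lt(res_d$p_bonferroni, 0.001)
  # m_tests = 1 returns the raw p; matches prop.test directly
  res_raw <- phylum_proportion_tests(list(g1 = mk(0.7, 50), g2 = mk(0.4, 50)),
                                     phyla = "Firmicutes", m_tests = 1)
  oracle <- prop.test(c(round(0.7 * 50), round(0.4 * 50)), c(50, 50))$p.value
  expect_equal(res_raw$p_raw, oracle)
  expect_equal(res_raw$p_bonferroni, res_raw$p_raw)
})

test_that("one-tailed Mann-Whitney matches the exact U distribution", {
  # complete separation with n = m = 3: P = 1 / C(6,3) = 0.05
  expect_equal(mw_one_tailed(c(1, 2, 3), c(4, 5, 6), "less"), 0.05)
  # symmetric: identical samples give exactly 1/2 either way
  p_sym <- mw_one_tailed(c(1, 2, 3, 4), c(1, 2, 3, 4), "less")
  expect_equal(p_sym, 0.5)
  expect_equal(p_sym, mw_one_tailed(c(1, 2, 3, 4), c(1, 2, 3, 4), "greater"))
  # swapping groups with mirrored direction is identical
  set.seed(42)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(mw_one_tailed(a, b, "less"), mw_one_tailed(b, a, "greater"))
  # no two-sided default
  expect_error(mw_one_tailed(a, b), "direction")
})

test_that("Bray-Curtis dissimilarity matches hand computations", {
  counts <- rbind(S1 = c(6, 0, 0, 0), S2 = c(2, 4, 0, 0), S3 = c(6, 0, 0, 0),
                  S4 = c(0, 0, 5, 5))
  colnames(counts) <- names(toy_taxonomy)
  tb <- abundance_table(counts, toy_taxonomy)
  d <- bray_curtis(tb)
  expect_equal(d["S1", "S2"], 2 / 3)   # (|6-2| + 4) / 12
  expect_equal(d["S1", "S3"], 0)       # identical
  expect_equal(d["S1", "S4"], 1)       # disjoint supports
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})
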