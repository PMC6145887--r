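test_that("stage 1 merges the planted rare leaf into its sibling, conserving counts", {
  tb <- toy_rare_table()
  s1 <- merge_low_abundance(tb)
  res <- s1$result
  expect_length(res$groups, 3L)
  # D (rare in 10/10 samples) merged into its sibling C
  grp_cd <- res$groups[vapply(res$groups, function(g) "D" %in% g, TRUE)]
  expect_equal(sort(grp_cd[[1]]), c("C", "D"))
  # counts conserved to the unit
  expect_equal(rowSums(s1$matrix), rowSums(tb$counts))
  expect_equal(s1$matrix[, names(grp_cd)], tb$counts[, "C"] + tb$counts[, "D"],
               ignore_attr = TRUE)
  # audit records the rarity rule
  expect_equal(res$audit$stage, 1L)
  expect_equal(res$audit$rule, "rarity")
})

test_that("stage 1 without rare taxa is the identity with an empty audit log", {
  set.seed(51)
  tb <- toy_table(matrix(rpois(40, 80) + 20, 10, 4,
                         dimnames = list(NULL, c("A", "B", "C", "D"))))
  s1 <- merge_low_abundance(tb)
  expect_length(s1$result$groups, 4L)
  expect_true(all(lengths(s1$result$groups) == 1L))
  expect_equal(nrow(s1$result$audit), 0L)
  expect_equal(unname(s1$matrix), unname(tb$counts))
})

test_that("all-rare taxa collapse to a single group holding the row sums", {
  set.seed(52)
  tb <- toy_table(matrix(rbinom(40, 2, 0.2), 10, 4,
                         dimnames = list(NULL, c("A", "B", "C", "D"))))
  s1 <- merge_low_abundance(tb)
  expect_length(s1$result$groups, 1L)
  expect_setequal(s1$result$groups[[1]], c("A", "B", "C", "D"))
  expect_equal(unname(s1$matrix[, 1]), unname(rowSums(tb$counts)))
})

test_that("stage 2 merges perfectly correlated siblings by element-wise mean", {
  cnt <- cbind(A = 1:10 * 2, B = 1:10 * 3, C = rpois(10, 30) + 5,
               D = rev(1:10) * 4)
  tb <- toy_table(cnt)
  res <- merge_correlated(tb)
  ab <- res$groups[vapply(res$groups, function(g) setequal(g, c("A", "B")), TRUE)]
  expect_length(ab, 1L)
  expect_equal(unname(res$matrix[, names(ab)]), unname((cnt[, "A"] + cnt[, "B"]) / 2))
  # C and D are siblings but negatively correlated: untouched
  expect_true(all(c("C", "D") %in% names(res$groups)))
  expect_equal(res$audit$rule, "correlation")
  expect_gt(res$audit$statistic, 0.99)
})

test_that("chained correlated siblings collapse in traversal order with two audit entries", {
  tr <- ape::read.tree(text = "((A:1,B:1,C:1)p__Firmicutes:1,(D:1,E:1)p__Bacteroidetes:1)root;")
  base <- 1:12
  cnt <- cbind(A = base * 2, B = base * 2 + 1, C = base * 3 + 2,
               D = rpois(12, 40) + 10, E = rev(base) * 5)
  rownames(cnt) <- paste0("S", 1:12)
  tax <- c(A = "Firmicutes", B = "Firmicutes", C = "Firmicutes",
           D = "Bacteroidetes", E = "Bacteroidetes")
  tb <- abundance_table(cnt, tax, tr)
  res <- merge_correlated(tb)
  abc <- res$groups[vapply(res$groups, function(g) setequal(g, c("A", "B", "C")), TRUE)]
  expect_length(abc, 1L)
  expect_equal(sum(res$audit$stage == 2L), 2L)
})

test_that("constant-zero columns are never merged by the correlation rule", {
  cnt <- cbind(A = 1:10, B = 2 * (1:10), C = rep(0L, 10), D = rep(0L, 10))
  tb <- toy_table(cnt)
  res <- merge_correlated(tb)
  expect_true("C" %in% names(res$groups))
  expect_true("D" %in% names(res$groups))
})

test_that("two-stage merge handles planted structure and is deterministic", {
  tr <- sim_tax_tree(30, seed = 61)
  pair <- growthmicro:::sibling_pair(tr)
  tb <- sim_abundances(tr, 80, 15000, sparsity_frac = 0.5,
                       corr_blocks = list(pair), seed = 61)
  res <- merge_taxa(tb)
  expect_lt(length(res$groups), 30L)
  # rare leaves absorbed: no surviving singleton group is rare
  single <- names(res$groups)[lengths(res$groups) == 1L]
  for (g in single) {
    expect_false(sum(res$matrix[, g] < 5) > 0.9 * 80)
  }
  # the planted correlated pair ended up in one group
  holds_pair <- vapply(res$groups, function(g) all(pair %in% g), TRUE)
  expect_equal(sum(holds_pair), 1L)
  # determinism
  res2 <- merge_taxa(tb)
  expect_identical(res$groups, res2$groups)
  expect_identical(res$matrix, res2$matrix)

  # no structure, no merges: groups = genera
  tb0 <- sim_abundances(tr, 80, 15000, sparsity_frac = 0, seed = 62)
  res0 <- merge_taxa(tb0)
  if (nrow(res0$audit) == 0L) expect_length(res0$groups, 30L)
})

test_that("merge result is a partition and both stages are idempotent", {
  tr <- sim_tax_tree(20, seed = 63)
  tb <- sim_abundances(tr, 60, 12000, sparsity_frac = 0.4, seed = 63)
  s1 <- merge_low_abundance(tb)
  # stage 1 idempotent: no surviving group fires the rarity rule
  for (g in colnames(s1$matrix)) {
    expect_false(sum(s1$matrix[, g] < 5) > 0.9 * 60)
  }
  res <- merge_correlated(s1)
  # partition: every genus in exactly one group
  members <- unlist(res$groups)
  expect_setequal(members, tr$tip.label)
  expect_equal(anyDuplicated(members), 0L)
  # stage 2 idempotent: no surviving sibling pair exceeds the threshold in
  # a rerun of the full procedure on equal inputs
  expect_identical(merge_taxa(tb)$groups, res$groups)

  # grand total conserved through stage 1
  expect_equal(sum(s1$matrix), sum(tb$counts))
})

test_that("taxa missing from the tree are reported", {
  cnt <- cbind(A = 1:5, B = 2:6, X = 3:7)
  rownames(cnt) <- paste0("S", 1:5)
  tb <- abundance_table(cnt, c(A = "Firmicutes", B = "Firmicutes",
                               X = "Firmicutes"))
  expect_error(merge_low_abundance(tb, toy_tree()), "X")
})
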