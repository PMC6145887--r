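#' Rarefy an abundance table to a common depth
#'
#' Uniform subsampling of each sample's reads without replacement so that
#' every retained sample sums exactly to `depth` (the cohort analyses used
#' 100,000 reads). Samples with fewer than `depth` reads are dropped with a
#' warning and recorded in the `dropped` attribute.
#'
#' @param table an `abundance_table`.
#' @param depth target read depth (> 0); default 100000.
#' @param seed integer seed for the subsampling.
#' @return rarefied `abundance_table` (attribute `dropped` lists removed
#'   samples).
#' @export
rarefy_counts <- function(table, depth = 100000, seed = 1L) {
  stopifnot(inherits(table, "abundance_table"))
  if (depth <= 0) stop_invalid("depth must be positive")
  totals <- rowSums(table$counts)
  drop <- totals < depth
  if (all(drop)) stop_invalid("no sample reaches depth %g", depth)
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %g: %s", sum(drop), depth,
                    paste(rownames(table$counts)[drop], collapse = ", ")))
  }
  kept <- table$counts[!drop, , drop = FALSE]
  out <- with_seed(substream_seed(seed, "rarefy"), {
    # vegan warns on count tables whose smallest positive entry is > 1 (a
    # raw-data heuristic); depths are validated above, so silence it
    suppressWarnings(vegan::rrarefy(kept, depth))
  })
  res <- abundance_table(out, table$taxonomy, table$tree)
  attr(res, "dropped") <- rownames(table$counts)[drop]
  res
}

# Aggregate counts to a taxonomic level ("genus" = identity, "phylum" =
# sum within phyla).
aggregate_level <- function(table, level = c("phylum", "genus")) {
  level <- match.arg(level)
  if (level == "genus") return(table$counts)
  phyla <- table$taxonomy
  t(rowsum(t(table$counts), group = phyla))
}

#' Alpha diversity summaries
#'
#' Simpson concentration `D = sum p_i^2`, inverse Simpson `1/D`, and
#' Shannon `-sum p_i log p_i` per sample, computed (as in the original
#' analyses, via vegan) on counts aggregated to `level` — phylum by
#' default.
#'
#' @param table an `abundance_table` (rarefy first for comparability).
#' @param level `"phylum"` (default) or `"genus"`.
#' @return data.frame: sample_id, inverse_simpson, shannon, simpson.
#' @export
alpha_diversity <- function(table, level = c("phylum", "genus")) {
  m <- aggregate_level(table, match.arg(level))
  if (any(rowSums(m) == 0)) {
    stop_invalid("all-zero sample(s): %s — diversity undefined",
                 paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  }
  data.frame(sample_id = rownames(m),
             inverse_simpson = vegan::diversity(m, index = "invsimpson"),
             shannon = vegan::diversity(m, index = "shannon"),
             simpson = vegan::diversity(m, index = "simpson"),
             row.names = NULL)
}

#' Firmicutes-to-Bacteroidetes ratio
#'
#' Total reads assigned to Firmicutes divided by total reads assigned to
#' Bacteroidetes, per sample. A zero Bacteroidetes total makes the ratio
#' undefined (NA with `defined = FALSE`) rather than infinite, so
#' downstream rank tests stay well-defined; such samples are excluded
#' there and logged.
#'
#' @param table an `abundance_table` whose taxonomy includes both phyla.
#' @return data.frame: sample_id, firmicutes, bacteroidetes, ratio,
#'   defined.
#' @export
fb_ratio <- function(table) {
  ph <- aggregate_level(table, "phylum")
  for (p in c("Firmicutes", "Bacteroidetes")) {
    if (!p %in% colnames(ph)) {
      stop_invalid("phylum '%s' absent from the taxonomy map", p)
    }
  }
  f <- ph[, "Firmicutes"]; b <- ph[, "Bacteroidetes"]
  defined <- b > 0
  if (any(!defined)) {
    message(sprintf("F:B undefined (zero Bacteroidetes) for %d sample(s): %s",
                    sum(!defined), paste(rownames(ph)[!defined], collapse = ", ")))
  }
  data.frame(sample_id = rownames(ph), firmicutes = f, bacteroidetes = b,
             ratio = ifelse(defined, f / b, NA_real_), defined = defined,
             row.names = NULL)
}

#' Phylum proportion tests across sample groups
#'
#' For each phylum, the per-group "number of successes" is the average
#' within-sample proportion of reads assigned to that phylum multiplied by
#' the group size (rounded to the nearest integer; the published
#' construction yields non-integers without saying how they were handled),
#' failures are group size minus successes, and groups are compared by
#' Pearson's chi-squared test (`prop.test`, hence Yates continuity
#' correction for two groups, none for three or more). P-values are
#' Bonferroni-multiplied by `m_tests` and capped at 1.
#'
#' @param tables named list of `abundance_table`, one per group (>= 2).
#' @param phyla phyla to test; default: all phyla present in every group.
#' @param m_tests Bonferroni multiplier (number of tests in the family);
#'   default: number of comparisons performed here.
#' @return data.frame: phylum, successes/size per group, p_raw,
#'   p_bonferroni.
#' @export
phylum_proportion_tests <- function(tables, phyla = NULL, m_tests = NULL) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  props <- lapply(tables, function(tb) {
    ph <- aggregate_level(tb, "phylum")
    if (nrow(ph) == 0L) stop_invalid("group with 0 samples")
    sweep(ph, 1, rowSums(ph), "/")
  })
  if (is.null(phyla)) phyla <- Reduce(intersect, lapply(props, colnames))
  if (!length(phyla)) stop_invalid("no phylum shared by all groups")
  if (is.null(m_tests)) m_tests <- length(phyla)
  rows <- lapply(phyla, function(p) {
    succ <- vapply(props, function(pr) round(mean(pr[, p]) * nrow(pr)), 1)
    n <- vapply(props, nrow, 1L)
    pv <- suppressWarnings(prop.test(succ, n)$p.value)
    data.frame(phylum = p, t(setNames(succ, paste0("successes_", names(tables)))),
               t(setNames(n, paste0("n_", names(tables)))),
               p_raw = pv, p_bonferroni = min(1, pv * m_tests))
  })
  do.call(rbind, rows)
}

#' One-tailed Mann-Whitney U test
#'
#' Two-group rank comparison with an explicit alternative — the cohort
#' hypotheses were directional (rapid weight gain: *lower* diversity,
#' *higher* F:B ratio), so no two-sided default is offered. Uses the exact
#' U distribution when both groups are small and tie-free, otherwise the
#' normal approximation with tie correction (no continuity correction, so
#' identical samples give exactly p = 1/2).
#'
#' @param values_a,values_b numeric samples (>= 2 values each; NAs
#'   dropped).
#' @param direction alternative for group a relative to b: `"less"` or
#'   `"greater"`.
#' @return the one-tailed p-value.
#' @export
mw_one_tailed <- function(values_a, values_b, direction) {
  if (missing(direction)) stop_invalid("direction ('less' or 'greater') is required")
  direction <- match.arg(direction, c("less", "greater"))
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) stop_invalid("each group needs >= 2 values")
  suppressWarnings(wilcox.test(a, b, alternative = direction,
                               correct = FALSE))$p.value
}

#' Kruskal-Wallis test across factor levels
#'
#' Rank test for a diversity/F:B summary across a categorical co-factor
#' with three or more levels (chi-squared approximation).
#'
#' @param values numeric response.
#' @param groups factor of the same length.
#' @return p-value.
#' @export
kruskal_factor_test <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  kruskal.test(values[ok], factor(groups[ok]))$p.value
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_i - b_i| / sum (a_i + b_i)` between every pair of
#' samples (rarefy to a common depth first). Pairs where both samples are
#' empty are undefined and flagged NA.
#'
#' @param table an `abundance_table`.
#' @return symmetric matrix with zero diagonal, entries in [0, 1].
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$counts
  zero <- rowSums(m) == 0
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  if (any(zero)) {
    d[zero, zero] <- NA_real_
    message(sprintf("Bray-Curtis undefined for all-zero sample pair(s): %s",
                    paste(rownames(m)[zero], collapse = ", ")))
  }
  diag(d) <- 0
  d
}

#' Write the per-sample diversity CSV
#'
#' Columns: sample_id, inverse_simpson, shannon, simpson, fb_ratio.
#'
#' @param table an `abundance_table`.
#' @param path output CSV.
#' @param level aggregation level for diversity.
#' @return the merged data.frame, invisibly.
#' @export
write_diversity <- function(table, path, level = "phylum") {
  div <- alpha_diversity(table, level)
  fb <- fb_ratio(table)
  out <- merge(div, fb[, c("sample_id", "ratio")], by = "sample_id", sort = FALSE)
  names(out)[names(out) == "ratio"] <- "fb_ratio"
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
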