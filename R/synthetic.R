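#' Configuration for the synthetic mother-child cohort
#'
#' States the simulated world: cohort size, visit schedule (birth, 3-4
#' weeks, 16, 28 and 40 weeks, one year, two years), per-visit missingness,
#' the number of genus-level taxa, measurement noise on the weight-for-length
#' growth index, and which predictors truly drive growth.
#'
#' @param n_children cohort size (>= 10).
#' @param n_genera number of genus leaves in the taxonomic tree.
#' @param visit_ages visit schedule in days; strictly increasing, first 0.
#' @param missing_rate probability each non-birth visit is missed.
#' @param effect_map list of effects, each `list(predictor=, shape=,
#'   amplitude=)` with shape one of `"sin"`, `"linear"`, `"const"`;
#'   amplitude is in growth-index units (kg/cm) per SD of the predictor.
#' @param noise_sd i.i.d. visit-level noise on the growth index (kg/cm).
#' @param seed master integer seed, fanned out to per-component substreams.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_children = 200L,
                             n_genera = 75L,
                             visit_ages = c(0, 25, 112, 196, 280, 365, 730),
                             missing_rate = 0.15,
                             effect_map = list(),
                             noise_sd = 0.003,
                             seed = 1L) {
  if (n_children < 10L) stop_invalid("n_children must be >= 10")
  if (visit_ages[1] != 0 || any(diff(visit_ages) <= 0)) {
    stop_invalid("visit_ages must be strictly increasing with first age 0")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop_invalid("missing_rate must be in [0, 1)")
  structure(list(n_children = as.integer(n_children),
                 n_genera = as.integer(n_genera),
                 visit_ages = visit_ages, missing_rate = missing_rate,
                 effect_map = effect_map, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.phylum_pool <- c("Firmicutes", "Bacteroidetes", "Proteobacteria", "Actinobacteria")
.phylum_weights <- c(0.45, 0.25, 0.20, 0.10)

#' Simulate a rooted taxonomic tree with recoverable phyla
#'
#' Builds a rooted bifurcating tree over `n_genera` uniquely named genus
#' leaves, partitioned among up to four phyla (always including Firmicutes
#' and Bacteroidetes). Each phylum subtree root carries a `p__<Phylum>`
#' node label so [genus_phyla()] can recover the phylum of every leaf.
#'
#' @param n_genera number of leaves (>= 4).
#' @param seed integer seed; identical inputs give an identical newick.
#' @return a `phylo` tree.
#' @export
sim_tax_tree <- function(n_genera, seed = 1L) {
  if (n_genera < 4L) stop_invalid("n_genera must be >= 4")
  n_phyla <- max(2L, min(4L, n_genera %/% 2L))
  phyla <- .phylum_pool[seq_len(n_phyla)]
  w <- .phylum_weights[seq_len(n_phyla)]
  alloc <- pmax(2L, floor(n_genera * w / sum(w)))
  while (sum(alloc) > n_genera) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_genera) alloc[which.max(w)] <- alloc[which.max(w)] + 1L

  with_seed(substream_seed(seed, "tree"), {
    counter <- 0L
    subtree_newick <- function(leaves) {
      if (length(leaves) == 1L) return(leaves)
      k <- if (length(leaves) == 2L) 1L else sample.int(length(leaves) - 1L, 1L)
      left <- leaves[seq_len(k)]
      right <- leaves[-seq_len(k)]
      counter <<- counter + 1L
      sprintf("(%s:%.4f,%s:%.4f)n%d", subtree_newick(left), runif(1, 0.2, 1),
              subtree_newick(right), runif(1, 0.2, 1), counter)
    }
    sub <- character(n_phyla)
    start <- 0L
    for (p in seq_len(n_phyla)) {
      leaves <- sprintf("genus_%03d", start + seq_len(alloc[p]))
      start <- start + alloc[p]
      nwk <- subtree_newick(sample(leaves))
      # phylum root label replaces the generated internal label (or names a
      # single-leaf clade wrapper)
      if (alloc[p] == 1L) {
        nwk <- sprintf("(%s:0.5)p__%s", nwk, phyla[p])
      } else {
        nwk <- sub("n[0-9]+$", sprintf("p__%s", phyla[p]), nwk)
      }
      sub[p] <- nwk
    }
    backbone <- sub[1]
    for (p in seq(2L, n_phyla)) {
      backbone <- sprintf("(%s:%.4f,%s:%.4f)b%d", backbone, runif(1, 0.5, 1.5),
                          sub[p], runif(1, 0.5, 1.5), p - 1L)
    }
    tree <- ape::read.tree(text = paste0(backbone, ";"))
    tree
  })
}

#' Simulate genus count tables with planted sparsity and correlation
#'
#' Multinomial reads per sample over log-normal-perturbed base proportions.
#' A fraction `sparsity_frac` of genera are made rare (expected count about
#' one read, hence under 5 counts in over 90% of samples); designated
#' sibling pairs share a latent log-normal factor so their counts are
#' strongly correlated (Pearson r > 0.8 in expectation) even after the
#' multinomial layer.
#'
#' @param tree taxonomic tree from [sim_tax_tree()].
#' @param n_samples number of samples.
#' @param depth per-sample read depth (>= 1000).
#' @param sparsity_frac fraction of genera made rare, in [0, 1).
#' @param corr_blocks list of length-2 character vectors naming sibling
#'   leaf pairs to correlate.
#' @param seed integer seed.
#' @return an `abundance_table` with the tree attached.
#' @export
sim_abundances <- function(tree, n_samples, depth = 10000, sparsity_frac = 0,
                           corr_blocks = list(), seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (depth < 1000) stop_invalid("depth must be >= 1000")
  if (sparsity_frac < 0 || sparsity_frac >= 1) stop_invalid("sparsity_frac must be in [0, 1)")
  genera <- tree$tip.label
  G <- length(genera)

  # validate that each correlated pair is a sibling pair on the tree
  if (length(corr_blocks)) {
    parent <- rep(NA_integer_, G + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    for (blk in corr_blocks) {
      idx <- match(blk, genera)
      if (anyNA(idx)) stop_invalid("corr_blocks names unknown leaves: %s",
                                   paste(blk[is.na(idx)], collapse = ", "))
      if (length(blk) != 2L || parent[idx[1]] != parent[idx[2]]) {
        stop_invalid("corr_blocks pair (%s) are not sibling leaves",
                     paste(blk, collapse = ", "))
      }
    }
  }

  with_seed(substream_seed(seed, "abund"), {
    corr_members <- unlist(corr_blocks)
    n_rare <- round(sparsity_frac * G)
    eligible <- setdiff(genera, corr_members)
    if (n_rare > length(eligible)) {
      stop_invalid("sparsity_frac too high given correlated pairs")
    }
    rare <- sample(eligible, n_rare)
    base <- rlnorm(G, meanlog = 0, sdlog = 1.2)
    names(base) <- genera
    base <- base / sum(base)
    # lift correlated members well above rarity so correlation is measurable
    base[corr_members] <- pmax(base[corr_members], 4 / G)
    nonrare <- setdiff(genera, rare)
    base[nonrare] <- pmax(base[nonrare], 100 / depth)
    base <- base / sum(base)
    # rare genera: expected count ~ 0.3-1.2 reads, so < 5 in nearly all samples
    base[rare] <- runif(n_rare, 0.3, 1.2) / depth
    base[nonrare] <- base[nonrare] * (1 - sum(base[rare])) / sum(base[nonrare])

    sigma <- 1.0
    z <- matrix(rnorm(n_samples * G, sd = sigma), n_samples, G,
                dimnames = list(NULL, genera))
    rho_lat <- 0.96
    for (blk in corr_blocks) {
      f <- rnorm(n_samples, sd = sigma)
      for (g in blk) z[, g] <- sqrt(rho_lat) * f + sqrt(1 - rho_lat) * z[, g]
    }
    counts <- matrix(0, n_samples, G, dimnames = list(sprintf("S%03d", seq_len(n_samples)), genera))
    for (s in seq_len(n_samples)) {
      wts <- base * exp(z[s, ])
      counts[s, ] <- rmultinom(1, size = depth, prob = wts / sum(wts))
    }
    abundance_table(counts, genus_phyla(tree), tree)
  })
}

#' Synthetic LMS growth reference
#'
#' A WHO-style stand-in: per sex and daily age 0-730, LMS triplets for one
#' measure (weight in kg or recumbent length in cm) with a smooth strictly
#' increasing median M, S in (0, 0.3) and L in [-2, 2]. This is synthetic;
#' it emulates the shape of gender-specific growth standards but is not the
#' WHO table.
#'
#' @param ages ages (days) to tabulate; must cover [0, 730].
#' @param measure `"weight"` or `"length"`.
#' @return a data.frame of class `growth_reference` with columns
#'   sex, age_days, L, M, S (and a `measure` attribute).
#' @export
sim_reference <- function(ages = 0:730, measure = c("weight", "length")) {
  measure <- match.arg(measure)
  if (min(ages) > 0 || max(ages) < 730) stop_invalid("ages must cover [0, 730] days")
  ref_m <- function(a, sex) {
    if (measure == "weight") {
      base <- 3.3 + 6.2 * (1 - exp(-a / 150)) + 0.0035 * a
      if (sex == "male") base * 1.04 else base
    } else {
      base <- 49.9 + 28 * (1 - exp(-a / 220)) + 0.011 * a
      if (sex == "male") base + 0.8 else base
    }
  }
  L <- if (measure == "weight") 0.35 else 1
  S <- if (measure == "weight") 0.12 else 0.035
  out <- do.call(rbind, lapply(c("male", "female"), function(sx) {
    data.frame(sex = sx, age_days = ages, L = L, M = ref_m(ages, sx), S = S)
  }))
  attr(out, "measure") <- measure
  class(out) <- c("growth_reference", "data.frame")
  out
}

.effect_shape <- function(shape, grid, domain = c(0, 730)) {
  u <- (grid - domain[1]) / diff(domain)
  switch(shape,
         sin = sin(pi * u),
         linear = u,
         const = rep(1, length(grid)),
         stop_invalid("unknown effect shape '%s'", shape))
}

#' Simulate sparse growth records with known functional ground truth
#'
#' Each child's latent weight-for-length index curve is
#' `mu(t) + sum_k xi_ik phi_k(t) + sum_j x_ij beta_j(t)`: a smooth
#' increasing population mean, two orthonormal principal components with
#' decreasing variances, and optional predictor effects from
#' `config$effect_map`. The curve is observed at the scheduled visits
#' (birth never missing, others dropped with `missing_rate`) with i.i.d.
#' noise; lengths come from the reference median times child-level
#' log-normal variation, and weight is back-solved as index x length so the
#' weight/length signal is exactly the simulated curve.
#'
#' @param config a [synthetic_config()].
#' @param abundance_features data.frame/matrix of per-child scalar
#'   predictors (rows = children) referenced by `effect_map`; may be NULL
#'   when no effects are configured.
#' @param reference_length optional `growth_reference` for length
#'   (defaults to [sim_reference()] for length).
#' @return list with `records` (list of `anthro_record`), `anthro` (long
#'   data.frame), and `truth` (a `synthetic_truth`: grid, mean, phi,
#'   lambda, scores, per-child true curves, effect curves).
#' @export
sim_growth <- function(config, abundance_features = NULL,
                       reference_length = sim_reference(measure = "length")) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_children
  ages <- config$visit_ages
  grid <- seq(0, 730, length.out = 731L)
  Tlen <- 730

  ref_w <- sim_reference(measure = "weight")
  mu_fun <- function(a, sex = "female") {
    Mw <- approx(ref_w$age_days[ref_w$sex == sex], ref_w$M[ref_w$sex == sex], a)$y
    Ml <- approx(reference_length$age_days[reference_length$sex == sex],
                 reference_length$M[reference_length$sex == sex], a)$y
    Mw / Ml
  }

  phi1 <- function(a) sqrt(2 / Tlen) * sin(pi * a / Tlen)
  phi2 <- function(a) sqrt(2 / Tlen) * cos(pi * a / Tlen)
  lambda <- c(0.0133, 0.0033)

  effects <- config$effect_map
  if (length(effects)) {
    if (is.null(abundance_features)) stop_invalid("effect_map given but no predictors")
    abundance_features <- as.data.frame(abundance_features)
    if (nrow(abundance_features) != n) {
      stop_invalid("abundance_features must have %d rows", n)
    }
    for (ef in effects) {
      if (!ef$predictor %in% colnames(abundance_features)) {
        stop_invalid("effect_map names unknown predictor '%s'", ef$predictor)
      }
    }
  }

  with_seed(substream_seed(config$seed, "growth"), {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    xi <- cbind(rnorm(n, sd = sqrt(lambda[1])), rnorm(n, sd = sqrt(lambda[2])))
    len_dev <- rnorm(n, sd = 0.025)   # child-level log length deviation

    eff_on_grid <- matrix(0, n, length(grid))
    effect_curves <- list()
    if (length(effects)) {
      for (ef in effects) {
        x <- abundance_features[[ef$predictor]]
        xs <- if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
        bcurve <- ef$amplitude * .effect_shape(ef$shape, grid)
        effect_curves[[ef$predictor]] <- bcurve
        eff_on_grid <- eff_on_grid + outer(xs, bcurve)
      }
    }

    mu_grid_by_sex <- list(male = mu_fun(grid, "male"), female = mu_fun(grid, "female"))
    true_curves <- matrix(NA_real_, n, length(grid))
    records <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      true_curves[i, ] <- mu_grid_by_sex[[sex[i]]] +
        xi[i, 1] * phi1(grid) + xi[i, 2] * phi2(grid) + eff_on_grid[i, ]
      keep <- c(TRUE, runif(length(ages) - 1L) >= config$missing_rate)
      a_obs <- ages[keep]
      idx <- match(a_obs, grid)
      y <- true_curves[i, idx] + rnorm(length(a_obs), sd = config$noise_sd)
      refL <- reference_length[reference_length$sex == sex[i], ]
      # child-level size deviation plus visit-level measurement jitter
      # (~0.3%, about 0.2 cm) so the two LAZ occasions are not collinear
      len <- approx(refL$age_days, refL$M, a_obs)$y * exp(len_dev[i]) *
        exp(rnorm(length(a_obs), sd = 0.003))
      wt <- y * len
      # guard: indexes are positive at realistic noise levels
      wt <- pmax(wt, 0.1)
      records[[i]] <- anthro_record(sprintf("C%03d", i), sex[i],
                                    data.frame(age_days = a_obs, weight_kg = wt,
                                               length_cm = len))
      rows[[i]] <- data.frame(child_id = sprintf("C%03d", i), sex = sex[i],
                              age_days = a_obs, weight_kg = wt, length_cm = len)
    }
    mean_grid <- colMeans(rbind(mu_grid_by_sex$male, mu_grid_by_sex$female))
    truth <- structure(
      list(grid = grid, mean = mean_grid,
           mean_by_sex = mu_grid_by_sex,
           phi = cbind(phi1(grid), phi2(grid)), lambda = lambda,
           scores = xi, true_curves = true_curves, sex = sex,
           effect_curves = effect_curves,
           nonzero = vapply(effects, function(e) e$predictor, character(1))),
      class = "synthetic_truth")
    list(records = records, anthro = do.call(rbind, rows), truth = truth)
  })
}

#' Simulate the 17-covariate confounder table
#'
#' Nine non-diet factors (sex, antibiotic and acid-reducer exposure,
#' delivery mode, intervention arm, gestational diabetes, gestational
#' weight gain, maternal smoking, family income) and ten weekly diet
#' frequencies (0-42 times/week). Two diet columns are built collinear so
#' that correlation pruning at 0.7 has work to do: `milk` tracks `dairy`
#' and `vegetables_no_potato` tracks `vegetables` with r > 0.7.
#'
#' @param n_children cohort size (>= 10).
#' @param seed integer seed.
#' @param sex optional character vector of sexes to keep the table
#'   consistent with the anthropometry.
#' @return data.frame with `child_id`, 9 factors and 10 diet counts; diet
#'   column names in attribute `diet_cols`.
#' @export
sim_covariates <- function(n_children, seed = 1L, sex = NULL) {
  if (n_children < 10L) stop_invalid("n_children must be >= 10")
  with_seed(substream_seed(seed, "covar"), {
    n <- n_children
    rbern <- function(p) sample(c("yes", "no"), n, TRUE, c(p, 1 - p))
    if (is.null(sex)) sex <- sample(c("male", "female"), n, TRUE)
    dairy <- pmin(rpois_int(n, 8), 42L)
    milk <- pmin(pmax(round(0.9 * dairy + rnorm(n, sd = 1.2)), 0L), 42L)
    veg <- pmin(rpois_int(n, 10), 42L)
    veg_np <- pmin(pmax(veg - rpois_int(n, 2), 0L), 42L)
    out <- data.frame(
      child_id = sprintf("C%03d", seq_len(n)),
      sex = sex,
      antibiotics = rbern(0.3),
      acid_reducers = rbern(0.1),
      delivery_mode = sample(c("vaginal", "cesarean"), n, TRUE, c(0.7, 0.3)),
      intervention = sample(c("control", "responsive"), n, TRUE),
      gestational_diabetes = rbern(0.08),
      gestational_weight_gain = sample(c("low", "normal", "high"), n, TRUE,
                                       c(0.2, 0.5, 0.3)),
      smoking = rbern(0.12),
      income = sample(c("low", "middle", "high"), n, TRUE, c(0.25, 0.5, 0.25)),
      ssb = pmin(rpois_int(n, 4), 42L),
      milk = milk,
      dairy = dairy,
      fruit = pmin(rpois_int(n, 9), 42L),
      vegetables = veg,
      vegetables_no_potato = veg_np,
      snacks = pmin(rpois_int(n, 6), 42L),
      sweets = pmin(rpois_int(n, 5), 42L),
      meats = pmin(rpois_int(n, 7), 42L),
      fried_foods = pmin(rpois_int(n, 2), 42L),
      stringsAsFactors = FALSE)
    attr(out, "diet_cols") <- c("ssb", "milk", "dairy", "fruit", "vegetables",
                                "vegetables_no_potato", "snacks", "sweets",
                                "meats", "fried_foods")
    out
  })
}

rpois_int <- function(n, lambda) as.integer(stats::rpois(n, lambda))

#' Generate the full synthetic cohort
#'
#' One call wiring together tree, abundances, per-child microbiota summary
#' features, growth records and covariates, with the master seed fanned out
#' to independent substreams. Optionally writes every artifact to disk in
#' the plain-text formats the readers understand.
#'
#' @param config a [synthetic_config()].
#' @param depth per-sample read depth for the count table.
#' @param sparsity_frac fraction of rare genera.
#' @param corr_blocks sibling pairs to correlate (default: one pair chosen
#'   from the tree).
#' @param dir optional output directory; when given, writes counts TSV,
#'   newick tree, anthropometry CSV, covariates CSV and the two reference
#'   CSVs.
#' @return list: `tree`, `counts` (`abundance_table`), `records`, `anthro`,
#'   `truth`, `covariates`, `reference_weight`, `reference_length`,
#'   `features` (per-child diversity/F:B summary used as predictors).
#' @export
sim_cohort <- function(config = synthetic_config(), depth = 10000,
                       sparsity_frac = 0.4, corr_blocks = NULL, dir = NULL) {
  tree <- sim_tax_tree(config$n_genera, config$seed)
  if (is.null(corr_blocks)) corr_blocks <- list(sibling_pair(tree))
  counts <- sim_abundances(tree, config$n_children, depth, sparsity_frac,
                           corr_blocks, config$seed)
  rownames(counts$counts) <- sprintf("C%03d", seq_len(config$n_children))
  div <- alpha_diversity(counts, level = "phylum")
  fb <- fb_ratio(counts)
  features <- data.frame(child_id = rownames(counts$counts),
                         inverse_simpson = div$inverse_simpson,
                         fb_ratio = fb$ratio)
  growth <- sim_growth(config, features)
  covars <- sim_covariates(config$n_children, config$seed,
                           sex = growth$truth$sex)
  ref_w <- sim_reference(measure = "weight")
  ref_l <- sim_reference(measure = "length")
  out <- list(tree = tree, counts = counts, records = growth$records,
              anthro = growth$anthro, truth = growth$truth,
              covariates = covars, reference_weight = ref_w,
              reference_length = ref_l, features = features)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(counts, file.path(dir, "counts.tsv"))
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    write.csv(growth$anthro, file.path(dir, "anthro.csv"), row.names = FALSE)
    write.csv(covars, file.path(dir, "covariates.csv"), row.names = FALSE)
    write_reference(ref_w, file.path(dir, "reference_weight.csv"))
    write_reference(ref_l, file.path(dir, "reference_length.csv"))
  }
  out
}

# First sibling leaf pair found in the tree (deterministic traversal order).
sibling_pair <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  for (p in sort(as.integer(names(kids)))) {
    tips <- kids[[as.character(p)]]
    tips <- tips[tips <= n_tip]
    if (length(tips) >= 2L) return(tree$tip.label[tips[1:2]])
  }
  stop_invalid("tree has no sibling leaf pair")
}
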