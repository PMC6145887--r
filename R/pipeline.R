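# End-to-end orchestration: synthetic-or-load -> CWG -> growth curves ->
# diversity -> taxon merge -> FoSR -> FLAME -> covariate models, each
# stage writing its artifact plus a manifest.

#' Pipeline configuration
#'
#' Either `paths` (counts TSV, newick tree, anthropometry CSV, covariates
#' CSV, weight/length reference CSVs) or a `synthetic` block (a
#' [synthetic_config()]), plus all stage parameters with their published
#' defaults: rarefaction depth 100,000 reads, rarity rule 5 counts in 90%
#' of samples, correlation threshold 0.7, FoSR smoothing parameter 10,000,
#' 102 spline basis functions, FPCA variance threshold 0.99.
#'
#' @param synthetic a [synthetic_config()], or NULL when loading data.
#' @param paths named list: counts, tree, anthro, covariates,
#'   reference_weight, reference_length.
#' @param depth rarefaction depth.
#' @param min_count,prevalence,r_threshold taxon-merge parameters.
#' @param lambda_s FoSR smoothing parameter.
#' @param n_basis spline basis size.
#' @param fve FPCA fraction-of-variance threshold.
#' @param cv_folds FLAME cross-validation folds.
#' @param register run curve registration (default FALSE: alignment had
#'   only minor effects on growth-index curves).
#' @param run_flame,run_covariates stage toggles.
#' @param seed global seed.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(), paths = NULL,
                            depth = 100000, min_count = 5, prevalence = 0.90,
                            r_threshold = 0.7, lambda_s = 10000,
                            n_basis = 102L, fve = 0.99, cv_folds = 10L,
                            register = FALSE, run_flame = TRUE,
                            run_covariates = TRUE, seed = 1L,
                            outdir = tempfile("growthmicro_run")) {
  if (is.null(synthetic) && is.null(paths)) {
    stop_invalid("either a synthetic block or input paths must be given")
  }
  stopifnot(depth > 0, min_count > 0, prevalence > 0, prevalence < 1,
            r_threshold > 0, r_threshold <= 1, lambda_s >= 0,
            n_basis >= 8, fve > 0, fve <= 1, cv_folds >= 2)
  structure(list(synthetic = synthetic, paths = paths, depth = depth,
                 min_count = min_count, prevalence = prevalence,
                 r_threshold = r_threshold, lambda_s = lambda_s,
                 n_basis = as.integer(n_basis), fve = fve,
                 cv_folds = as.integer(cv_folds), register = register,
                 run_flame = run_flame, run_covariates = run_covariates,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file whose top-level fields mirror the
#'   [pipeline_config()] arguments (the `synthetic` block holds
#'   [synthetic_config()] arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  syn <- if (!is.null(cfg$synthetic)) do.call(synthetic_config, cfg$synthetic)
  args <- cfg[setdiff(names(cfg), "synthetic")]
  args$synthetic <- syn
  do.call(pipeline_config, args)
}

log_stage <- function(stage, msg, t0) {
  message(sprintf("[%s] %s (%.1fs elapsed)", stage, msg,
                  as.numeric(Sys.time()) - t0))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes: data generation or loading, CWG scoring and rapid/non-rapid
#' classification, rarefaction and diversity/F:B summaries, FPCA curve
#' reconstruction (optionally registration), marginal function-on-scalar
#' regressions of growth curves on diversity and F:B with the three
#' significance measures, two-stage taxon merging, FLAME selection over
#' the merged groups, and the co-factor analyses (pruning, best subset,
#' joint functional regression). Every stage writes its artifact under
#' `config$outdir` plus a `manifest.json` echoing parameters and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- as.numeric(Sys.time())
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  stage <- "init"
  res <- list()
  tryCatch({
    # ---- data ----
    stage <- "data"
    if (!is.null(config$synthetic)) {
      # sequencing depth at twice the rarefaction target, so rarefaction
      # has real subsampling to do (cohort samples averaged ~2.4x the
      # 100,000-read target)
      cohort <- sim_cohort(config$synthetic, depth = 2 * config$depth,
                           dir = file.path(outdir, "data"))
      counts <- cohort$counts; records <- cohort$records
      covars <- cohort$covariates
      ref_w <- cohort$reference_weight; ref_l <- cohort$reference_length
      res$truth <- cohort$truth
      log_stage(stage, sprintf("synthetic cohort: %d children, %d genera",
                               config$synthetic$n_children,
                               config$synthetic$n_genera), t0)
    } else {
      p <- config$paths
      tree <- ape::read.tree(p$tree)
      counts <- read_counts(p$counts, tree = tree)
      records <- read_anthro(p$anthro)
      covars <- read.csv(p$covariates, stringsAsFactors = FALSE)
      ref_w <- read_reference(p$reference_weight)
      ref_l <- read_reference(p$reference_length)
      log_stage(stage, sprintf("loaded %d samples, %d children",
                               nrow(counts$counts), length(records)), t0)
    }
    res$counts <- counts

    # ---- anthropometrics / CWG ----
    stage <- "anthropometrics"
    cwg <- cwg_from_records(records, ref_w, ref_l)
    write.csv(as.data.frame(cwg), file.path(outdir, "cwg.csv"), row.names = FALSE)
    res$cwg <- cwg
    log_stage(stage, sprintf("CWG: %d rapid / %d non-rapid", sum(cwg$rapid),
                             sum(!cwg$rapid)), t0)

    # ---- diversity ----
    stage <- "diversity"
    depth_eff <- min(config$depth, min(rowSums(counts$counts)))
    rare <- rarefy_counts(counts, depth_eff, seed = config$seed)
    div <- write_diversity(rare, file.path(outdir, "diversity.csv"))
    res$diversity <- div
    # rapid vs non-rapid one-tailed comparisons (lower diversity, higher F:B)
    grp <- classify_rapid(cwg)
    in_rapid <- div$sample_id %in% grp$rapid
    res$group_tests <- data.frame(
      measure = c("inverse_simpson", "fb_ratio"),
      p = c(mw_one_tailed(div$inverse_simpson[in_rapid],
                          div$inverse_simpson[!in_rapid], "less"),
            mw_one_tailed(div$fb_ratio[in_rapid & !is.na(div$fb_ratio)],
                          div$fb_ratio[!in_rapid & !is.na(div$fb_ratio)],
                          "greater")))
    log_stage(stage, sprintf("rarefied to %g reads; %d samples", depth_eff,
                             nrow(rare$counts)), t0)

    # ---- growth curves ----
    stage <- "growth_curves"
    fpca <- fit_fpca(records, fve_threshold = config$fve)
    curves <- predict_curves(fpca, spline_basis(config$n_basis))
    if (config$register) curves <- register_curves(curves)
    write_curves(curves, file.path(outdir, "curves.csv"),
                 file.path(outdir, "basis.json"))
    res$fpca <- fpca; res$curves <- curves
    log_stage(stage, sprintf("FPCA: K = %d, sigma = %.4g", fpca$K,
                             sqrt(fpca$sigma2)), t0)

    # ---- FoSR on summary measures ----
    stage <- "fosr"
    ids <- rownames(curves$coefs)
    div_m <- div[match(ids, div$sample_id), ]
    fits <- list()
    for (feat in c("inverse_simpson", "fb_ratio")) {
      ok <- !is.na(div_m[[feat]])
      fit <- fit_fosr(curve_set(curves$coefs[ok, , drop = FALSE], curves$basis),
                      div_m[ok, feat, drop = FALSE],
                      lambda_s = config$lambda_s)
      write_fosr(fit, file.path(outdir, sprintf("fosr_%s.json", feat)))
      fits[[feat]] <- fit
    }
    res$fosr <- fits
    log_stage(stage, sprintf("Choi p: diversity %.3g, F:B %.3g",
                             test_coefficient(fits$inverse_simpson, 2, "Choi"),
                             test_coefficient(fits$fb_ratio, 2, "Choi")), t0)

    # ---- taxon merge ----
    stage <- "taxon_merge"
    merged <- merge_taxa(rare, min_count = config$min_count,
                         prevalence = config$prevalence,
                         r_threshold = config$r_threshold)
    write_merge_result(merged, file.path(outdir, "merge"))
    res$merge <- merged
    log_stage(stage, sprintf("%d genera -> %d taxonomic groups",
                             sum(lengths(merged$groups)),
                             length(merged$groups)), t0)

    # ---- FLAME ----
    if (config$run_flame) {
      stage <- "flame"
      keep <- rownames(merged$matrix)[rownames(merged$matrix) %in% ids]
      fl <- fit_flame(curve_set(curves$coefs[keep, , drop = FALSE], curves$basis),
                      merged$matrix[keep, , drop = FALSE],
                      n_folds = config$cv_folds, seed = config$seed)
      write_flame(fl, file.path(outdir, "flame.json"))
      res$flame <- fl
      log_stage(stage, sprintf("%d group(s) selected", length(fl$selected)), t0)
    }

    # ---- covariate models ----
    if (config$run_covariates) {
      stage <- "covariates"
      diet_cols <- attr(covars, "diet_cols") %||%
        intersect(c("ssb", "milk", "dairy", "fruit", "vegetables",
                    "vegetables_no_potato", "snacks", "sweets", "meats",
                    "fried_foods"), names(covars))
      retained <- prune_correlated(covars[, diet_cols, drop = FALSE])
      cv_m <- covars[match(div$sample_id, covars$child_id), ]
      mr <- multi_regression(div$inverse_simpson,
                             cv_m[, retained, drop = FALSE])
      all17 <- cv_m[, setdiff(names(covars), c("child_id",
                    setdiff(diet_cols, retained))), drop = FALSE]
      bs <- best_subset(div$inverse_simpson, all17)
      sel_diet <- intersect(bs$selected, retained)
      joint <- if (length(sel_diet)) {
        joint_fosr(curves,
                   data.frame(child_id = div$sample_id,
                              inverse_simpson = div$inverse_simpson)[
                                div$sample_id %in% ids, ],
                   data.frame(child_id = cv_m$child_id, cv_m[, sel_diet,
                              drop = FALSE])[cv_m$child_id %in% ids, ],
                   lambda_s = config$lambda_s)
      }
      res$covariates <- list(retained_diet = retained, regression = mr,
                             best_subset = bs, joint = joint)
      jsonlite::write_json(
        list(retained_diet = as.character(retained),
             dropped = attr(retained, "dropped"),
             best_subset = bs$selected,
             criterion = bs$criterion),
        file.path(outdir, "covariates.json"), auto_unbox = TRUE, digits = NA)
      log_stage(stage, sprintf("diet retained: %d/%d; best subset: {%s}",
                               length(retained), length(diet_cols),
                               paste(bs$selected, collapse = ",")), t0)
    }

    # ---- manifest ----
    manifest <- list(
      parameters = config[setdiff(names(config), c("synthetic", "paths"))],
      synthetic = if (!is.null(config$synthetic))
        unclass(config$synthetic)[c("n_children", "n_genera", "visit_ages",
                                    "missing_rate", "noise_sd", "seed")],
      seed = config$seed,
      package_version = as.character(utils::packageVersion("growthmicro")),
      stages_run = names(res))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(res)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
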