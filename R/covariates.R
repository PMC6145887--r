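# Co-factor analyses: correlation pruning of diet frequencies, scalar
# multiple regressions, exhaustive best-subset selection, and joint
# functional regressions combining microbiota summaries with diet.

#' Prune correlated diet variables
#'
#' Greedy scan in declared column order: a column is dropped when its
#' absolute Pearson correlation with an already-retained column exceeds
#' `cutoff` (0.7 in the cohort analyses, which eliminated 'milk' and
#' 'vegetables excluding potatoes'). Constant columns have undefined
#' correlation; they are retained and logged.
#'
#' @param diet_table data.frame/matrix of numeric columns.
#' @param cutoff correlation cutoff (default 0.7).
#' @return character vector of retained column names; attributes
#'   `dropped` (data.frame of dropped column, partner, r) and `constant`.
#' @export
prune_correlated <- function(diet_table, cutoff = 0.7) {
  m <- as.matrix(as.data.frame(diet_table))
  storage.mode(m) <- "double"
  cols <- colnames(m)
  retained <- character(0)
  dropped <- list()
  constant <- character(0)
  for (cl in cols) {
    if (sd(m[, cl]) == 0) {
      constant <- c(constant, cl)
      retained <- c(retained, cl)
      next
    }
    partner <- NA_character_; r_hit <- NA_real_
    for (rt in retained) {
      if (sd(m[, rt]) == 0) next
      r <- cor(m[, cl], m[, rt])
      if (is.finite(r) && abs(r) > cutoff) { partner <- rt; r_hit <- r; break }
    }
    if (is.na(partner)) {
      retained <- c(retained, cl)
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(
        column = cl, correlated_with = partner, r = r_hit)
    }
  }
  structure(retained,
            dropped = if (length(dropped)) do.call(rbind, dropped) else
              data.frame(column = character(0), correlated_with = character(0),
                         r = numeric(0)),
            constant = constant)
}

#' Multiple linear regression summary
#'
#' Ordinary least squares of a scalar microbiota summary on covariates,
#' reported the way cohort co-factor tables are: per-coefficient
#' estimates and t statistics (null: coefficient equals zero), the
#' overall-F p-value and the adjusted R-squared.
#'
#' @param response numeric vector.
#' @param predictors data.frame/matrix (categoricals entered via
#'   reference-level dummy coding, reference = first declared level).
#' @return object of class `multi_regression`: `coefficients`
#'   (estimate, se, t, p per term), `overall_p`, `r_squared`,
#'   `adj_r_squared`, and the underlying `lm` fit.
#' @export
multi_regression <- function(response, predictors) {
  df <- as.data.frame(predictors)
  df$.y <- response
  n <- nrow(df)
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    stop_invalid("singular design: aliased terms %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  p <- length(coef(fit)) - 1L
  if (n <= p + 1L) stop_invalid("need n > p + 1 (n = %d, p = %d)", n, p)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  overall_p <- if (is.null(fstat)) NA_real_ else
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  ct <- as.data.frame(sm$coefficients)
  names(ct) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = ct, overall_p = overall_p,
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 n = n, fit = fit),
            class = "multi_regression")
}

#' @export
print.multi_regression <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d: overall p = %.4g, adj. R^2 = %.4f\n",
              x$n, x$overall_p, x$adj_r_squared))
  print(signif(as.matrix(x$coefficients), 4))
  invisible(x)
}

# Fast exhaustive subset scan via precomputed cross-products.
# Returns RSS for each subset (list of index vectors).
subset_rss <- function(XtX, Xty, yty, subsets) {
  vapply(subsets, function(s) {
    s <- c(1L, s + 1L)                       # always include intercept (col 1)
    b <- tryCatch(solve(XtX[s, s, drop = FALSE], Xty[s]),
                  error = function(e) NULL)
    if (is.null(b)) return(Inf)
    yty - sum(b * Xty[s])
  }, numeric(1))
}

#' Exhaustive best-subset selection for a multiple linear regression
#'
#' Enumerates all `2^p` covariate subsets, fits each by OLS, and returns
#' the subset minimizing the information criterion (BIC by default); the
#' restricted model is then refit and reported as a co-factor table
#' (coefficients, t statistics, overall p, adjusted R-squared).
#'
#' @param response numeric vector.
#' @param covariates data.frame (numeric or factor columns; factors are
#'   dummy-coded and selected as a block).
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @return object of class `subset_selection`: `selected` (names),
#'   `criterion`, `best_value`, `n_subsets`, `refit`
#'   (a `multi_regression`, NULL for the intercept-only model), and the
#'   top of the criterion table.
#' @export
best_subset <- function(response, covariates, criterion = c("BIC", "AIC")) {
  criterion <- match.arg(criterion)
  cov_df <- as.data.frame(covariates)
  p_vars <- ncol(cov_df)
  if (p_vars > 20L) {
    stop_invalid("p = %d > 20: exhaustive enumeration infeasible; pre-screen covariates first",
                 p_vars)
  }
  y <- response
  n <- length(y)
  # model matrix blocks per declared covariate (factors expand to dummies)
  mm <- stats::model.matrix(~ ., data = cov_df)
  assign_map <- attr(mm, "assign")                   # 0 = intercept
  X <- mm
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)

  subsets <- lapply(0:(2^p_vars - 1L), function(code) {
    vars <- which(bitwAnd(code, bitwShiftL(1L, seq_len(p_vars) - 1L)) != 0L)
    which(assign_map %in% vars) - 1L                 # column idx minus intercept
  })
  rss <- subset_rss(XtX, Xty, yty, subsets)   # intercept always included
  k <- vapply(subsets, length, 1L) + 1L              # parameters incl. intercept
  ll_term <- n * log(pmax(rss, 1e-300) / n)
  crit <- ll_term + if (criterion == "BIC") log(n) * (k + 1) else 2 * (k + 1)
  best <- which.min(crit)
  sel_vars <- unique(assign_map[subsets[[best]] + 1L])
  selected <- colnames(cov_df)[sel_vars]
  refit <- if (length(selected)) {
    multi_regression(y, cov_df[, selected, drop = FALSE])
  } else NULL
  ord <- order(crit)
  structure(list(selected = selected, criterion = criterion,
                 best_value = crit[best], n_subsets = length(subsets),
                 refit = refit,
                 table = data.frame(
                   subset = vapply(subsets[head(ord, 10)], function(s)
                     paste(colnames(X)[s + 1L], collapse = "+"), ""),
                   value = crit[head(ord, 10)])),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  cat(sprintf("Best-subset selection (%s over %d subsets)\n",
              x$criterion, x$n_subsets))
  if (length(x$selected)) {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    print(x$refit)
  } else cat("  selected: intercept-only model\n")
  invisible(x)
}

#' Joint functional regression: microbiota summaries plus diet
#'
#' Refits the function-on-scalar regression of growth curves on a
#' microbiota summary with diet covariates added to the design, reporting
#' all three significance measures per coefficient — the comparison that
#' shows whether diet confounds, masks or suppresses the microbiota
#' effect.
#'
#' @param curves `curve_set` with child ids as rownames.
#' @param microbiota_summary data.frame: `child_id` plus summary
#'   column(s).
#' @param selected_diet data.frame: `child_id` plus diet columns (e.g.
#'   the [best_subset()] selection), or NULL for the marginal fit.
#' @param ... passed to [fit_fosr()] (e.g. `lambda_s`).
#' @return a `fosr` fit on the joined design.
#' @export
joint_fosr <- function(curves, microbiota_summary, selected_diet = NULL, ...) {
  stopifnot(inherits(curves, "curve_set"))
  ids <- rownames(curves$coefs)
  ms <- as.data.frame(microbiota_summary)
  stopifnot("child_id" %in% names(ms))
  design <- ms
  pred_ids <- ms$child_id
  if (!is.null(selected_diet)) {
    sd_df <- as.data.frame(selected_diet)
    stopifnot("child_id" %in% names(sd_df))
    design <- merge(design, sd_df, by = "child_id", sort = FALSE)
    pred_ids <- union(pred_ids, sd_df$child_id)
  }
  orphans_c <- setdiff(ids, design$child_id)
  orphans_d <- setdiff(pred_ids, ids)
  if (length(orphans_c) || length(orphans_d)) {
    stop_invalid("child id mismatch; curves without predictors: [%s]; predictors without curves: [%s]",
                 paste(orphans_c, collapse = ","), paste(orphans_d, collapse = ","))
  }
  design <- design[match(ids, design$child_id), ]
  fit_fosr(curves, design[, setdiff(names(design), "child_id"), drop = FALSE], ...)
}
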