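# Function-on-scalar regression: growth curves regressed on scalar
# predictors by penalized least squares (second-derivative penalty on the
# coefficient curves), with a sandwich covariance surface built from the
# empirical residual curves and three quadratic-form significance measures
# (L2, PCA, Choi).

#' Fit a penalized function-on-scalar regression
#'
#' Minimizes
#' `sum_i int (Y_i(t) - sum_j x_ij beta_j(t))^2 dt +
#'  lambda_s * sum_j int (beta_j''(t))^2 dt`
#' over coefficient curves expressed in the curves' shared cubic B-spline
#' basis; the solution is closed-form generalized ridge. The covariance
#' surface of each coefficient curve is the sandwich of the penalized hat
#' operator with the residual-curve covariance estimated from the pooled
#' empirical residual curves (no working-independence assumption along t).
#'
#' @param curves a `curve_set`, or a numeric matrix of curve values
#'   (children x grid) accompanied by `value_grid`.
#' @param X design data.frame/matrix of scalar predictors (one row per
#'   curve). An intercept column is added unless already present.
#' @param lambda_s roughness penalty weight; the cohort analyses fixed it
#'   at 10,000 (default).
#' @param scale_x center and scale non-constant predictors (default TRUE).
#' @param out_grid grid on which coefficient curves and covariance
#'   surfaces are returned (default 101 equispaced ages).
#' @param value_grid grid of `curves` when a value matrix is given.
#' @param penalize_intercept penalize the intercept like other
#'   coefficients (default TRUE; set FALSE for an unpenalized intercept).
#' @return an object of class `fosr`: `coef_curves` (p x grid),
#'   `V` (list of per-coefficient covariance surfaces), `grid`,
#'   `lambda_s`, `names`, `n`, plus basis-space internals.
#' @export
fit_fosr <- function(curves, X = NULL, lambda_s = 10000, scale_x = TRUE,
                     out_grid = NULL, value_grid = NULL,
                     penalize_intercept = TRUE) {
  if (is.matrix(curves) && !inherits(curves, "curve_set")) {
    if (is.null(value_grid)) stop_invalid("value_grid required for a value matrix")
    curves <- project_curves(curves, value_grid)
  }
  stopifnot(inherits(curves, "curve_set"))
  C <- curves$coefs
  n <- nrow(C)
  basis <- curves$basis
  L <- basis$n_basis
  if (is.null(out_grid)) {
    out_grid <- seq(basis$domain[1], basis$domain[2], length.out = 101L)
  }

  # design matrix
  if (is.null(X)) {
    Xm <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    Xm <- as.matrix(as.data.frame(X))
    storage.mode(Xm) <- "double"
    if (any(!is.finite(Xm))) stop_invalid("non-finite values in X")
    if (scale_x) {
      for (j in seq_len(ncol(Xm))) {
        s <- sd(Xm[, j])
        if (s > 0) Xm[, j] <- (Xm[, j] - mean(Xm[, j])) / s
      }
    }
    has_const <- any(apply(Xm, 2, function(v) sd(v) == 0 && v[1] != 0))
    if (!has_const) Xm <- cbind(`(Intercept)` = 1, Xm)
  }
  # identically-zero predictors carry no information: fit without them and
  # report exactly-zero coefficient curves with zero covariance
  zero_cols <- which(colSums(Xm != 0) == 0L)
  all_names <- colnames(Xm)
  if (length(zero_cols)) Xm <- Xm[, -zero_cols, drop = FALSE]
  p <- ncol(Xm)
  if (n < p + 2L) stop_invalid("need n >= p + 2 (n = %d, p = %d)", n, p)

  # basis Gram and roughness penalty via fine quadrature
  qgrid <- seq(basis$domain[1], basis$domain[2], length.out = max(6L * L, 400L))
  wq <- trapez_weights(qgrid)
  Theta_q <- eval_basis(basis, qgrid)
  J <- crossprod(Theta_q, Theta_q * wq)
  D2 <- splines::splineDesign(basis$knots, qgrid, ord = basis$degree + 1L,
                              derivs = rep(2L, length(qgrid)))
  P <- crossprod(D2, D2 * wq)

  S <- crossprod(Xm)
  cn <- tryCatch(kappa(S %x% J + lambda_s * diag(p) %x% P, exact = FALSE),
                 error = function(e) Inf)
  # solve X'X B J + lambda B P = X' C J row-block-wise via eigen of X'X
  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < max(es$values) * 1e-12 && lambda_s == 0) {
    stop_invalid("singular penalized system (condition number %.3g)", cn)
  }
  Rhs <- t(es$vectors) %*% crossprod(Xm, C %*% J)   # p x L
  Bt <- matrix(0, p, L)
  pen_scale <- rep(1, p)
  if (!penalize_intercept) {
    # identify the constant column and exempt it: solved jointly below via
    # the vec system instead of the eigen shortcut
    const_col <- which(apply(Xm, 2, function(v) sd(v) == 0))[1]
  }
  if (penalize_intercept || is.na(const_col <- const_col %||% NA)) {
    for (k in seq_len(p)) {
      Bt[k, ] <- solve(es$values[k] * J + lambda_s * P, Rhs[k, ])
    }
    B <- es$vectors %*% Bt
  } else {
    Pen <- diag(p); Pen[const_col, const_col] <- 0
    A_full <- J %x% S + lambda_s * (P %x% Pen)
    b <- solve(A_full, as.vector(crossprod(Xm, C %*% J)))
    B <- matrix(b, p, L)
  }
  rownames(B) <- colnames(Xm)

  # residual covariance in coefficient space
  E <- C - Xm %*% B
  Sigma_c <- crossprod(E) / max(n - p, 1L)

  # Cov(vec B) = A^-1 [ (J Sigma J) kron (X'X) ] A^-1  (vec = column-major of p x L B)
  A <- J %x% S + lambda_s * (P %x% diag(p))
  A_inv <- solve(A)
  Mid <- (J %*% Sigma_c %*% J) %x% S
  Cov_b <- A_inv %*% Mid %*% A_inv

  Theta_o <- eval_basis(basis, out_grid)
  coef_curves <- B %*% t(Theta_o)
  V <- vector("list", p)
  names(V) <- colnames(Xm)
  for (j in seq_len(p)) {
    idx <- seq(j, p * L, by = p)
    V[[j]] <- Theta_o %*% Cov_b[idx, idx] %*% t(Theta_o)
  }

  if (length(zero_cols)) {
    G <- length(out_grid)
    full_cc <- matrix(0, length(all_names), G,
                      dimnames = list(all_names, NULL))
    full_cc[rownames(coef_curves) %||% colnames(Xm), ] <- coef_curves
    full_V <- setNames(rep(list(matrix(0, G, G)), length(all_names)),
                       all_names)
    full_V[colnames(Xm)] <- V
    full_B <- matrix(0, length(all_names), L,
                     dimnames = list(all_names, NULL))
    full_B[colnames(Xm), ] <- B
    coef_curves <- full_cc; V <- full_V; B <- full_B
    Xfull <- matrix(0, n, length(all_names),
                    dimnames = list(NULL, all_names))
    Xfull[, colnames(Xm)] <- Xm
    Xm <- Xfull
  }

  structure(list(coef_curves = coef_curves, V = V, grid = out_grid,
                 lambda_s = lambda_s, names = colnames(Xm), n = n,
                 basis = basis, B = B, X = Xm, Sigma_c = Sigma_c,
                 condition = cn, curve_coefs = C),
            class = "fosr")
}

#' @export
print.fosr <- function(x, ...) {
  cat(sprintf("Function-on-scalar regression: n = %d curves, %d coefficient curve(s), lambda_s = %g\n",
              x$n, length(x$names), x$lambda_s))
  cat("  predictors:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.fosr <- function(object, ...) object$coef_curves

#' @export
fitted.fosr <- function(object, ...) {
  object$X %*% object$B %*% t(eval_basis(object$basis, object$grid))
}

#' @export
residuals.fosr <- function(object, ...) {
  object$curve_coefs %*% t(eval_basis(object$basis, object$grid)) -
    fitted(object)
}

#' Pointwise confidence band for a coefficient curve
#'
#' `beta_j(t) +/- z_{1-alpha/2} sqrt(V_j(t,t))` on the fit's grid.
#'
#' @param fit a `fosr` object.
#' @param j coefficient index or name.
#' @param level band level in (0,1), default 0.95.
#' @return data.frame: t, estimate, lower, upper.
#' @export
pointwise_band <- function(fit, j = 2L, level = 0.95) {
  stopifnot(inherits(fit, "fosr"), level > 0, level < 1)
  if (is.character(j)) j <- match(j, fit$names)
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(diag(fit$V[[j]]), 0))
  data.frame(t = fit$grid, estimate = fit$coef_curves[j, ],
             lower = fit$coef_curves[j, ] - z * se,
             upper = fit$coef_curves[j, ] + z * se)
}

#' @export
plot.fosr <- function(x, j = 2L, level = 0.95, ...) {
  b <- pointwise_band(x, j, level)
  nm <- if (is.character(j)) j else x$names[j]
  graphics::plot(b$t, b$estimate, type = "l", lwd = 2, ylim = range(b[, -1], 0),
                 xlab = "age (days)", ylab = sprintf("beta_%s(t)", nm), ...)
  graphics::lines(b$t, b$lower, lty = 2)
  graphics::lines(b$t, b$upper, lty = 2)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}

# Quadrature-weighted eigenstructure of a coefficient's covariance
# surface, plus the curve's scores in that eigenbasis.
fosr_eigs <- function(fit, j, tol = 1e-12) {
  w <- trapez_weights(fit$grid)
  sw <- sqrt(w)
  M <- (sw %o% sw) * fit$V[[j]]
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nu <- pmax(e$values, 0)
  keep <- nu > tol * max(nu, 0)
  if (!any(keep)) stop_invalid("degenerate covariance for coefficient %d", j)
  z <- drop(t(e$vectors[, keep, drop = FALSE]) %*% (sw * fit$coef_curves[j, ]))
  list(nu = nu[keep], z = z)
}

#' Significance of a coefficient curve (L2, PCA or Choi measure)
#'
#' Three weighted quadratic forms on the eigen-decomposition
#' `V_j = sum_m nu_m psi_m psi_m'` with scores `z_m = <beta_j, psi_m>`:
#' \describe{
#'   \item{L2}{`T = sum z_m^2` (the squared integral of the estimate); null
#'     law `sum nu_m chi^2_1`, evaluated by Monte-Carlo.}
#'   \item{PCA}{`T = sum_{m<=M} z_m^2 / nu_m ~ chi^2_M`, with M the
#'     components reaching 95% of `sum nu`.}
#'   \item{Choi}{`T = sum_{m<=M'} z_m^2 / sqrt(nu_m)`, null
#'     `sum sqrt(nu_m) chi^2_1` (Monte-Carlo), M' reaching 99.9% — a
#'     weighting in between PCA and L2, letting more components enter.}
#' }
#'
#' @param fit a `fosr` object.
#' @param j coefficient index or name (default 2, the first non-intercept).
#' @param method `"L2"`, `"PCA"` or `"Choi"`.
#' @param n_mc Monte-Carlo draws for the weighted-chi-squared null laws.
#' @param mc_seed fixed internal seed for reproducible p-values
#'   (overridable).
#' @return the p-value.
#' @export
test_coefficient <- function(fit, j = 2L, method = c("L2", "PCA", "Choi"),
                             n_mc = 1e5, mc_seed = 42L) {
  stopifnot(inherits(fit, "fosr"))
  method <- match.arg(method)
  if (is.character(j)) j <- match(j, fit$names)
  eg <- fosr_eigs(fit, j)
  nu <- eg$nu; z <- eg$z
  mc_tail <- function(weights, Tobs) {
    with_seed(substream_seed(mc_seed, paste0("fosr_mc", method)), {
      draws <- matrix(rchisq(n_mc * length(weights), df = 1), n_mc)
      Tnull <- drop(draws %*% weights)
      mean(Tnull >= Tobs)
    })
  }
  switch(method,
    L2 = {
      Tobs <- sum(z^2)
      if (Tobs == 0) return(1)
      mc_tail(nu, Tobs)
    },
    PCA = {
      M <- which(cumsum(nu) / sum(nu) >= 0.95)[1]
      Tobs <- sum(z[1:M]^2 / nu[1:M])
      pchisq(Tobs, df = M, lower.tail = FALSE)
    },
    Choi = {
      M <- which(cumsum(nu) / sum(nu) >= 0.999)[1]
      Tobs <- sum(z[1:M]^2 / sqrt(nu[1:M]))
      if (Tobs == 0) return(1)
      mc_tail(sqrt(nu[1:M]), Tobs)
    })
}

#' @export
summary.fosr <- function(object, methods = c("L2", "PCA", "Choi"), ...) {
  print(object)
  non_int <- which(object$names != "(Intercept)")
  if (length(non_int)) {
    tab <- sapply(methods, function(m) {
      vapply(non_int, function(j) test_coefficient(object, j, m), numeric(1))
    })
    tab <- matrix(tab, nrow = length(non_int),
                  dimnames = list(object$names[non_int], methods))
    cat("  p-values per significance measure:\n")
    print(signif(tab, 4))
    invisible(tab)
  } else invisible(NULL)
}

#' Write a fitted FoSR model to JSON
#'
#' Grid, coefficient curves, pointwise bands and the three p-values per
#' non-intercept coefficient.
#'
#' @param fit a `fosr`.
#' @param path output JSON path.
#' @param level band level.
#' @export
write_fosr <- function(fit, path, level = 0.95) {
  non_int <- which(fit$names != "(Intercept)")
  out <- list(
    grid = fit$grid, lambda_s = fit$lambda_s, n = fit$n,
    coefficients = lapply(seq_along(fit$names), function(j) {
      b <- pointwise_band(fit, j, level)
      list(name = fit$names[j], estimate = b$estimate,
           lower = b$lower, upper = b$upper)
    }),
    p_values = lapply(non_int, function(j) {
      list(name = fit$names[j],
           L2 = test_coefficient(fit, j, "L2"),
           PCA = test_coefficient(fit, j, "PCA"),
           Choi = test_coefficient(fit, j, "Choi"))
    }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
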