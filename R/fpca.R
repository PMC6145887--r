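# Sparse functional PCA for growth-index trajectories: pooled local-linear
# mean and covariance smoothing, eigen-analysis on a working grid, and
# conditional-expectation (BLUP) scores, in the PACE tradition.

# Local-linear smoother with Gaussian kernel. Returns fitted values at
# `xout`; when `diag_hat = TRUE` also the hat diagonal at the data points
# (for GCV).
llin_smooth <- function(x, y, xout, h, w = NULL, diag_hat = FALSE) {
  if (is.null(w)) w <- rep(1, length(x))
  fit_at <- function(x0) {
    k <- w * dnorm((x - x0) / h)
    xc <- x - x0
    s0 <- sum(k); s1 <- sum(k * xc); s2 <- sum(k * xc^2)
    den <- s0 * s2 - s1^2
    if (den <= .Machine$double.eps * s0^2 || s0 == 0) {
      # kernel degenerate at x0: fall back to local weighted mean
      return(sum(k * y) / max(s0, .Machine$double.xmin))
    }
    l <- k * (s2 - xc * s1) / den
    sum(l * y)
  }
  est <- vapply(xout, fit_at, numeric(1))
  if (!diag_hat) return(est)
  # hat weight of a SINGLE observation sitting at x_i (w holds replication
  # counts when data are binned)
  hat <- vapply(seq_along(x), function(i) {
    x0 <- x[i]
    k <- w * dnorm((x - x0) / h)
    xc <- x - x0
    s0 <- sum(k); s1 <- sum(k * xc); s2 <- sum(k * xc^2)
    den <- s0 * s2 - s1^2
    k1 <- dnorm(0)
    if (den <= .Machine$double.eps * s0^2) return(k1 / max(s0, .Machine$double.xmin))
    (k1 * (s2 - xc[i] * s1) / den)
  }, numeric(1))
  list(est = est, hat = hat)
}

# Aggregate scattered (x, y) onto distinct x values (or equi-spaced bins
# when there are many), returning bin centers, means and counts. Weighted
# local-linear smoothing of the binned data equals smoothing the raw data.
bin_xy <- function(x, y, max_distinct = 80L, nbins = 101L) {
  ux <- sort(unique(x))
  if (length(ux) <= max_distinct) {
    idx <- match(x, ux)
    n_b <- tabulate(idx, length(ux))
    ybar <- rowsum(y, idx)[, 1] / n_b
    return(list(x = ux, y = ybar, n = n_b,
                rss_within = sum(y^2) - sum(n_b * ybar^2)))
  }
  br <- seq(min(x), max(x), length.out = nbins + 1L)
  idx <- pmin(findInterval(x, br, rightmost.closed = TRUE), nbins)
  keep <- sort(unique(idx))
  n_b <- tabulate(idx, nbins)[keep]
  ybar <- rowsum(y, idx)[, 1] / n_b
  ctr <- (br[-1] + br[-length(br)]) / 2
  list(x = ctr[keep], y = ybar, n = n_b,
       rss_within = sum(y^2) - sum(n_b * ybar^2))
}

# Generalized cross-validation over a bandwidth grid, on binned data.
gcv_bandwidth <- function(x, y, h_grid) {
  b <- bin_xy(x, y)
  n <- length(x)
  scores <- vapply(h_grid, function(h) {
    f <- llin_smooth(b$x, b$y, b$x, h, w = b$n, diag_hat = TRUE)
    tr <- sum(b$n * f$hat)
    if (tr >= n - 1) return(Inf)
    rss <- b$rss_within + sum(b$n * (b$y - f$est)^2)
    n * rss / (n - tr)^2
  }, numeric(1))
  h_grid[which.min(scores)]
}

# Local-plane (2D local-linear) smoother of scattered surface values onto
# a square grid, product Gaussian kernel, exploiting symmetry of the input.
llin_smooth_2d <- function(x1, x2, v, gout, h, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x1))
  G <- length(gout)
  out <- matrix(NA_real_, G, G)
  for (a in seq_len(G)) {
    k1 <- w * dnorm((x1 - gout[a]) / h)
    d1 <- x1 - gout[a]
    for (b in a:G) {
      k <- k1 * dnorm((x2 - gout[b]) / h)
      d2 <- x2 - gout[b]
      s0 <- sum(k)
      if (s0 <= 0) { out[a, b] <- 0; next }
      X11 <- sum(k * d1 * d1); X22 <- sum(k * d2 * d2); X12 <- sum(k * d1 * d2)
      X01 <- sum(k * d1); X02 <- sum(k * d2)
      A <- matrix(c(s0, X01, X02,
                    X01, X11, X12,
                    X02, X12, X22), 3, 3)
      rhs <- c(sum(k * v), sum(k * d1 * v), sum(k * d2 * v))
      beta <- tryCatch(solve(A, rhs), error = function(e) c(rhs[1] / s0, 0, 0))
      out[a, b] <- beta[1]
    }
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  (out + t(out)) / 2
}

#' Fit sparse functional PCA to growth records
#'
#' Reconstructs the population structure of weight-for-length growth-index
#' curves from sparse clinic visits by pooling information across
#' children: the mean by local-linear smoothing of the pooled (age, index)
#' scatter, the covariance surface by local-linear smoothing of the
#' off-diagonal raw covariance products, measurement-error variance from
#' the smoothed diagonal minus the surface diagonal (floored at 0),
#' eigenfunctions/values by quadrature-weighted eigendecomposition, and
#' per-child scores by the conditional expectation (BLUP)
#' `xi_i = Lambda Phi_i' (Phi_i Lambda Phi_i' + sigma^2 I)^{-1} (y_i - mu_i)`.
#'
#' @param records list of `anthro_record`, or a data.frame with columns
#'   `child_id`, `age_days`, `index`.
#' @param fve_threshold fraction of variance explained that fixes the
#'   number of components K (default 0.99).
#' @param grid dense output grid (default 731 daily points on [0, 730]).
#' @param work_points size of the working grid for covariance smoothing.
#' @param h_mu,h_cov optional fixed bandwidths (days); by default the mean
#'   bandwidth is chosen by GCV (with floor `h_floor`) and the surface
#'   bandwidth is 1.5 times it.
#' @param h_floor bandwidth floor in days (default 30).
#' @return an object of class `fpca_model`: grid, `mu`, `phi`
#'   (grid x K, orthonormal under trapezoid quadrature), `lambda`,
#'   `sigma2`, `scores` (children x K), per-child inputs, and the
#'   smoothing metadata.
#' @export
fit_fpca <- function(records, fve_threshold = 0.99,
                     grid = seq(0, 730, length.out = 731L),
                     work_points = 41L, h_mu = NULL, h_cov = NULL,
                     h_floor = 30) {
  if (is.data.frame(records)) {
    df <- records
    stopifnot(all(c("child_id", "age_days", "index") %in% names(df)))
  } else {
    df <- do.call(rbind, lapply(records, function(r) {
      gi <- growth_index(r)
      data.frame(child_id = r$child_id, age_days = gi$age_days, index = gi$index)
    }))
  }
  ids <- unique(df$child_id)
  n <- length(ids)
  if (n < 20L) stop_invalid("need at least 20 children, have %d", n)
  obs <- split(df[, c("age_days", "index")], factor(df$child_id, levels = ids))
  if (!any(vapply(obs, nrow, 1L) >= 2L)) {
    stop_invalid("no child has 2+ observations; covariance cannot be formed")
  }
  rng <- range(grid)
  if (min(df$age_days) > rng[1] + diff(rng) * 0.05 ||
      max(df$age_days) < rng[2] - diff(rng) * 0.05) {
    stop_invalid("pooled observations do not cover the grid range")
  }

  # mean function (GCV bandwidth unless fixed). Visit designs cluster the
  # ages, so the bandwidth is floored at a third of the largest gap
  # between distinct observed ages — below that, local-linear fits
  # oscillate in the unobserved stretches.
  x <- df$age_days; y <- df$index
  gap_floor <- max(diff(sort(unique(x)))) / 3
  h_floor <- max(h_floor, gap_floor)
  if (is.null(h_mu)) {
    h_grid <- pmax(h_floor, diff(rng) * c(0.03, 0.05, 0.08, 0.12, 0.2, 0.3))
    h_mu <- gcv_bandwidth(x, y, unique(h_grid))
  }
  wgrid <- seq(rng[1], rng[2], length.out = work_points)
  bm <- bin_xy(x, y)
  mu_w <- llin_smooth(bm$x, bm$y, wgrid, h_mu, w = bm$n)
  mu_obs <- approx(wgrid, mu_w, x)$y

  # raw covariance products, off-diagonal only, binned onto distinct
  # age pairs (weighted smoothing of bin means equals raw smoothing)
  resid <- y - mu_obs
  rl <- split(data.frame(t = x, e = resid), factor(df$child_id, levels = ids))
  raw <- do.call(rbind, lapply(rl, function(d) {
    m <- nrow(d)
    if (m < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    data.frame(t1 = d$t[idx[, 1]], t2 = d$t[idx[, 2]],
               v = d$e[idx[, 1]] * d$e[idx[, 2]])
  }))
  if (is.null(h_cov)) h_cov <- 1.5 * h_mu
  snap_i <- function(v) pmax(1L, pmin(work_points,
    as.integer(round((v - rng[1]) / diff(rng) * (work_points - 1L)) + 1L)))
  i1 <- snap_i(raw$t1); i2 <- snap_i(raw$t2)
  key <- (i1 - 1L) * work_points + i2
  agg <- rowsum(cbind(raw$v, 1), key)
  cells <- as.integer(rownames(agg))
  t1b <- wgrid[(cells - 1L) %/% work_points + 1L]
  t2b <- wgrid[(cells - 1L) %% work_points + 1L]
  agg_n <- agg[, 2]
  vb <- agg[, 1] / agg_n
  C_w <- llin_smooth_2d(c(t1b, t2b), c(t2b, t1b), c(vb, vb),
                        wgrid, h_cov, w = c(agg_n, agg_n))

  # noise variance: smoothed squared residuals minus surface diagonal,
  # averaged over the central part of the domain, floored at 0
  bd <- bin_xy(x, resid^2)
  diag_sm <- llin_smooth(bd$x, bd$y, wgrid, h_cov, w = bd$n)
  central <- wgrid >= rng[1] + 0.25 * diff(rng) & wgrid <= rng[2] - 0.25 * diff(rng)
  sigma2 <- max(0, mean(diag_sm[central] - diag(C_w)[central]))

  # quadrature-weighted eigendecomposition on the working grid
  w_q <- trapez_weights(wgrid)
  sw <- sqrt(w_q)
  eig <- eigen((sw %o% sw) * C_w, symmetric = TRUE)
  lambda_all <- pmax(eig$values, 0)
  tot <- sum(lambda_all)
  if (tot <= 1e-14) {
    K <- 0L
  } else {
    K <- which(cumsum(lambda_all) / tot >= fve_threshold)[1]
  }
  if (is.na(K)) K <- length(lambda_all)
  phi_w <- if (K > 0) eig$vectors[, seq_len(K), drop = FALSE] / sw else
    matrix(0, length(wgrid), 0)
  lambda <- lambda_all[seq_len(K)]

  # interpolate to the dense grid and re-orthonormalize (Loewdin), so
  # quadrature orthonormality holds on the output grid too
  mu <- approx(wgrid, mu_w, grid)$y
  if (K > 0) {
    phi <- apply(phi_w, 2, function(p) stats::spline(wgrid, p, xout = grid)$y)
    phi <- matrix(phi, ncol = K)
    wq_d <- trapez_weights(grid)
    Gm <- t(phi) %*% (phi * wq_d)
    e <- eigen(Gm, symmetric = TRUE)
    Gm_inv_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-15)), K) %*% t(e$vectors)
    phi <- phi %*% Gm_inv_sqrt
    # sign convention: positive integral (or positive max deviation)
    for (k in seq_len(K)) {
      if (trapez_int(phi[, k], grid) < 0) phi[, k] <- -phi[, k]
    }
  } else phi <- matrix(0, length(grid), 0)

  # conditional-expectation scores
  scores <- matrix(0, n, max(K, 1L))[, seq_len(K), drop = FALSE]
  rownames(scores) <- ids
  if (K > 0) {
    Lam <- diag(lambda, K)
    for (i in seq_len(n)) {
      d <- obs[[i]]
      Phi_i <- matrix(apply(phi, 2, function(p) approx(grid, p, d$age_days)$y),
                      ncol = K)
      mu_i <- approx(grid, mu, d$age_days)$y
      M <- Phi_i %*% Lam %*% t(Phi_i) + diag(max(sigma2, 1e-12), nrow(d))
      scores[i, ] <- drop(Lam %*% t(Phi_i) %*% solve(M, d$index - mu_i))
    }
  }

  structure(list(grid = grid, mu = mu, phi = phi, lambda = lambda,
                 sigma2 = sigma2, scores = scores, K = K,
                 fve_threshold = fve_threshold, child_ids = ids, obs = obs,
                 bandwidths = c(mean = h_mu, covariance = h_cov),
                 fve = if (tot > 0) cumsum(lambda_all)[max(K, 1)] / tot else 1),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("Sparse FPCA: %d children, %d component(s), FVE %.1f%%\n",
              length(x$child_ids), x$K, 100 * x$fve))
  cat(sprintf("  noise sd %.4g (index units); bandwidths mean %.0f / surface %.0f days\n",
              sqrt(x$sigma2), x$bandwidths[1], x$bandwidths[2]))
  if (x$K > 0) cat("  eigenvalues:", signif(x$lambda, 3), "\n")
  invisible(x)
}

#' @export
summary.fpca_model <- function(object, ...) {
  print(object)
  if (object$K > 0) {
    pct <- 100 * object$lambda / sum(object$lambda)
    cat("  variance share per component:", sprintf("%.1f%%", pct), "\n")
  }
  invisible(object)
}

#' Reconstruct smooth per-child growth curves
#'
#' Best linear unbiased predictor curves
#' `mu + sum_k xi_ik phi_k`, projected onto the shared cubic B-spline
#' basis (102 functions by default) by least squares on the grid.
#'
#' @param model a fitted `fpca_model`.
#' @param basis target `spline_basis` (default 102 cubic B-splines).
#' @return a `curve_set` with one row per child.
#' @export
predict_curves <- function(model, basis = spline_basis()) {
  stopifnot(inherits(model, "fpca_model"))
  vals <- matrix(rep(model$mu, length(model$child_ids)),
                 nrow = length(model$child_ids), byrow = TRUE)
  if (model$K > 0) vals <- vals + model$scores %*% t(model$phi)
  rownames(vals) <- model$child_ids
  project_curves(vals, model$grid, basis)
}

#' @export
predict.fpca_model <- function(object, basis = spline_basis(), ...) {
  predict_curves(object, basis)
}

#' @export
plot.fpca_model <- function(x, n_curves = 20, ...) {
  graphics::plot(x$grid, x$mu, type = "l", lwd = 2, xlab = "age (days)",
                 ylab = "growth index (kg/cm)",
                 main = "FPCA mean and sample curves", ...)
  if (x$K > 0) {
    for (i in seq_len(min(n_curves, nrow(x$scores)))) {
      graphics::lines(x$grid, x$mu + drop(x$phi %*% x$scores[i, ]),
                      col = grDevices::adjustcolor("steelblue", 0.4))
    }
    graphics::lines(x$grid, x$mu, lwd = 2)
  }
  invisible(x)
}
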