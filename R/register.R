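# Continuous registration (temporal alignment) of growth curves to their
# cross-sectional mean, with strictly increasing endpoint-fixed warps.

# Monotone warp family: h(t) = a + (b-a) * int_a^t exp(s(u)) du /
# int_a^b exp(s(u)) du, with s a cubic spline in `coefs`. coefs = 0 gives
# the identity; any coefs give a strictly increasing warp fixing both ends.
make_warp <- function(coefs, domain = c(0, 730), n_quad = 201L) {
  u <- seq(domain[1], domain[2], length.out = n_quad)
  B <- splines::bs(u, df = length(coefs), degree = 3, intercept = TRUE,
                   Boundary.knots = domain)
  s <- drop(B %*% coefs)
  s <- pmin(pmax(s, -4), 4)          # keep warps numerically tame
  g <- exp(s)
  cg <- cumsum((c(0, diff(u))) * (g + c(g[1], head(g, -1))) / 2)  # trapezoid
  H <- domain[1] + diff(domain) * cg / cg[n_quad]
  H[1] <- domain[1]; H[n_quad] <- domain[2]
  function(t) approx(u, H, pmin(pmax(t, domain[1]), domain[2]))$y
}

#' Temporally align growth curves
#'
#' Continuous registration to the cross-sectional mean: each curve gets a
#' strictly increasing, endpoint-fixed warp `h_i` from a low-dimensional
#' monotone spline family (`exp`-spline parameterization, identity at zero
#' coefficients), chosen to minimize the squared distance between
#' `x_i(h_i(t))` and the current mean plus a small ridge penalty that
#' keeps warps near the identity. Mean and warps are iterated.
#'
#' @param curves a `curve_set` (growth indexes are monotone-dominant; the
#'   procedure assumes amplitude variation dominates).
#' @param max_iter outer (mean, warp) iterations, default 2.
#' @param warp_df dimension of the warp spline family (default 7: cubic
#'   with 5 interior-ish degrees of freedom).
#' @param ridge penalty weight on the warp coefficients (default 1e-4
#'   relative to curve scale).
#' @param n_eval evaluation grid size for the alignment criterion.
#' @return a `curve_set` of aligned curves with the warp functions in
#'   `$warps` (named by child).
#' @export
register_curves <- function(curves, max_iter = 2L, warp_df = 7L,
                            ridge = 1e-4, n_eval = 101L) {
  stopifnot(inherits(curves, "curve_set"))
  dom <- curves$basis$domain
  grid <- seq(dom[1], dom[2], length.out = n_eval)
  vals <- eval_curves(curves, grid)
  if (any(!is.finite(vals))) stop_invalid("non-finite curve values")
  n <- nrow(vals)
  scale2 <- mean(apply(vals, 1, var)) + 1e-12

  coefs <- matrix(0, n, warp_df)
  aligned <- vals
  for (iter in seq_len(max_iter)) {
    template <- colMeans(aligned)
    for (i in seq_len(n)) {
      ci <- curves$coefs[i, ]
      obj <- function(cf) {
        h <- make_warp(cf, dom)
        xi <- drop(eval_basis(curves$basis, h(grid)) %*% ci)
        mean((xi - template)^2) + ridge * scale2 * sum(cf^2)
      }
      opt <- optim(coefs[i, ], obj, method = "BFGS",
                   control = list(maxit = 40, reltol = 1e-8))
      coefs[i, ] <- opt$par
      h <- make_warp(coefs[i, ], dom)
      aligned[i, ] <- drop(eval_basis(curves$basis, h(grid)) %*% ci)
    }
  }
  warps <- lapply(seq_len(n), function(i) make_warp(coefs[i, ], dom))
  names(warps) <- rownames(curves$coefs)
  # final projection on a grid dense relative to the basis (the alignment
  # criterion grid can be coarser than the 102-function basis)
  dense <- seq(dom[1], dom[2],
               length.out = max(7L * curves$basis$n_basis, n_eval))
  aligned_d <- matrix(NA_real_, n, length(dense))
  for (i in seq_len(n)) {
    aligned_d[i, ] <- drop(eval_basis(curves$basis, warps[[i]](dense)) %*%
                             curves$coefs[i, ])
  }
  rownames(aligned_d) <- rownames(curves$coefs)
  out <- project_curves(aligned_d, dense, curves$basis)
  out$warps <- warps
  attr(out, "warp_coefs") <- coefs
  out
}
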