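#' Cubic B-spline basis specification
#'
#' Builds the shared cubic B-spline basis used to represent growth curves:
#' `n_basis` functions with evenly spaced knots on `domain` (age in days,
#' birth to two years by default). The default of 102 basis functions
#' matches the representation used throughout the functional analyses.
#'
#' @param n_basis number of basis functions (default 102).
#' @param domain numeric length-2, the age domain in days.
#' @param degree spline degree (3 = cubic).
#' @return an object of class `spline_basis` with the knot vector and an
#'   evaluator.
#' @export
spline_basis <- function(n_basis = 102L, domain = c(0, 730), degree = 3L) {
  stopifnot(n_basis >= degree + 1L, domain[2] > domain[1])
  n_interior <- n_basis - degree - 1L
  interior <- if (n_interior > 0) {
    seq(domain[1], domain[2], length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  knots <- c(rep(domain[1], degree + 1L), interior, rep(domain[2], degree + 1L))
  structure(
    list(n_basis = as.integer(n_basis), domain = domain,
         degree = as.integer(degree), knots = knots),
    class = "spline_basis"
  )
}

#' Evaluate a spline basis on a grid
#'
#' @param basis a `spline_basis`.
#' @param grid ages (days) within the basis domain.
#' @return matrix, `length(grid)` x `n_basis`.
#' @export
eval_basis <- function(basis, grid) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(grid < basis$domain[1] - 1e-8 | grid > basis$domain[2] + 1e-8)) {
    stop_invalid("grid points outside basis domain [%g, %g]",
                 basis$domain[1], basis$domain[2])
  }
  g <- pmin(pmax(grid, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, g, ord = basis$degree + 1L,
                        outer.ok = FALSE)
}

#' A set of curves in a common spline basis
#'
#' Container tying a coefficient matrix (one row per child) to a shared
#' `spline_basis`, with optional time-warping functions from registration.
#'
#' @param coefs numeric matrix, children x n_basis; rownames are child ids.
#' @param basis a `spline_basis`.
#' @param warps optional list of warping functions `h_i` (see
#'   [register_curves()]).
#' @return an object of class `curve_set`.
#' @export
curve_set <- function(coefs, basis, warps = NULL) {
  stopifnot(inherits(basis, "spline_basis"),
            is.matrix(coefs), ncol(coefs) == basis$n_basis)
  structure(list(coefs = coefs, basis = basis, warps = warps),
            class = "curve_set")
}

#' Evaluate a curve set on a grid
#'
#' @param curves a `curve_set`.
#' @param grid evaluation ages (days). Defaults to 731 daily points.
#' @param registered if `TRUE` and warps are present, evaluate the aligned
#'   curves `x_i(h_i(t))`.
#' @return matrix, children x length(grid).
#' @export
eval_curves <- function(curves, grid = NULL, registered = FALSE) {
  stopifnot(inherits(curves, "curve_set"))
  b <- curves$basis
  if (is.null(grid)) grid <- seq(b$domain[1], b$domain[2], length.out = 731L)
  if (registered && !is.null(curves$warps)) {
    out <- matrix(NA_real_, nrow(curves$coefs), length(grid))
    for (i in seq_len(nrow(curves$coefs))) {
      hi <- curves$warps[[i]](grid)
      out[i, ] <- drop(eval_basis(b, hi) %*% curves$coefs[i, ])
    }
  } else {
    out <- curves$coefs %*% t(eval_basis(b, grid))
  }
  rownames(out) <- rownames(curves$coefs)
  out
}

#' Project curves sampled on a grid onto a spline basis
#'
#' Least-squares projection of grid-sampled curves onto the basis; with the
#' default 102-function basis the projection residual is negligible for
#' smooth curves.
#'
#' @param values matrix, curves x grid points.
#' @param grid the common grid (days).
#' @param basis a `spline_basis`.
#' @return a `curve_set`.
#' @export
project_curves <- function(values, grid, basis = spline_basis()) {
  if (length(grid) < basis$n_basis) {
    stop_invalid("grid (%d points) coarser than the basis (%d functions); projection underdetermined",
                 length(grid), basis$n_basis)
  }
  Theta <- eval_basis(basis, grid)
  qr_T <- qr(Theta)
  coefs <- t(qr.coef(qr_T, t(values)))
  coefs[is.na(coefs)] <- 0
  rownames(coefs) <- rownames(values)
  curve_set(coefs, basis)
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("Curve set: %d curves in a %d-function cubic B-spline basis on [%g, %g] days\n",
              nrow(x$coefs), x$basis$n_basis, x$basis$domain[1], x$basis$domain[2]))
  if (!is.null(x$warps)) cat("  (registered: warping functions attached)\n")
  invisible(x)
}

#' Write a curve set to CSV plus a basis-spec JSON
#'
#' @param curves a `curve_set`.
#' @param csv_path output CSV (child_id then one column per coefficient).
#' @param json_path output JSON with degree, knots and domain.
#' @export
write_curves <- function(curves, csv_path, json_path) {
  df <- data.frame(child_id = rownames(curves$coefs) %||%
                     as.character(seq_len(nrow(curves$coefs))),
                   curves$coefs, check.names = FALSE)
  colnames(df)[-1] <- paste0("b", seq_len(ncol(curves$coefs)))
  write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(degree = curves$basis$degree, n_basis = curves$basis$n_basis,
         domain = curves$basis$domain, knots = curves$basis$knots),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Read a curve set written by [write_curves()]
#'
#' @param csv_path,json_path paths written by [write_curves()].
#' @return a `curve_set`.
#' @export
read_curves <- function(csv_path, json_path) {
  spec <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  df <- read.csv(csv_path, check.names = FALSE)
  coefs <- as.matrix(df[, -1, drop = FALSE])
  rownames(coefs) <- as.character(df[[1]])
  b <- spline_basis(spec$n_basis, spec$domain, spec$degree)
  curve_set(coefs, b)
}
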