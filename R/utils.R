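#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor dist dnorm ecdf integrate lm lm.fit
#'   median optim pchisq pf pnorm pt qnorm quantile rbinom rchisq
#'   rlnorm rmultinom rnorm runif sd setNames uniroot var wilcox.test
#'   kruskal.test prop.test residuals rexp predict
#' @importFrom utils head read.delim write.table combn read.csv write.csv
NULL

# Derive a reproducible substream seed (< 2^31) from a master seed and a
# component tag, so independent generators do not share RNG streams.
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Trapezoidal quadrature weights for a (possibly non-uniform) grid.
trapez_weights <- function(grid) {
  G <- length(grid)
  stopifnot(G >= 2L)
  w <- numeric(G)
  d <- diff(grid)
  w[1] <- d[1] / 2
  w[G] <- d[G - 1] / 2
  if (G > 2) w[2:(G - 1)] <- (d[-1] + d[-(G - 1)]) / 2
  w
}

# Trapezoidal integral of f sampled on grid.
trapez_int <- function(f, grid) sum(trapez_weights(grid) * f)

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
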