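# Shared fixtures, all built in code at test time.

# Four-leaf toy tree ((A,B),(C,D)) with two phyla.
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1)p__Firmicutes:1,(C:1,D:1)p__Bacteroidetes:1)root;")
}

toy_taxonomy <- c(A = "Firmicutes", B = "Firmicutes",
                  C = "Bacteroidetes", D = "Bacteroidetes")

toy_table <- function(counts) {
  rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  abundance_table(counts, toy_taxonomy, toy_tree())
}

# The documented 10-sample toy table: D rare in 10/10 samples, others
# abundant.
toy_rare_table <- function() {
  set.seed(101)
  toy_table(cbind(A = rpois(10, 50) + 10, B = rpois(10, 60) + 10,
                  C = rpois(10, 40) + 10, D = c(0, 1, 0, 2, 0, 1, 0, 0, 0, 0)))
}

# Smooth curves in a given spline basis: mean + two orthonormal harmonics
# with child scores, plus optional per-predictor effects. Returns values
# on a dense grid and the curve_set.
make_curves <- function(n, basis = spline_basis(25), seed = 1,
                        sd1 = 0.11, sd2 = 0.055, effects = NULL, X = NULL,
                        grid_n = 201L) {
  dom <- basis$domain
  gr <- seq(dom[1], dom[2], length.out = grid_n)
  Tlen <- diff(dom)
  phi1 <- sqrt(2 / Tlen) * sin(pi * (gr - dom[1]) / Tlen)
  phi2 <- sqrt(2 / Tlen) * cos(pi * (gr - dom[1]) / Tlen)
  mu <- 0.07 + 0.00009 * (gr - dom[1])
  # substream keeps the curve scores decoupled from any set.seed(seed)
  # draws made by the calling test
  set.seed(growthmicro:::substream_seed(seed, "make_curves"))
  vals <- matrix(rep(mu, n), n, byrow = TRUE) +
    outer(rnorm(n, sd = sd1), phi1) + outer(rnorm(n, sd = sd2), phi2)
  if (!is.null(effects)) {
    for (k in seq_along(effects)) {
      vals <- vals + outer(X[, k], effects[[k]](gr))
    }
  }
  rownames(vals) <- sprintf("C%03d", seq_len(n))
  list(values = vals, grid = gr, curves = project_curves(vals, gr, basis),
       mu = mu, phi = cbind(phi1, phi2))
}
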