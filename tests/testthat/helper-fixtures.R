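# Shared in-code fixtures for the test suite.

# Small two-population DH program with trials: fast enough to rebuild per file.
small_config <- function(seed = 7, ...) {
  sim_config(n_populations = 2, lines_per_population = c(30, 30),
             phenotyped_per_population = c(20, 20),
             n_chromosomes = 2, markers_per_chromosome = 60, n_qtl = 20,
             blocks_per_rep = 4, n_checks = 2, seed = seed, ...)
}

# Random marker matrix with line IDs (not family-structured).
random_markers <- function(n, p, seed = 1, freq = NULL) {
  set.seed(seed)
  pr <- freq %||% stats::runif(p, 0.2, 0.8)
  X <- sapply(pr, function(q) stats::rbinom(n, 1, q))
  dimnames(X) <- list(sprintf("L%03d", seq_len(n)), sprintf("M%04d", seq_len(p)))
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw genetic values ~ N(0, s2 * G) through the eigendecomposition.
draw_gvalues <- function(G, s2 = 1) {
  ev <- eigen(G, symmetric = TRUE)
  drop(ev$vectors %*% (sqrt(pmax(ev$values, 0) * s2) * stats::rnorm(nrow(G))))
}

# Balanced multi-location plot table around supplied entry genetic values.
balanced_pheno <- function(gv, n_loc = 2, n_rep = 2, s2_gl = 0, s2_e = 1,
                           mu = 10, loc_eff = NULL, seed = 1) {
  set.seed(seed)
  ng <- length(gv)
  entries <- sprintf("G%03d", seq_len(ng))
  locs <- sprintf("L%d", seq_len(n_loc))
  le <- loc_eff %||% stats::rnorm(n_loc, 0, 0.5)
  glv <- matrix(if (s2_gl > 0) stats::rnorm(ng * n_loc, 0, sqrt(s2_gl)) else 0,
                ng, n_loc)
  d <- expand.grid(entry = entries, location = locs, rep = seq_len(n_rep),
                   stringsAsFactors = FALSE)
  d$block <- 1L
  d$management <- "WW"
  i <- match(d$entry, entries); j <- match(d$location, locs)
  d$y <- mu + le[j] + gv[i] + glv[cbind(i, j)] +
    stats::rnorm(nrow(d), 0, sqrt(s2_e))
  d
}
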