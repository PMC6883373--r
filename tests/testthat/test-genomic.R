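test_that("GRM matches a brute-force center/scale computation", {
  X <- matrix(c(0, 1, 1, 0, 1, 1, 0, 0), 4, 2,
              dimnames = list(sprintf("L%d", 1:4), c("m1", "m2")))
  g <- build_grm(X)
  # independent brute force: center, scale by divisor-n sd, Xs Xs' / p
  Xc <- sweep(X, 2, colMeans(X), "-")
  sdn <- sqrt(colSums(Xc^2) / nrow(X))
  Xs <- sweep(Xc, 2, sdn, "/")
  expect_equal(g$G, tcrossprod(Xs) / 2, tolerance = 1e-12)
  expect_equal(g$p, 2L)
})

test_that("GRM invariants: unit mean diagonal, symmetry, duplicate rows", {
  X <- random_markers(30, 80, seed = 2)
  g <- build_grm(X)
  expect_equal(mean(diag(g$G)), 1, tolerance = 1e-12)
  expect_equal(g$G, t(g$G), tolerance = 1e-10)
  expect_gt(min(eigen(g$G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # duplicate lines give identical rows and rank deficiency
  X2 <- rbind(X, dup = X[1, ])
  rownames(X2)[nrow(X2)] <- "dup"
  g2 <- build_grm(X2)
  expect_equal(unname(g2$G["dup", ]), unname(g2$G["L001", ]), tolerance = 1e-12)
  expect_lt(min(eigen(g2$G, symmetric = TRUE, only.values = TRUE)$values), 1e-10)
})

test_that("GRM handles missing codes and rejects degenerate input", {
  X <- random_markers(20, 40, seed = 3)
  Xm <- X; Xm[1, 1] <- NA
  g <- build_grm(Xm)
  expect_equal(mean(diag(g$G)), 1, tolerance = 1e-12)
  # monomorphic markers are dropped
  Xmono <- cbind(X, mono = 1L)
  expect_equal(build_grm(Xmono)$p, build_grm(X)$p)
  expect_error(build_grm(matrix(1L, 5, 4)), "no polymorphic")
  Xall <- X; Xall[2, ] <- NA
  expect_error(build_grm(Xall), "L002")
})

test_that("fixed-variance Gibbs posterior means solve the mixed-model equations", {
  set.seed(42)
  n <- 8
  X <- random_markers(n, 30, seed = 42)
  g <- build_grm(X)
  y <- draw_gvalues(g$G) + 5 + rnorm(n, 0, 0.5)
  bl <- data.frame(line = rownames(X), value = y)
  s2g <- 1; s2e <- 0.5
  # dense MME oracle with intercept and g ~ N(0, G s2g)
  Gi <- solve(g$G + diag(1e-8, n))
  C <- rbind(cbind(n, t(rep(1, n))),
             cbind(rep(1, n), diag(n) + s2e * Gi / s2g)) / s2e
  sol <- solve(C, c(sum(y), y) / s2e)
  fit <- fit_genomic(bl, g, variant = "G+e", iters = 4000, burnin = 1000,
                     thin = 1, seed = 3,
                     fix_variances = list(sigma2_g = s2g, sigma2_e = s2e))
  expect_equal(unname(fit$g), unname(sol[-1]), tolerance = 1e-3)
})

test_that("constant phenotypes give zero genomic signal", {
  X <- random_markers(15, 50, seed = 5)
  g <- build_grm(X)
  bl <- data.frame(line = rownames(X), value = 4.2)
  fit <- fit_genomic(bl, g, iters = 1500, burnin = 500, seed = 8)
  expect_lt(max(abs(fit$g)), 0.05)
  expect_equal(fit$mu, 4.2, tolerance = 0.05)
})

test_that("sampler is bit-reproducible given the seed and shift-invariant", {
  X <- random_markers(20, 60, seed = 6)
  g <- build_grm(X)
  set.seed(1); y <- draw_gvalues(g$G) + rnorm(20, 0, 0.6)
  bl <- data.frame(line = rownames(X), value = y)
  f1 <- fit_genomic(bl, g, iters = 800, burnin = 200, seed = 77)
  f2 <- fit_genomic(bl, g, iters = 800, burnin = 200, seed = 77)
  expect_identical(f1$g, f2$g)
  expect_identical(f1$var_samples, f2$var_samples)
  f3 <- fit_genomic(bl, g, iters = 800, burnin = 200, seed = 78)
  expect_false(identical(f1$g, f3$g))
  bl2 <- bl; bl2$value <- bl2$value + 11
  f4 <- fit_genomic(bl2, g, iters = 800, burnin = 200, seed = 77)
  expect_equal(f4$g, f1$g, tolerance = 1e-10)
  expect_equal(f4$mu - f1$mu, 11, tolerance = 1e-10)
})

test_that("reaction-norm model with interaction variance forced to zero matches main effects", {
  set.seed(7)
  X <- random_markers(40, 100, seed = 7)
  g <- build_grm(X)
  gv <- draw_gvalues(g$G)
  bl <- expand.grid(line = rownames(X), env = c("A", "B"),
                    stringsAsFactors = FALSE)
  bl$value <- 5 + (bl$env == "B") + gv[match(bl$line, rownames(X))] +
    rnorm(nrow(bl), 0, 0.5)
  fx <- list(sigma2_g = 1, sigma2_e = 0.25)
  f_main <- fit_genomic(bl, g, variant = "E+G+e", iters = 1200, burnin = 300,
                        seed = 5, fix_variances = fx)
  f_ge0 <- fit_genomic(bl, g, variant = "E+G+GE+e", iters = 1200, burnin = 300,
                       seed = 5, fix_variances = c(fx, list(sigma2_gE = 0)))
  expect_equal(f_ge0$g, f_main$g, tolerance = 1e-10)
})

test_that("heritability is recovered from single-environment fits", {
  set.seed(10)
  n <- 400
  X <- random_markers(n, 600, seed = 10)
  g <- build_grm(X)
  h2 <- numeric(5)
  for (s in 1:5) {
    set.seed(s)
    y <- 5 + draw_gvalues(g$G) + rnorm(n, 0, 1)   # true ratio 0.5
    bl <- data.frame(line = rownames(X), value = y)
    fit <- fit_genomic(bl, g, iters = 2500, burnin = 800, thin = 2,
                       seed = s * 100)
    h2[s] <- fit$varcomp$sigma2_g /
      (fit$varcomp$sigma2_g + fit$varcomp$sigma2_e)
  }
  expect_lt(abs(mean(h2) - 0.5), 0.1)
})

test_that("GEBVs for unphenotyped lines follow the joint genomic prior", {
  # family-structured lines from the DH simulator: 100 phenotyped, 50 masked
  cfg <- sim_config(n_populations = 3, lines_per_population = rep(50, 3),
                    phenotyped_per_population = rep(34, 3),
                    n_chromosomes = 2, markers_per_chromosome = 80,
                    n_qtl = 30, blocks_per_rep = 4, n_checks = 0,
                    variance_targets = list(WW = c(G = 1, GxE = 0, e = 0.25),
                                            WS = c(G = 1, GxE = 0, e = 0.25)),
                    seed = 20)
  pr <- simulate_program(cfg)
  g <- build_grm(pr$genotypes)
  tr1 <- pr$truth[pr$truth$env == "WW1", ]
  gv <- setNames(tr1$g_true, tr1$line)
  set.seed(30)
  train <- pr$lines$line[pr$lines$phenotyped]
  test <- pr$lines$line[!pr$lines$phenotyped]
  y <- 5 + gv[train] + rnorm(length(train), 0, 0.5)   # h2 = 0.8
  bl <- data.frame(line = train, value = unname(y))
  fit <- fit_genomic(bl, g, iters = 2500, burnin = 800, seed = 30)
  pred <- predict_gebv(fit, test)
  expect_gt(cor(pred$gebv, gv[pred$line]), 0.5)
  # unknown target lines are reported by ID
  expect_error(predict_gebv(fit, c("nope1", train[1])), "nope1")
})

test_that("prediction respects relationship structure in edge cases", {
  X <- random_markers(25, 80, seed = 21)
  g <- build_grm(X)
  set.seed(2); y <- draw_gvalues(g$G) + rnorm(25, 0, 0.4)
  train <- rownames(X)[1:20]
  bl <- data.frame(line = train, value = y[1:20])
  # a target with zero relationship to training lines: GEBV = prior mean 0
  G2 <- g$G
  G2 <- rbind(cbind(G2, orphan = 0), orphan = c(rep(0, 25), 1))
  fit0 <- fit_genomic(bl, G2, iters = 1000, burnin = 300, seed = 9)
  expect_equal(predict_gebv(fit0, "orphan")$gebv, 0, tolerance = 1e-10)
  # a duplicate of a training line predicts that line's fitted value
  Xd <- rbind(X, twin = X[1, ]); rownames(Xd)[26] <- "twin"
  gd <- build_grm(Xd)
  fitd <- fit_genomic(bl, gd, iters = 1500, burnin = 500, seed = 10)
  expect_equal(predict_gebv(fitd, "twin")$gebv,
               unname(fitd$g[train[1]]), tolerance = 0.02)
})

test_that("environment-specific predictions add environment and interaction terms", {
  set.seed(31)
  X <- random_markers(30, 80, seed = 31)
  g <- build_grm(X)
  gv <- draw_gvalues(g$G)
  bl <- expand.grid(line = rownames(X), env = c("A", "B"),
                    stringsAsFactors = FALSE)
  bl$value <- 5 + 2 * (bl$env == "B") + gv[match(bl$line, rownames(X))] +
    rnorm(nrow(bl), 0, 0.3)
  fit <- fit_genomic(bl, g, variant = "E+G+GE+e", iters = 1500, burnin = 500,
                     seed = 12)
  pe <- predict_gebv(fit, rownames(X)[1:5], what = "env")
  expect_setequal(unique(pe$env), c("A", "B"))
  dAB <- tapply(pe$gebv, pe$env, mean)
  expect_equal(unname(dAB["B"] - dAB["A"]), 2, tolerance = 0.3)
})

test_that("invalid chain and model configurations are rejected", {
  X <- random_markers(10, 30, seed = 40)
  g <- build_grm(X)
  bl <- data.frame(line = rownames(X), value = rnorm(10))
  expect_error(fit_genomic(bl, g, iters = 100, burnin = 100, seed = 1),
               "burnin")
  expect_error(fit_genomic(bl, g, seed = NULL), "seed")
  expect_error(fit_genomic(bl, g, variant = "E+G+GE+e", iters = 200,
                           burnin = 50, seed = 1), ">= 2 environments")
  bl2 <- rbind(bl, data.frame(line = rownames(X), value = rnorm(10)))
  bl2$env <- rep(c("A", "B"), each = 10)
  expect_error(fit_genomic(bl2, g, variant = "G+e", iters = 200, burnin = 50,
                           seed = 1), "exactly one environment")
  # non-PSD matrix is reported with its smallest eigenvalue
  Gbad <- g$G; Gbad[1, 2] <- Gbad[1, 2] + 2; Gbad[2, 1] <- Gbad[1, 2]
  expect_error(fit_genomic(bl, Gbad, iters = 200, burnin = 50, seed = 1),
               "positive semidefinite")
})
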