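test_that("REML on balanced no-block data matches the ANOVA EMS estimators", {
  set.seed(3)
  ng <- 40; l <- 2; r <- 2
  gv <- rnorm(ng, 0, sqrt(2))
  d <- balanced_pheno(gv, n_loc = l, n_rep = r, s2_gl = 1, s2_e = 0.64, seed = 3)
  # expected-mean-squares oracle from the classical balanced ANOVA
  a <- stats::aov(y ~ location + location:factor(rep) + entry + entry:location,
                  data = d)
  tab <- summary(a)[[1]]
  ms <- tab[, "Mean Sq"]; rn <- trimws(rownames(tab))
  s2e_an <- ms[rn == "Residuals"]
  s2gl_an <- (ms[rn == "location:entry"] - s2e_an) / r
  s2g_an <- (ms[rn == "entry"] - ms[rn == "location:entry"]) / (l * r)
  fit <- fit_multi_location(d, "y", genotype_role = "random")
  expect_equal(unname(fit$varcomp["sigma2_G"]), unname(s2g_an), tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["sigma2_GL"]), unname(s2gl_an), tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["sigma2_e"]), unname(s2e_an), tolerance = 1e-6)
})

test_that("BLUEs equal across-location plot means on balanced noise-free data", {
  set.seed(5)
  gv <- rnorm(30)
  d <- balanced_pheno(gv, s2_gl = 0, s2_e = 0, seed = 5)
  fit <- fit_multi_location(d, "y", genotype_role = "fixed")
  mns <- tapply(d$y, d$entry, mean)
  expect_equal(fit$blues$blue, as.numeric(mns[fit$blues$entry]),
               tolerance = 1e-8)
  expect_lt(fit$varcomp["sigma2_e"], 1e-8)
})

test_that("variance components are equivariant under entry relabelling", {
  set.seed(8)
  d <- balanced_pheno(rnorm(25), s2_gl = 0.5, s2_e = 1, seed = 8)
  f1 <- fit_multi_location(d, "y", genotype_role = "random")
  perm <- sample(unique(d$entry))
  d2 <- d
  d2$entry <- perm[match(d$entry, unique(d$entry))]
  f2 <- fit_multi_location(d2, "y", genotype_role = "random")
  expect_equal(f1$varcomp, f2$varcomp, tolerance = 1e-6)
  b1 <- fit_multi_location(d, "y", "fixed")$blues
  b2 <- fit_multi_location(d2, "y", "fixed")$blues
  expect_equal(b2$blue[match(perm[match(b1$entry, unique(d$entry))], b2$entry)],
               b1$blue, tolerance = 1e-8)
})

test_that("single-location model recovers known variance components", {
  set.seed(9)
  ng <- 500
  gv <- as.numeric(scale(rnorm(ng)))  # realized genetic variance exactly 1
  d <- expand.grid(entry = sprintf("G%03d", seq_len(ng)), rep = 1:2,
                   stringsAsFactors = FALSE)
  d$location <- "WS1"; d$management <- "WS"
  # resolvable blocking: entries re-randomized to blocks in each replicate
  d$block <- unlist(lapply(1:2, function(r)
    sample(rep(seq_len(10), length.out = ng))))
  d$y <- 3 + gv[match(d$entry, unique(d$entry))] + rnorm(nrow(d), 0, 1)
  fit <- fit_single_location(d, "y", genotype_role = "random")
  expect_lt(abs(fit$varcomp["sigma2_G"] - 1), 0.15)
  expect_lt(abs(fit$varcomp["sigma2_e"] - 1), 0.15)
  expect_error(fit_multi_location(d, "y"), "single_location")
})

test_that("single-location BLUEs handle degenerate designs", {
  d <- data.frame(entry = rep(c("A", "B"), each = 2), location = "WS1",
                  management = "WS", rep = rep(1:2, 2), block = 1,
                  y = c(4, 4, 6, 6))
  fit <- fit_single_location(d, "y", genotype_role = "fixed")
  expect_equal(sort(fit$blues$blue), c(4, 6), tolerance = 1e-10)
  expect_lt(fit$varcomp["sigma2_e"], 1e-12)
  # an entry seen in only one rep still gets a BLUE, with a larger SE
  d2 <- rbind(d, data.frame(entry = "C", location = "WS1", management = "WS",
                            rep = 1, block = 1, y = 5.5))
  d2$y <- d2$y + c(0.1, -0.1, 0.05, -0.05, 0)
  fit2 <- fit_single_location(d2, "y", genotype_role = "fixed")
  b <- fit2$blues
  expect_true("C" %in% b$entry)
  expect_gt(b$se[b$entry == "C"], max(b$se[b$entry != "C"]))
  # multi-location input is rejected
  d3 <- d; d3$location <- rep(c("L1", "L2"), 2)
  expect_error(fit_single_location(d3, "y"), "exactly one location")
})

test_that("across-trial model absorbs a constant trial offset", {
  set.seed(12)
  gv <- rnorm(20)
  d1 <- balanced_pheno(gv, n_loc = 2, n_rep = 2, s2_e = 0.2, seed = 12)
  d1$trial <- "T1"
  d2 <- d1; d2$trial <- "T2"; d2$y <- d2$y + 1.5
  both <- rbind(d1, d2)
  fit <- fit_across_trials(both, "y", genotype_role = "fixed")
  tr_coef <- fit$fixef[grep("^trial", names(fit$fixef))]
  expect_equal(unname(tr_coef), 1.5, tolerance = 1e-6)
  expect_true(fit$connected)
  # identical entries in both trials: BLUEs are mid-offset entry means
  b <- fit$blues
  mns <- tapply(both$y, both$entry, mean)
  expect_equal(b$blue, as.numeric(mns[b$entry]), tolerance = 1e-6)
  expect_error(fit_across_trials(d1, "y"), ">= 2 trials")
})

test_that("trials connected only through checks stay estimable and are flagged otherwise", {
  set.seed(13)
  mk_trial <- function(tr, entries, off) {
    d <- expand.grid(entry = entries, location = c("L1", "L2"), rep = 1:2,
                     stringsAsFactors = FALSE)
    d$block <- 1; d$management <- "WW"; d$trial <- tr
    d$y <- 6 + off + rnorm(nrow(d), 0, 0.3)
    d
  }
  t1 <- mk_trial("T1", c(sprintf("A%d", 1:6), "CHK1"), 0)
  t2 <- mk_trial("T2", c(sprintf("B%d", 1:6), "CHK1"), 0.8)
  fit <- fit_across_trials(rbind(t1, t2), "y", genotype_role = "fixed")
  expect_true(fit$connected)
  expect_equal(nrow(fit$blues), 13)
  expect_true(all(is.finite(fit$blues$blue)))
  # no shared entries: connectivity warning
  t2b <- mk_trial("T2", sprintf("B%d", 1:6), 0.8)
  expect_warning(fit2 <- fit_across_trials(rbind(t1, t2b), "y", "fixed"),
                 "not connected")
  expect_false(fit2$connected)
})

test_that("trait summary implements the entry-mean h2, LSD and CV formulas", {
  fake_fit <- structure(list(variant = "multi_location", trait = "GY",
                             genotype_role = "random", n_locations = 3,
                             n_reps = 2, n_entries = 100, n_obs = 600,
                             grand_mean = 6.03,
                             varcomp = c(sigma2_B = 0, sigma2_G = 0.19,
                                         sigma2_GL = 0.18, sigma2_e = 1.41)),
                        class = "model_fit")
  ts <- trait_summary(fake_fit)
  expect_equal(ts$h2, 0.19 / (0.19 + 0.18 / 3 + 1.41 / 6), tolerance = 1e-12)
  expect_equal(ts$CV, 100 * sqrt(1.41) / 6.03, tolerance = 1e-12)
  df <- (100 - 1) * (6 - 1)
  expect_equal(ts$LSD, qt(0.975, df) * sqrt(2 * 1.41 / 6), tolerance = 1e-12)
  # limit cases
  fake_fit$varcomp <- c(sigma2_B = 0, sigma2_G = 0.3, sigma2_GL = 0, sigma2_e = 0)
  expect_equal(trait_summary(fake_fit)$h2, 1)
  fake_fit$varcomp <- c(sigma2_B = 0, sigma2_G = 0, sigma2_GL = 0.2, sigma2_e = 1)
  expect_equal(trait_summary(fake_fit)$h2, 0)
})

test_that("h2 is monotone in genetic variance and in replication", {
  h <- function(g, l, r) heritability(g, 0.2, 1.2, l, r)
  gs <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(sapply(gs, h, l = 3, r = 2)) > 0))
  expect_true(all(diff(sapply(1:6, function(l) h(0.3, l, 2))) > 0))
  expect_true(all(diff(sapply(1:6, function(r) h(0.3, 3, r))) > 0))
})
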