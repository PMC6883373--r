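# Genomic relationship matrix and Bayesian G-BLUP / reaction-norm models.
#
# Line genomic values follow g ~ N(0, G sigma2_g) with G = Xs Xs' / p on the
# column-standardized marker matrix. Three model variants on line-by-
# environment means y_ij:
#   G+e:       y_j  = mu + g_j + e_j                (single environment)
#   E+G+e:     y_ij = mu + E_i + g_j + e_ij
#   E+G+GE+e:  y_ij = mu + E_i + g_j + gE_ij + e_ij
# where gE ~ N(0, (Zg G Zg') o (ZE ZE') sigma2_gE), the Hadamard product of
# the genomic and environment-incidence kernels: within an environment the
# interaction is G-correlated across lines, across environments independent.
#
# Estimation is a Gibbs sampler with flat priors on mu/E and scaled-inverse-
# chi-square priors on all variance components. G is eigendecomposed once and
# the genomic terms are sampled in the eigenbasis, which makes the updates
# diagonal whenever each training line is observed once per environment.

#' Build the genomic relationship matrix
#'
#' Monomorphic markers are dropped, missing codes mean-imputed per marker,
#' columns centered and scaled by the per-marker standard deviation with
#' divisor n, and G = Xs Xs' / p. The divisor-n scaling makes
#' `mean(diag(G)) == 1` exact.
#'
#' @param markers Numeric matrix, lines in rows (rownames = line IDs),
#'   markers in columns; codes 0/1 or 0/1/2, `NA` allowed.
#' @return Object of class `grm`: list with `G`, `p` (markers retained),
#'   `centers`, `scales`, `markers`.
#' @export
build_grm <- function(markers) {
  X <- as.matrix(markers)
  if (is.null(rownames(X))) rownames(X) <- sprintf("L%d", seq_len(nrow(X)))
  if (nrow(X) < 2) stop_("need >= 2 lines to build a GRM")
  if (anyDuplicated(rownames(X))) stop_("duplicate line IDs")
  if (!is.null(colnames(X)) && anyDuplicated(colnames(X)))
    stop_("duplicate marker IDs")
  all_miss <- rowSums(!is.na(X)) == 0
  if (any(all_miss))
    stop_("line(s) with all marker codes missing: %s",
          paste(rownames(X)[all_miss], collapse = ", "))
  storage.mode(X) <- "double"
  n <- nrow(X)
  centers <- colMeans(X, na.rm = TRUE)
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- centers[idx[, 2]]
  }
  # population (divisor-n) standard deviation per marker
  scales <- sqrt(colMeans(X^2) - colMeans(X)^2)
  keep <- scales > 0
  if (!any(keep)) stop_("no polymorphic markers")
  Xs <- sweep(X[, keep, drop = FALSE], 2, centers[keep], "-")
  Xs <- sweep(Xs, 2, scales[keep], "/")
  p <- sum(keep)
  G <- tcrossprod(Xs) / p
  structure(list(G = G, p = p, centers = centers[keep], scales = scales[keep],
                 markers = colnames(X)[keep] %||% which(keep)),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM over %d lines from %d polymorphic markers; mean diag = %.6f\n",
              nrow(x$G), x$p, mean(diag(x$G))))
  invisible(x)
}

grm_matrix <- function(grm) {
  if (inherits(grm, "grm")) grm$G
  else if (is.matrix(grm)) grm
  else stop_("grm must be a 'grm' object or a matrix")
}

siChisq_scale <- function(mode, df) mode * (df + 2) / df

draw_scaled_inv_chisq <- function(ss, df0, scale0, n) {
  (ss + df0 * scale0) / stats::rchisq(1L, df = df0 + n)
}

#' Fit a Bayesian G-BLUP / reaction-norm model by Gibbs sampling
#'
#' @param blues Data frame of line-by-environment means with columns `line`,
#'   `env`, `value` (for a single-environment fit `env` may be omitted).
#' @param grm A [build_grm()] object (or a relationship matrix) covering
#'   every phenotyped line; lines present in the GRM but not in `blues` are
#'   predicted by [predict_gebv()] through their genomic relationships.
#' @param variant `"auto"` (default: `G+e` for one environment, `E+G+e`
#'   otherwise), `"G+e"`, `"E+G+e"` or `"E+G+GE+e"`.
#' @param iters,burnin,thin Chain settings; defaults 15000/5000/5.
#' @param seed RNG seed (mandatory: the sampler is fully reproducible given
#'   the seed).
#' @param df0 Prior degrees of freedom for every variance component.
#' @param fix_variances Optional named list (`sigma2_g`, `sigma2_gE`,
#'   `sigma2_e`) of variance components to hold fixed instead of sampling
#'   (used for closed-form validation).
#' @param min_eigen Tolerance on the smallest eigenvalue of G; eigenvalues in
#'   `(-min_eigen, 0]` receive a `1e-8` jitter, anything lower is an error.
#' @return Object of class `genomic_fit` with posterior means of `mu`,
#'   environment effects, line values `g`, interactions `gE`, variance
#'   components (and their retained samples), plus the eigen-structures
#'   needed for prediction.
#' @export
fit_genomic <- function(blues, grm, variant = c("auto", "G+e", "E+G+e", "E+G+GE+e"),
                        iters = 15000L, burnin = 5000L, thin = 5L,
                        seed = NULL, df0 = 5,
                        fix_variances = NULL, min_eigen = 1e-8) {
  variant <- match.arg(variant)
  if (is.null(seed)) stop_("fit_genomic requires an explicit seed")
  if (burnin >= iters) stop_("burnin must be smaller than iters")
  if (thin < 1) stop_("thin must be >= 1")
  G <- grm_matrix(grm)
  if (!"env" %in% names(blues)) blues$env <- "E1"
  need <- c("line", "env", "value")
  if (!all(need %in% names(blues)))
    stop_("blues needs columns line, env, value")
  blues <- blues[is.finite(blues$value), , drop = FALSE]
  envs <- sort(unique(as.character(blues$env)))
  n_env <- length(envs)
  if (variant == "auto") variant <- if (n_env == 1) "G+e" else "E+G+e"
  if (variant == "G+e" && n_env != 1)
    stop_("variant G+e requires exactly one environment")
  if (variant == "E+G+GE+e" && n_env < 2)
    stop_("variant E+G+GE+e requires >= 2 environments")
  use_ge <- variant == "E+G+GE+e"

  train <- sort(unique(as.character(blues$line)))
  missing_lines <- setdiff(train, rownames(G))
  if (length(missing_lines))
    stop_("phenotyped line(s) absent from the GRM: %s",
          paste(utils::head(missing_lines, 5), collapse = ", "))
  n_t <- length(train)
  if (anyDuplicated(paste(blues$line, blues$env)))
    stop_("duplicate line x environment records in blues")

  # observations as an n_t x n_env matrix, NA where a cell is unobserved
  Y <- matrix(NA_real_, n_t, n_env, dimnames = list(train, envs))
  Y[cbind(match(blues$line, train), match(blues$env, envs))] <- blues$value
  obs <- !is.na(Y)
  n_obs <- sum(obs)
  balanced <- all(obs)

  Gtt <- G[train, train, drop = FALSE]
  ev <- eigen((Gtt + t(Gtt)) / 2, symmetric = TRUE)
  d <- ev$values
  if (min(d) < -min_eigen)
    stop_("G is not positive semidefinite: smallest eigenvalue %.3e", min(d))
  d <- pmax(d, 0) + 1e-8   # jitter against rank deficiency (duplicate lines)
  U <- ev$vectors
  k <- n_t

  vy <- stats::var(blues$value)
  if (!is.finite(vy) || vy == 0) vy <- 1
  n_gen <- 1L + use_ge
  S_g <- siChisq_scale(0.5 * vy / n_gen, df0)
  S_ge <- siChisq_scale(0.5 * vy / n_gen, df0)
  S_e <- siChisq_scale(0.5 * vy, df0)

  fx <- fix_variances %||% list()
  s2g <- fx$sigma2_g %||% (0.5 * vy / n_gen)
  s2ge <- if (use_ge) fx$sigma2_gE %||% (0.5 * vy / n_gen) else 0
  s2e <- fx$sigma2_e %||% (0.5 * vy)
  fix_g <- !is.null(fx$sigma2_g); fix_ge <- !is.null(fx$sigma2_gE)
  fix_e <- !is.null(fx$sigma2_e)

  if (!balanced) {
    # precompute cross-products of the eigenbasis over observed cells
    A_g <- matrix(0, k, k)
    A_e <- vector("list", n_env)
    for (e in seq_len(n_env)) {
      Ue <- U[obs[, e], , drop = FALSE]
      A_e[[e]] <- crossprod(Ue)
      A_g <- A_g + A_e[[e]]
    }
  }

  keep_iters <- seq.int(burnin + thin, iters, by = thin)
  n_keep <- length(keep_iters)
  if (n_keep < 1) stop_("chain settings retain no samples")

  with_seed(seed, {
    beta <- rep(mean(blues$value), n_env)
    a <- rep(0, k); g <- rep(0, n_t)
    b <- matrix(0, k, n_env); gE <- matrix(0, n_t, n_env)
    beta_cm <- beta; g_cm <- g; gE_cm <- gE
    mu_b <- rep(0, k); mu_b_all <- matrix(0, k, n_env)
    sum_beta <- rep(0, n_env); sum_g <- rep(0, n_t)
    sum_gE <- matrix(0, n_t, n_env)
    var_samp <- matrix(NA_real_, n_keep, 3,
                       dimnames = list(NULL, c("sigma2_g", "sigma2_gE", "sigma2_e")))
    ki <- 0L
    n_per_env <- colSums(obs)

    for (it in seq_len(iters)) {
      ## fixed effects (flat prior): per-environment intercepts
      R0 <- Y - g - gE
      for (e in seq_len(n_env)) {
        m <- mean(R0[obs[, e], e])
        beta_cm[e] <- m
        beta[e] <- stats::rnorm(1, m, sqrt(s2e / n_per_env[e]))
      }
      Rb <- sweep(Y, 2, beta, "-")

      ## genomic main effects in the eigenbasis
      Rg <- Rb - gE
      if (balanced) {
        s <- rowSums(Rg)
        atil <- crossprod(U, s)
        prec <- n_env / s2e + 1 / (d * s2g)
        mu_a <- (atil / s2e) / prec
        a <- stats::rnorm(k, mu_a, sqrt(1 / prec))
      } else {
        s <- rowSums(Rg * obs, na.rm = TRUE)
        rhs <- crossprod(U, s) / s2e
        C <- A_g / s2e + diag(1 / (d * s2g), k)
        ch <- chol(C)
        mu_a <- backsolve(ch, forwardsolve(t(ch), rhs))
        a <- mu_a + backsolve(ch, stats::rnorm(k))
      }
      g <- drop(U %*% a)
      g_cm <- drop(U %*% mu_a)

      ## interaction effects, independent across environments
      if (use_ge && s2ge > 0) {
        Re <- Rb - g
        for (e in seq_len(n_env)) {
          if (balanced) {
            btil <- crossprod(U, Re[, e])
            prec <- 1 / s2e + 1 / (d * s2ge)
            mu_b <- (btil / s2e) / prec
            b[, e] <- stats::rnorm(k, mu_b, sqrt(1 / prec))
          } else {
            r_e <- ifelse(obs[, e], Re[, e], 0)
            rhs <- crossprod(U, r_e) / s2e
            C <- A_e[[e]] / s2e + diag(1 / (d * s2ge), k)
            ch <- chol(C)
            mu_b <- backsolve(ch, forwardsolve(t(ch), rhs))
            b[, e] <- mu_b + backsolve(ch, stats::rnorm(k))
            mu_b_all[, e] <- mu_b
          }
        }
        gE <- U %*% b
        gE_cm <- U %*% mu_b_all
      }

      ## variance components: scaled-inverse-chi-square full conditionals
      if (!fix_g)
        s2g <- draw_scaled_inv_chisq(sum(a^2 / d), df0, S_g, k)
      if (use_ge && !fix_ge)
        s2ge <- draw_scaled_inv_chisq(sum(sweep(b^2, 1, d, "/")), df0, S_ge,
                                      k * n_env)
      resid <- Rb - g - gE
      if (!fix_e)
        s2e <- draw_scaled_inv_chisq(sum(resid[obs]^2), df0, S_e, n_obs)

      if (it > burnin && (it - burnin) %% thin == 0L) {
        ki <- ki + 1L
        sum_beta <- sum_beta + beta_cm
        sum_g <- sum_g + g_cm
        sum_gE <- sum_gE + gE_cm
        var_samp[ki, ] <- c(s2g, s2ge, s2e)
      }
    }
  })

  mu <- mean(sum_beta / n_keep)
  env_eff <- sum_beta / n_keep - mu
  names(env_eff) <- envs
  g_mean <- stats::setNames(sum_g / n_keep, train)
  gE_mean <- sum_gE / n_keep
  dimnames(gE_mean) <- list(train, envs)
  vc <- colMeans(var_samp)
  p_mark <- if (inherits(grm, "grm")) grm$p else NA_real_
  structure(list(variant = variant, envs = envs, train_lines = train,
                 mu = mu, env_effects = env_eff, g = g_mean, gE = gE_mean,
                 varcomp = as.list(vc),
                 sigma2_b = unname(vc["sigma2_g"]) / p_mark,
                 var_samples = as.data.frame(var_samp),
                 G = G, U = U, d = d,
                 chain = list(iters = iters, burnin = burnin, thin = thin,
                              seed = seed, n_kept = n_keep, df0 = df0)),
            class = "genomic_fit")
}

#' @export
print.genomic_fit <- function(x, ...) {
  cat(sprintf("Genomic fit [%s]: %d training lines, %d environment(s)\n",
              x$variant, length(x$train_lines), length(x$envs)))
  cat(sprintf("  posterior means: sigma2_g = %.4f, sigma2_gE = %.4f, sigma2_e = %.4f\n",
              x$varcomp$sigma2_g, x$varcomp$sigma2_gE, x$varcomp$sigma2_e))
  invisible(x)
}

#' Genomic estimated breeding values for target lines
#'
#' For training lines the GEBV is the posterior mean of g_j. For lines that
#' were genotyped but not phenotyped, the GEBV is the posterior mean implied
#' by the joint prior N(0, G sigma2_g): the conditional expectation
#' G_nt G_tt^-1 g_t of the target values given the training values (and
#' likewise for the within-environment interaction term).
#'
#' @param fit A [fit_genomic()] result.
#' @param target_line_ids Lines to predict; must all be present in the GRM
#'   used for fitting.
#' @param what `"line"` (default) returns one genomic value g_j per line;
#'   `"env"` returns environment-specific predictions
#'   mu + E_i + g_j (+ gE_ij when fitted).
#' @return Data frame `line`, `gebv` (plus `env` for `what = "env"`).
#' @export
predict_gebv <- function(fit, target_line_ids, what = c("line", "env")) {
  what <- match.arg(what)
  stopifnot(inherits(fit, "genomic_fit"))
  ids <- as.character(target_line_ids)
  missing_ids <- setdiff(ids, rownames(fit$G))
  if (length(missing_ids))
    stop_("target line(s) absent from the GRM: %s",
          paste(missing_ids, collapse = ", "))
  train <- fit$train_lines
  g_t <- numeric(length(ids)); names(g_t) <- ids
  in_train <- ids %in% train
  g_t[in_train] <- fit$g[ids[in_train]]
  gE_t <- matrix(0, length(ids), length(fit$envs),
                 dimnames = list(ids, fit$envs))
  gE_t[in_train, ] <- fit$gE[ids[in_train], , drop = FALSE]
  if (any(!in_train)) {
    new <- ids[!in_train]
    Gnt <- fit$G[new, train, drop = FALSE]
    # G_tt^-1 v through the eigendecomposition used in fitting
    ginv_apply <- function(v) fit$U %*% (crossprod(fit$U, v) / fit$d)
    g_t[new] <- drop(Gnt %*% ginv_apply(fit$g))
    if (any(fit$gE != 0))
      gE_t[new, ] <- Gnt %*% apply(fit$gE, 2, ginv_apply)
  }
  if (what == "line")
    return(data.frame(line = ids, gebv = unname(g_t), stringsAsFactors = FALSE))
  out <- expand.grid(line = ids, env = fit$envs, stringsAsFactors = FALSE)
  out$gebv <- fit$mu + fit$env_effects[out$env] + g_t[out$line] +
    gE_t[cbind(out$line, out$env)]
  out$gebv <- unname(out$gebv)
  rownames(out) <- NULL
  out
}
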