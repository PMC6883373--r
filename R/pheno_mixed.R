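# Mixed-model analysis of multi-environment testcross trials.
#
# Multi-location model:  Y_ijrk = mu + L_j + R_r(L_j) + B_k[R_r(L_j)] + G_i
#                                 + GL_ij + e_ijrk
# Single-location model: Y_irk  = mu + R_r + B_k(R_r) + G_i + e_irk
# Across-trial model:    multi-location model plus trial as a fixed effect,
#                        trials connected through common check entries.
#
# Location, replicate-within-location (and trial) are fixed; incomplete
# blocks and line-by-location interaction are random. BLUEs come from a fit
# with genotype fixed; variance components, BLUPs and heritability from a
# second fit with genotype random. Estimation is REML (lme4).

pheno_required <- c("location", "management", "rep", "block", "entry")

check_pheno <- function(pheno, trait) {
  miss <- setdiff(pheno_required, names(pheno))
  if (length(miss))
    stop_("phenotype table is missing column(s): %s", paste(miss, collapse = ", "))
  if (!trait %in% names(pheno)) stop_("trait column '%s' not found", trait)
  pheno <- pheno[is.finite(suppressWarnings(as.numeric(pheno[[trait]]))), ,
                 drop = FALSE]
  if (!nrow(pheno)) stop_("no finite observations for trait '%s'", trait)
  pheno
}

has_blocks <- function(pheno) {
  # blocking informative only if some rep contains more than one block
  any(tapply(pheno$block, paste(pheno$location, pheno$rep),
             function(b) length(unique(b))) > 1)
}

varcomp_of <- function(fit, term) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- vc$vcov[match(term, vc$grp)]
  ifelse(is.na(v), 0, v)
}

blues_from_fit <- function(fit) {
  em <- suppressMessages(
    emmeans::emmeans(fit, "entry", weights = "equal", lmer.df = "asymptotic"))
  s <- as.data.frame(em)
  data.frame(entry = as.character(s$entry), blue = s$emmean, se = s$SE,
             stringsAsFactors = FALSE)
}

new_model_fit <- function(variant, trait, genotype_role, fit, pheno, extra = list()) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  res <- list(variant = variant, trait = trait, genotype_role = genotype_role,
              n_locations = length(unique(pheno$location)),
              n_reps = length(unique(pheno$rep)),
              n_entries = length(unique(pheno$entry)),
              n_obs = nrow(pheno),
              grand_mean = mean(pheno[[".y"]]),
              logLik = as.numeric(stats::logLik(fit)),
              varcomp = c(
                sigma2_B = varcomp_of(fit, "blk_id"),
                sigma2_G = varcomp_of(fit, "entry"),
                sigma2_GL = varcomp_of(fit, "entry:location"),
                sigma2_e = stats::sigma(fit)^2),
              fixef = lme4::fixef(fit),
              model = fit)
  if (genotype_role == "fixed") {
    res$blues <- blues_from_fit(fit)
  } else {
    re <- lme4::ranef(fit)$entry
    res$blups <- data.frame(entry = rownames(re), blup = re[[1]],
                            stringsAsFactors = FALSE)
  }
  res[names(extra)] <- extra
  class(res) <- "model_fit"
  res
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Mixed-model fit (%s, trait %s, genotype %s)\n",
              x$variant, x$trait, x$genotype_role))
  cat(sprintf("  %d entries, %d locations, %d reps, %d plots\n",
              x$n_entries, x$n_locations, x$n_reps, x$n_obs))
  cat("  variance components:\n")
  print(round(x$varcomp, 4))
  invisible(x)
}

prep_factors <- function(pheno, trait) {
  pheno <- check_pheno(pheno, trait)
  pheno$.y <- as.numeric(pheno[[trait]])
  pheno$entry <- factor(pheno$entry)
  pheno$location <- factor(pheno$location)
  pheno$rep_f <- factor(paste(pheno$location, pheno$rep, sep = ":"))
  pheno$blk_id <- factor(paste(pheno$location, pheno$rep, pheno$block, sep = ":"))
  pheno
}

fit_lmm <- function(form, pheno) {
  suppressMessages(suppressWarnings(
    lme4::lmer(form, data = pheno, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore",
                                           calc.derivs = FALSE,
                                           optimizer = "bobyqa",
                                           optCtrl = list(rhoend = 1e-10)))))
}

#' Fit the multi-location mixed model
#'
#' Location and replicate-within-location are fixed; incomplete block within
#' replicate-within-location and the line-by-location interaction are random.
#' With `genotype_role = "fixed"` the fit yields per-entry BLUEs with
#' standard errors; with `"random"` it yields variance components
#' (sigma2_B, sigma2_G, sigma2_GL, sigma2_e) and entry BLUPs.
#'
#' @param pheno Plot-level phenotype table (see [simulate_trials()] for the
#'   expected columns).
#' @param trait Name of the trait column.
#' @param genotype_role `"fixed"` (BLUEs) or `"random"` (variance
#'   components / BLUPs).
#' @return A `model_fit` object.
#' @export
fit_multi_location <- function(pheno, trait,
                               genotype_role = c("fixed", "random")) {
  genotype_role <- match.arg(genotype_role)
  pheno <- prep_factors(pheno, trait)
  n_loc <- nlevels(pheno$location)
  if (n_loc < 2)
    stop_("only one location present: use fit_single_location()")
  if (length(unique(pheno$blk_id)) <= 1 && nlevels(pheno$entry) > 1 &&
      length(unique(paste(pheno$location, pheno$rep))) <= 1)
    stop_("unidentifiable design: all entries in a single block")
  blocks <- has_blocks(pheno)
  rhs <- "location + rep_f"
  re <- c(if (blocks) "(1 | blk_id)", "(1 | entry:location)")
  form <- if (genotype_role == "fixed")
    stats::reformulate(c("0", "entry", rhs, re), response = ".y")
  else
    stats::reformulate(c(rhs, "(1 | entry)", re), response = ".y")
  fit <- fit_lmm(form, pheno)
  new_model_fit("multi_location", trait, genotype_role, fit, pheno)
}

#' Fit the single-location mixed model
#'
#' For the managed-drought (single-site) analysis: replicate fixed, block
#' within replicate random, no location or line-by-location terms.
#'
#' @inheritParams fit_multi_location
#' @return A `model_fit` object.
#' @export
fit_single_location <- function(pheno, trait,
                                genotype_role = c("fixed", "random")) {
  genotype_role <- match.arg(genotype_role)
  pheno <- prep_factors(pheno, trait)
  if (nlevels(pheno$location) != 1)
    stop_("fit_single_location requires exactly one location")
  blocks <- has_blocks(pheno)
  multi_rep <- length(unique(pheno$rep)) > 1
  rhs <- if (multi_rep) "rep_f" else "1"
  re <- if (blocks) "(1 | blk_id)" else NULL
  form <- if (genotype_role == "fixed")
    stats::reformulate(c("0", "entry", if (multi_rep) rhs, re), response = ".y")
  else
    stats::reformulate(c(rhs, "(1 | entry)", re), response = ".y")
  if (is.null(lme4::findbars(form))) {
    # no random terms at all: ordinary least squares via lm
    fitl <- stats::lm(form, data = pheno)
    return(ols_model_fit("single_location", trait, genotype_role, fitl, pheno))
  }
  fit <- fit_lmm(form, pheno)
  out <- new_model_fit("single_location", trait, genotype_role, fit, pheno)
  out$varcomp["sigma2_GL"] <- NA_real_
  out
}

# Degenerate designs (no blocks, genotype fixed, single rep term) collapse to
# least squares; wrap the lm result in the same model_fit surface.
ols_model_fit <- function(variant, trait, genotype_role, fitl, pheno) {
  res <- list(variant = variant, trait = trait, genotype_role = genotype_role,
              n_locations = length(unique(pheno$location)),
              n_reps = length(unique(pheno$rep)),
              n_entries = length(unique(pheno$entry)),
              n_obs = nrow(pheno), grand_mean = mean(pheno$.y),
              logLik = as.numeric(stats::logLik(fitl)),
              varcomp = c(sigma2_B = 0, sigma2_G = 0, sigma2_GL = NA_real_,
                          sigma2_e = stats::sigma(fitl)^2),
              fixef = stats::coef(fitl), model = fitl)
  if (genotype_role == "fixed") {
    # noise-free designs are legitimate here; silence the perfect-fit note
    em <- suppressWarnings(
      as.data.frame(emmeans::emmeans(fitl, "entry", weights = "equal")))
    res$blues <- data.frame(entry = as.character(em$entry), blue = em$emmean,
                            se = em$SE, stringsAsFactors = FALSE)
  }
  class(res) <- "model_fit"
  res
}

#' Fit the across-trial mixed model
#'
#' The multi-location model with trial as an additional fixed effect; entry
#' BLUEs are comparable across trials through shared (check) entries. If the
#' trial/entry incidence graph is disconnected, a connectivity warning is
#' recorded in the fit metadata.
#'
#' @inheritParams fit_multi_location
#' @return A `model_fit` with an extra `connected` flag.
#' @export
fit_across_trials <- function(pheno, trait,
                              genotype_role = c("fixed", "random")) {
  genotype_role <- match.arg(genotype_role)
  if (!"trial" %in% names(pheno)) stop_("phenotype table needs a 'trial' column")
  if (length(unique(pheno$trial)) < 2)
    stop_("across-trial analysis needs >= 2 trials")
  connected <- trials_connected(pheno$trial, pheno$entry)
  if (!connected)
    warn_("trials are not connected by shared entries; BLUEs are not comparable across trials")
  pheno <- prep_factors(pheno, trait)
  pheno$trial <- factor(pheno$trial)
  blocks <- has_blocks(pheno)
  multi_loc <- nlevels(pheno$location) > 1
  rhs <- c("trial", if (multi_loc) "location", "rep_f")
  re <- c(if (blocks) "(1 | blk_id)",
          if (multi_loc) "(1 | entry:location)")
  form <- if (genotype_role == "fixed")
    stats::reformulate(c("0", "entry", rhs, re), response = ".y")
  else
    stats::reformulate(c(rhs, "(1 | entry)", re), response = ".y")
  fit <- fit_lmm(form, pheno)
  new_model_fit("across_trials", trait, genotype_role, fit, pheno,
                extra = list(connected = connected))
}

# union-find connectivity of the trial-entry bipartite graph
trials_connected <- function(trial, entry) {
  trial <- as.character(trial); entry <- as.character(entry)
  nodes <- c(unique(trial), unique(entry))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(trial)) {
    a <- find(trial[k]); b <- find(entry[k])
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(unique(trial), find, numeric(1)))) == 1
}

#' Entry-mean heritability, LSD and CV from a variance-component fit
#'
#' Computes the trait summary of a `genotype_role = "random"` fit:
#' * h2 = sigma2_G / (sigma2_G + sigma2_GL / l + sigma2_e / (l r)), with the
#'   GL term dropped for single-location fits;
#' * CV = 100 sqrt(sigma2_e) / grand mean;
#' * LSD = t(1 - alpha/2, residual df) sqrt(2 sigma2_e / (l r)).
#'
#' Residual degrees of freedom are taken as (g - 1)(l r - 1), the balanced
#' alpha-lattice value.
#'
#' @param fit A `model_fit` with `genotype_role = "random"`.
#' @param alpha Significance level for the LSD.
#' @return List with `h2`, `LSD`, `CV`, `grand_mean`, `l`, `r`.
#' @export
trait_summary <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$genotype_role != "random")
    stop_("trait_summary needs a genotype_role = 'random' fit")
  l <- fit$n_locations
  r <- fit$n_reps
  vc <- fit$varcomp
  gl <- if (fit$variant == "single_location" || is.na(vc["sigma2_GL"])) 0
        else vc["sigma2_GL"] / l
  denom <- vc["sigma2_G"] + gl + vc["sigma2_e"] / (l * r)
  h2 <- if (denom <= 0) 0 else unname(vc["sigma2_G"] / denom)
  if (fit$grand_mean == 0) stop_("grand mean is zero: CV undefined")
  cv <- unname(100 * sqrt(vc["sigma2_e"]) / abs(fit$grand_mean))
  df <- max(1, (fit$n_entries - 1) * (l * r - 1))
  lsd <- unname(stats::qt(1 - alpha / 2, df) * sqrt(2 * vc["sigma2_e"] / (l * r)))
  list(h2 = h2, LSD = lsd, CV = cv, grand_mean = fit$grand_mean, l = l, r = r)
}

#' Entry-mean heritability from variance components
#'
#' Direct evaluation of h2 = sigma2_G / (sigma2_G + sigma2_GL / l +
#' sigma2_e / (l r)).
#'
#' @param sigma2_G,sigma2_GL,sigma2_e Variance components (trait units^2).
#' @param l,r Numbers of locations and replicates.
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(0.19, 0.18, 1.41, l = 3, r = 2)
#' @export
heritability <- function(sigma2_G, sigma2_GL, sigma2_e, l, r) {
  if (any(c(sigma2_G, sigma2_GL, sigma2_e) < 0)) stop_("variance components must be >= 0")
  if (l < 1 || r < 1) stop_("l and r must be >= 1")
  denom <- sigma2_G + sigma2_GL / l + sigma2_e / (l * r)
  if (denom <= 0) return(0)
  sigma2_G / denom
}
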