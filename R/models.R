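#' Fit the per-site provenance mixed model
#'
#' REML fit of the within-site model
#' `Y_jkl = mu + B_k + P_j + (P x B)_jk + e_jkl`, with block fixed and
#' provenance and provenance-by-block random. Provenance BLUPs (conditional
#' means of the random provenance effects) and a likelihood-ratio test for
#' the provenance variance (chi-square, 1 df, from a REML refit without the
#' term) are computed alongside the variance components.
#'
#' Missing trait values are dropped listwise for the requested trait.
#'
#' @param data Trial tibble (see [simulate_met()] / [read_trial()]).
#' @param trait Name of the trait column to analyse.
#' @param site Optional site label to subset to; `data` must contain exactly
#'   one site after subsetting.
#' @param lrt Compute the likelihood-ratio test(s) by refitting without each
#'   random term (default `TRUE`; turn off to save two REML fits when only
#'   components/BLUPs are needed).
#' @return An object of class `site_fit` with components `varcomp` (tibble of
#'   variance components), `fixef`, `loglik`, `lrt`, `blups` (provenance
#'   BLUPs and BLUP-based predicted means), `n_obs`, `converged`.
#' @seealso [fit_met_model()], [variance_proportions()], [anova_fixed()]
#' @export
fit_site_model <- function(data, trait, site = NULL, lrt = TRUE) {
  d <- check_fit_input(data, trait)
  if (!is.null(site)) d <- d[d$site == site, ]
  if (length(unique(d$site)) != 1) {
    abort("fit_site_model needs data from exactly one site (use `site =`)",
          class = "metsel_design_error")
  }
  d <- d[!is.na(d$.y), ]
  if (length(unique(d$provenance)) < 2 || length(unique(d$block)) < 2) {
    abort("singular design: need >= 2 provenances and >= 2 blocks",
          class = "metsel_design_error")
  }
  d$provenance <- factor(d$provenance)
  d$block <- factor(d$block)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(.y ~ block + (1 | provenance) + (1 | provenance:block),
                    data = d, REML = TRUE, control = ctrl)
  red <- if (lrt) {
    lme4::lmer(.y ~ block + (1 | provenance:block),
               data = d, REML = TRUE, control = ctrl)
  }
  vc <- varcomp_lookup(fit)
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)$provenance
  mu_adj <- unname(fe[1] + mean(c(0, fe[grepl("^block", names(fe))])))
  blups <- tibble::tibble(
    provenance = rownames(re),
    blup = re[["(Intercept)"]],
    pred_mean = mu_adj + re[["(Intercept)"]]
  )
  structure(
    list(
      trait = trait,
      site = d$site[1],
      varcomp = tibble::tibble(
        component = c("provenance", "provenance_x_block", "residual"),
        variance = c(vc["provenance"], vc["provenance:block"], vc["Residual"])
      ),
      fixef = tibble::enframe(fe, name = "term", value = "estimate"),
      adjusted_mean = mu_adj,
      loglik = as.numeric(logLik(fit)),
      loglik_reduced = if (lrt) as.numeric(logLik(red)) else NA_real_,
      lrt = if (lrt) lrt_random_effect(logLik(fit), logLik(red), df = 1,
                                       term = "provenance"),
      blups = blups,
      n_obs = nrow(d),
      converged = length(fit@optinfo$conv$lme4$messages) == 0,
      frame = d[c("provenance", "block", ".y")]
    ),
    class = "site_fit"
  )
}

#' Fit the across-site mixed model with provenance-by-site interaction
#'
#' REML fit of `Y_ijkl = mu + S_i + B_k(i) + P_j + (S x P)_ij + e_ijkl`,
#' with site and block-within-site fixed and provenance and the
#' provenance-by-site interaction random. Beyond variance components and
#' provenance BLUPs, the fit carries the interaction BLUP matrix `theta`
#' (one row per provenance in the analysis set, one column per site;
#' provenance-site pairs absent from the data get the BLUP of an unobserved
#' effect, 0) — the input to the WAASB stability statistic. Likelihood-ratio
#' tests are computed for both random terms.
#'
#' @param data Trial tibble spanning >= 2 sites.
#' @param trait Trait column to analyse.
#' @param analysis_set `"common"` (default: provenances present at every
#'   site), `"all"`, or a character vector of provenance labels.
#' @inheritParams fit_site_model
#' @return An object of class `met_fit`; as [fit_site_model()] plus `theta`
#'   and a two-row `lrt` table (`provenance`, `provenance_x_site`).
#' @export
fit_met_model <- function(data, trait, analysis_set = "common", lrt = TRUE) {
  d <- check_fit_input(data, trait)
  sites <- unique(d$site)
  if (length(sites) < 2) {
    abort("across-site analysis needs >= 2 sites",
          class = "metsel_design_error")
  }
  set <- resolve_analysis_set(d, analysis_set)
  d <- d[d$provenance %in% set & !is.na(d$.y), ]
  n_sites_per_prov <- tapply(d$site, d$provenance, function(s) length(unique(s)))
  if (any(n_sites_per_prov < 2)) {
    warn(sprintf("%d provenance(s) observed at a single site; their interaction BLUPs are heavily shrunken",
                 sum(n_sites_per_prov < 2)))
  }
  d$provenance <- factor(d$provenance)
  d$site <- factor(d$site, levels = sites)
  d$block <- factor(d$block)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fit <- lme4::lmer(.y ~ site + site:block + (1 | provenance) +
                      (1 | provenance:site),
                    data = d, REML = TRUE, control = ctrl)
  red_g <- if (lrt) {
    lme4::lmer(.y ~ site + site:block + (1 | provenance:site),
               data = d, REML = TRUE, control = ctrl)
  }
  red_ge <- if (lrt) {
    lme4::lmer(.y ~ site + site:block + (1 | provenance),
               data = d, REML = TRUE, control = ctrl)
  }
  vc <- varcomp_lookup(fit)
  fe <- lme4::fixef(fit)
  re <- lme4::ranef(fit)
  mu_adj <- unname(fe[1] + mean(c(0, fe[grepl("^site", names(fe))])))
  blups <- tibble::tibble(
    provenance = rownames(re$provenance),
    blup = re$provenance[["(Intercept)"]],
    pred_mean = mu_adj + re$provenance[["(Intercept)"]]
  )
  theta <- matrix(0, length(levels(d$provenance)), length(sites),
                  dimnames = list(levels(d$provenance), sites))
  ge <- re$`provenance:site`
  parts <- strsplit(rownames(ge), ":", fixed = TRUE)
  idx <- cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
  theta[idx] <- ge[["(Intercept)"]]
  lrt_tbl <- if (lrt) {
    dplyr::bind_rows(
      lrt_random_effect(logLik(fit), logLik(red_g), df = 1,
                        term = "provenance"),
      lrt_random_effect(logLik(fit), logLik(red_ge), df = 1,
                        term = "provenance_x_site")
    )
  }
  structure(
    list(
      trait = trait,
      sites = sites,
      analysis_set = levels(d$provenance),
      varcomp = tibble::tibble(
        component = c("provenance", "provenance_x_site", "residual"),
        variance = c(vc["provenance"], vc["provenance:site"], vc["Residual"])
      ),
      fixef = tibble::enframe(fe, name = "term", value = "estimate"),
      adjusted_mean = mu_adj,
      loglik = as.numeric(logLik(fit)),
      loglik_reduced = if (lrt) {
        c(provenance = as.numeric(logLik(red_g)),
          provenance_x_site = as.numeric(logLik(red_ge)))
      },
      lrt = lrt_tbl,
      blups = blups,
      theta = theta,
      n_obs = nrow(d),
      converged = length(fit@optinfo$conv$lme4$messages) == 0,
      frame = d[c("provenance", "site", "block", ".y")]
    ),
    class = "met_fit"
  )
}

check_fit_input <- function(data, trait) {
  if (!trait %in% names(data)) {
    abort(sprintf("trait '%s' not found in data", trait),
          class = "metsel_param_error")
  }
  d <- tibble::as_tibble(data)
  d$.y <- d[[trait]]
  d
}

resolve_analysis_set <- function(d, analysis_set) {
  if (identical(analysis_set, "common")) {
    set <- common_provenances(d)
    if (!length(set)) {
      abort("no provenance is present at every site",
            class = "metsel_design_error")
    }
    set
  } else if (identical(analysis_set, "all")) {
    sort(unique(d$provenance))
  } else {
    set <- intersect(as.character(analysis_set), unique(d$provenance))
    if (!length(set)) {
      abort("analysis_set matches no provenance in the data",
            class = "metsel_param_error")
    }
    set
  }
}

varcomp_lookup <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  setNames(vc$vcov, vc$grp)
}

#' Likelihood-ratio test for a single random effect
#'
#' `statistic = max(0, 2 * (full - reduced))`, referred to a chi-square
#' distribution with `df` degrees of freedom (the conventional reported
#' test; no boundary mixture correction).
#'
#' @param full,reduced REML log-likelihoods (numbers or `logLik` objects) of
#'   the model with and without the term.
#' @param df Degrees of freedom (>= 1).
#' @param term Label for the tested term.
#' @return One-row tibble: `term`, `statistic`, `df`, `p_value`, `signif`.
#' @export
lrt_random_effect <- function(full, reduced, df = 1, term = "random effect") {
  full <- as.numeric(full)
  reduced <- as.numeric(reduced)
  if (df < 1 || df != round(df)) {
    abort("df must be a positive integer", class = "metsel_param_error")
  }
  if (full < reduced - 1e-6 * max(1, abs(reduced))) {
    warn("full-model log-likelihood is below the reduced model's; statistic clamped at 0")
  }
  statistic <- max(0, 2 * (full - reduced))
  p <- pchisq(statistic, df = df, lower.tail = FALSE)
  tibble::tibble(term = term, statistic = statistic, df = as.integer(df),
                 p_value = p, signif = p_stars(p))
}

#' Variance-component proportions of a fitted model
#'
#' Each reported random component divided by their sum. For a per-site fit
#' the total is `V_p + V_r` (the provenance-by-block component is excluded
#' from the denominator, matching the conventional per-site summary); for an
#' across-site fit it is `V_p + V_ge + V_r`. Also accepts a named numeric
#' vector of components directly.
#'
#' @param fit A `site_fit`, `met_fit`, or named numeric vector of variance
#'   components.
#' @return Tibble `component`, `variance`, `proportion` (proportions sum
#'   to 1).
#' @export
variance_proportions <- function(fit) UseMethod("variance_proportions")

#' @export
variance_proportions.site_fit <- function(fit) {
  vc <- fit$varcomp[fit$varcomp$component %in% c("provenance", "residual"), ]
  variance_proportions(setNames(vc$variance, vc$component))
}

#' @export
variance_proportions.met_fit <- function(fit) {
  variance_proportions(setNames(fit$varcomp$variance, fit$varcomp$component))
}

#' @export
variance_proportions.numeric <- function(fit) {
  if (sum(fit) <= 0) {
    abort("all variance components are zero: proportions undefined",
          class = "metsel_param_error")
  }
  tibble::tibble(
    component = names(fit) %||% paste0("component_", seq_along(fit)),
    variance = unname(fit),
    proportion = unname(fit) / sum(fit)
  )
}

#' Fixed-effect mean squares and F tests
#'
#' Mean squares for each fixed term from the sequential least-squares
#' decomposition of the observations (block within a site fit; site and
#' block-within-site within an across-site fit), tested against the REML
#' residual variance of the mixed model with observation-level residual
#' degrees of freedom.
#'
#' @param fit A `site_fit` or `met_fit`.
#' @return Tibble `term`, `df`, `mean_sq`, `statistic`, `df_resid`,
#'   `p_value`, `signif`.
#' @export
anova_fixed <- function(fit) UseMethod("anova_fixed")

#' @export
anova_fixed.site_fit <- function(fit) {
  an <- anova(stats::lm(.y ~ block, data = fit$frame))
  v_r <- fit$varcomp$variance[fit$varcomp$component == "residual"]
  seq_ms_table(an, c(block = "block"), v_r, fit$n_obs)
}

#' @export
anova_fixed.met_fit <- function(fit) {
  an <- anova(stats::lm(.y ~ site + site:block, data = fit$frame))
  v_r <- fit$varcomp$variance[fit$varcomp$component == "residual"]
  seq_ms_table(an, c(site = "site", site_x_block = "site:block"),
               v_r, fit$n_obs)
}

seq_ms_table <- function(an, terms, v_r, n_obs) {
  df_fixed <- sum(an$Df[rownames(an) %in% terms]) + 1
  df2 <- n_obs - df_fixed
  purrr::imap_dfr(terms, function(row, label) {
    ms <- an[row, "Mean Sq"]
    f <- if (v_r > 0) ms / v_r else Inf
    p <- pf(f, an[row, "Df"], df2, lower.tail = FALSE)
    tibble::tibble(term = label, df = an[row, "Df"], mean_sq = ms,
                   statistic = f, df_resid = df2, p_value = p,
                   signif = p_stars(p))
  })
}

#' BLUP-based predicted provenance means
#'
#' Adjusted trial mean (fixed intercept averaged over fixed-effect levels)
#' plus the provenance BLUP; the shrunken genotype means that feed the
#' MGIDI and the performance half of WAASBY.
#'
#' @param fit A `site_fit` or `met_fit`.
#' @return Tibble `provenance`, `pred_mean`.
#' @export
predicted_means <- function(fit) {
  stopifnot(inherits(fit, c("site_fit", "met_fit")))
  fit$blups[c("provenance", "pred_mean")]
}

#' Interaction BLUP matrix of an across-site fit
#'
#' @param fit A `met_fit`.
#' @return Numeric matrix, provenances by sites; unobserved pairs are 0.
#' @export
interaction_blups <- function(fit) {
  stopifnot(inherits(fit, "met_fit"))
  fit$theta
}

#' @export
print.site_fit <- function(x, ...) {
  cat(sprintf("<site_fit> trait %s at %s (n = %d)\n", x$trait, x$site, x$n_obs))
  print(x$varcomp)
  invisible(x)
}

#' @export
print.met_fit <- function(x, ...) {
  cat(sprintf("<met_fit> trait %s across %d sites (n = %d, %d provenances)\n",
              x$trait, length(x$sites), x$n_obs, length(x$analysis_set)))
  print(x$varcomp)
  invisible(x)
}

#' @export
tidy.site_fit <- function(x, effects = c("ran_pars", "ran_vals", "fixed"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    ran_pars = dplyr::mutate(
      variance_proportions(x),
      trait = x$trait, site = x$site, .before = 1),
    ran_vals = dplyr::mutate(x$blups, trait = x$trait, site = x$site,
                             .before = 1),
    fixed = x$fixef
  )
}

#' @export
tidy.met_fit <- function(x, effects = c("ran_pars", "ran_vals", "fixed"), ...) {
  effects <- match.arg(effects)
  switch(effects,
    ran_pars = dplyr::mutate(variance_proportions(x), trait = x$trait,
                             .before = 1),
    ran_vals = dplyr::mutate(x$blups, trait = x$trait, .before = 1),
    fixed = x$fixef
  )
}

#' @export
glance.site_fit <- function(x, ...) {
  vc <- setNames(x$varcomp$variance, x$varcomp$component)
  tibble::tibble(
    site = x$site, trait = x$trait, n_obs = x$n_obs,
    v_p = vc[["provenance"]], v_pb = vc[["provenance_x_block"]],
    v_r = vc[["residual"]],
    logLik = x$loglik,
    lrt_statistic = x$lrt$statistic, lrt_p = x$lrt$p_value,
    converged = x$converged
  )
}

#' @export
glance.met_fit <- function(x, ...) {
  vc <- setNames(x$varcomp$variance, x$varcomp$component)
  tibble::tibble(
    trait = x$trait, n_obs = x$n_obs, n_provenances = length(x$analysis_set),
    v_p = vc[["provenance"]], v_ge = vc[["provenance_x_site"]],
    v_r = vc[["residual"]],
    logLik = x$loglik,
    lrt_g = x$lrt$statistic[1], lrt_g_p = x$lrt$p_value[1],
    lrt_ge = x$lrt$statistic[2], lrt_ge_p = x$lrt$p_value[2],
    converged = x$converged
  )
}
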