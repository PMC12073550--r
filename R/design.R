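#' Define a multi-environment provenance trial design
#'
#' A trial design records the experimental layout of a set of common-garden
#' experiments: which provenances are planted at which site, the number of
#' randomized complete blocks per site, and the number of trees per
#' provenance plot within a block.
#'
#' @param site_ids Character vector of site labels.
#' @param provenance_sets Named list (one element per site, names matching
#'   `site_ids`) of character vectors of provenance labels planted at that
#'   site. Sets may differ between sites; the intersection across all sites
#'   is the "common set" used for across-site analyses.
#' @param n_blocks Number of blocks per site (>= 2).
#' @param n_trees_per_plot Number of trees per provenance plot within a
#'   block (>= 1).
#' @param traits Tibble with columns `trait` (label) and `higher_better`
#'   (logical orientation flag: `TRUE` when larger values are desirable).
#'
#' @return An object of class `trial_design`.
#' @seealso [default_design()] for the three-site Douglas fir layout,
#'   [simulate_met()] to draw data from a design.
#' @export
trial_design <- function(site_ids, provenance_sets, n_blocks = 3,
                         n_trees_per_plot = 25, traits = default_traits()) {
  site_ids <- as.character(site_ids)
  if (length(site_ids) < 1 || anyDuplicated(site_ids)) {
    abort("site_ids must be a non-empty set of unique labels",
          class = "metsel_design_error")
  }
  if (!is.list(provenance_sets) || !setequal(names(provenance_sets), site_ids)) {
    abort("provenance_sets must be a named list with one element per site",
          class = "metsel_design_error")
  }
  provenance_sets <- provenance_sets[site_ids]
  if (any(vapply(provenance_sets, length, 1L) == 0)) {
    abort("every site must have a non-empty provenance set",
          class = "metsel_design_error")
  }
  if (n_blocks < 2) {
    abort("n_blocks must be >= 2", class = "metsel_design_error")
  }
  if (n_trees_per_plot < 1) {
    abort("n_trees_per_plot must be >= 1", class = "metsel_design_error")
  }
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("trait", "higher_better") %in% names(traits)))
  structure(
    list(
      site_ids = site_ids,
      provenance_sets = lapply(provenance_sets, as.character),
      n_blocks = as.integer(n_blocks),
      n_trees_per_plot = as.integer(n_trees_per_plot),
      traits = traits
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design>\n")
  cat("  sites:", paste(x$site_ids, collapse = ", "), "\n")
  cat("  provenances per site:",
      paste(vapply(x$provenance_sets, length, 1L), collapse = "/"),
      sprintf("(%d common)", length(common_provenances(x))), "\n")
  cat("  blocks:", x$n_blocks, " trees/plot:", x$n_trees_per_plot, "\n")
  cat("  traits:", paste(x$traits$trait, collapse = ", "), "\n")
  invisible(x)
}

#' Provenances present at every site
#'
#' @param x A `trial_design` or a trial data frame with `site` and
#'   `provenance` columns.
#' @return Character vector of provenance labels present at all sites.
#' @export
common_provenances <- function(x) {
  sets <- if (inherits(x, "trial_design")) {
    x$provenance_sets
  } else {
    split(x$provenance, x$site)
  }
  sort(Reduce(intersect, lapply(sets, unique)))
}

#' Default trait table: DBH, TH, PH, all oriented higher-is-better
#'
#' Diameter at breast height (cm), total height (m) and pruned height (m;
#' height of the lowest green branch, a natural-pruning/wood-quality proxy).
#' @return Tibble with columns `trait`, `higher_better`, `unit`.
#' @export
default_traits <- function() {
  tibble::tibble(
    trait = c("DBH", "TH", "PH"),
    higher_better = TRUE,
    unit = c("cm", "m", "m")
  )
}

#' The default three-site Douglas fir provenance-trial layout
#'
#' Three common-garden sites with 55, 49 and 48 of a total of 61 provenances,
#' 38 of them planted at all three sites; three randomized complete blocks
#' per site and 25 trees (a 5 x 5 plot) per provenance per block.
#'
#' @return A `trial_design`.
#' @export
default_design <- function() {
  prov <- sprintf("P%02d", 1:61)
  common <- prov[1:38]
  trial_design(
    site_ids = c("Alesd", "Faget", "Pades"),
    provenance_sets = list(
      # 38 common + site-specific extras: 55 / 49 / 48 entries
      Alesd = c(common, prov[39:55]),
      Faget = c(common, prov[39:46], prov[56:58]),
      Pades = c(common, prov[47:53], prov[59:61])
    ),
    n_blocks = 3,
    n_trees_per_plot = 25,
    traits = default_traits()
  )
}

#' Variance parameters of the generative trial model
#'
#' Holds, per trait, the grand mean and the variance components of the
#' across-site mixed model (provenance, provenance-by-site, provenance-by-
#' block, residual), plus fixed site and block offsets. These drive
#' [simulate_met()]: for tree `l` of provenance `j` in block `k` of site `i`,
#' `Y = mu + S_i + P_j + B_k + (SxP)_ij + (PxB)_jk + e` with the random
#' terms drawn as independent zero-mean Gaussians at the stated variances.
#'
#' @param traits Tibble with columns `trait`, `mu`, `v_p`, `v_ge`, `v_pb`,
#'   `v_r` (trait units for `mu`; squared trait units for variances, all
#'   >= 0).
#' @param site_effects Tibble `site`, `trait`, `effect` of fixed site
#'   offsets (trait units). Defaults to 0 for every combination.
#' @param block_effects Tibble `block`, `trait`, `effect` of fixed block
#'   offsets, applied identically at each site. Defaults to 0.
#' @param prov_cor Optional trait-by-trait correlation matrix for the
#'   provenance effects, used to induce cross-trait correlation at the
#'   genotype level (traits are otherwise generated independently).
#' @param survival_rate Probability in (0, 1] that a planted tree is alive
#'   at measurement; used by [apply_mortality()] via the pipeline.
#'
#' @return An object of class `variance_params`.
#' @export
variance_params <- function(traits, site_effects = NULL, block_effects = NULL,
                            prov_cor = NULL, survival_rate = 1) {
  traits <- tibble::as_tibble(traits)
  need <- c("trait", "mu", "v_p", "v_ge", "v_pb", "v_r")
  if (!all(need %in% names(traits))) {
    abort(paste("traits must have columns", paste(need, collapse = ", ")),
          class = "metsel_param_error")
  }
  vmat <- as.matrix(traits[c("v_p", "v_ge", "v_pb", "v_r")])
  if (any(vmat < 0)) {
    abort("variance components must be non-negative",
          class = "metsel_param_error")
  }
  if (survival_rate <= 0 || survival_rate > 1) {
    abort("survival_rate must be in (0, 1]", class = "metsel_param_error")
  }
  if (!is.null(prov_cor)) {
    prov_cor <- as.matrix(prov_cor)
    if (nrow(prov_cor) != nrow(traits) || any(abs(diag(prov_cor) - 1) > 1e-8)) {
      abort("prov_cor must be a trait-by-trait correlation matrix",
            class = "metsel_param_error")
    }
  }
  structure(
    list(
      traits = traits,
      site_effects = site_effects,
      block_effects = block_effects,
      prov_cor = prov_cor,
      survival_rate = survival_rate
    ),
    class = "variance_params"
  )
}

#' @export
print.variance_params <- function(x, ...) {
  cat("<variance_params>\n")
  print(x$traits)
  invisible(x)
}

#' Default generative parameters for the Douglas fir scenario
#'
#' Grand means and fixed site offsets reproduce the published per-site trait
#' means; provenance and residual variances are the per-site REML components
#' averaged across sites, and the provenance-by-site variances are the
#' across-site REML estimates, so that simulated trait standard deviations
#' match the published overall means +/- SD. Block offsets default to zero
#' and the provenance-by-block variance to zero (the across-site model omits
#' that term).
#'
#' @param design A `trial_design`, used only for site labels.
#' @return A `variance_params`.
#' @export
default_params <- function(design = default_design()) {
  traits <- tibble::tibble(
    trait = c("DBH", "TH", "PH"),
    mu = c(33.03, 29.50, 17.47),
    v_p = c(mean(c(7.23, 2.87, 1.93)),
            mean(c(3.36, 2.009, 1.59)),
            mean(c(0.98, 1.73, 0.38))),
    v_ge = c(3.91, 1.75, 0.92),
    v_pb = 0,
    v_r = c(mean(c(60.77, 56.16, 50.89)),
            mean(c(19.68, 24.73, 15.29)),
            mean(c(7.34, 12.05, 6.74)))
  )
  site_means <- tibble::tribble(
    ~site, ~trait, ~mean,
    "Alesd", "DBH", 36.05, "Alesd", "TH", 30.36, "Alesd", "PH", 17.48,
    "Faget", "DBH", 28.82, "Faget", "TH", 29.61, "Faget", "PH", 17.32,
    "Pades", "DBH", 34.71, "Pades", "TH", 28.77, "Pades", "PH", 17.68
  )
  site_effects <- site_means |>
    dplyr::left_join(traits[c("trait", "mu")], by = "trait") |>
    dplyr::mutate(effect = .data$mean - .data$mu) |>
    dplyr::select("site", "trait", "effect")
  # map generic site labels if the design renamed them positionally
  if (length(design$site_ids) == 3 &&
      !setequal(design$site_ids, unique(site_effects$site))) {
    lut <- setNames(design$site_ids, c("Alesd", "Faget", "Pades"))
    site_effects$site <- unname(lut[site_effects$site])
  }
  variance_params(traits, site_effects = site_effects)
}
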