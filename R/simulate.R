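#' Simulate a multi-environment provenance trial
#'
#' Draws individual-tree trait values from the across-site mixed model: for
#' tree `l` of provenance `j` in block `k` at site `i`,
#' `Y_ijkl = mu + S_i + P_j + B_k(i) + (SxP)_ij + (PxB)_jk(i) + e_ijkl`,
#' with `P_j ~ N(0, v_p)`, `(SxP)_ij ~ N(0, v_ge)`, `(PxB)_jk ~ N(0, v_pb)`
#' and `e ~ N(0, v_r)`. The same provenance effect draw is reused across
#' sites, so provenances planted at several sites (the common set) carry the
#' same genetic value everywhere — this is what makes genotype-by-site
#' interaction identifiable downstream.
#'
#' The drawn provenance and interaction effects (the simulation "truth") are
#' attached as `attr(, "truth")`, a list with `provenance` and `interaction`
#' tibbles, so parameter-recovery and shrinkage tests can compare estimates
#' against them.
#'
#' @param design A [trial_design()].
#' @param params A [variance_params()] with one row per design trait.
#' @param seed Integer master seed; per-stage substreams (provenance,
#'   interaction, block-plot, residual draws) are derived from it
#'   deterministically, so the output is bit-reproducible.
#'
#' @return A tibble with columns `site`, `provenance`, `block`, `tree`, and
#'   one numeric column per trait; one row per planted tree.
#' @export
simulate_met <- function(design, params, seed) {
  if (!inherits(design, "trial_design")) {
    abort("design must be a trial_design", class = "metsel_design_error")
  }
  if (!inherits(params, "variance_params")) {
    abort("params must be a variance_params", class = "metsel_param_error")
  }
  if (missing(seed) || !is.numeric(seed)) {
    abort("an explicit integer seed is required", class = "metsel_param_error")
  }
  tr <- params$traits
  missing_tr <- setdiff(design$traits$trait, tr$trait)
  if (length(missing_tr)) {
    abort(paste("params missing traits:", paste(missing_tr, collapse = ", ")),
          class = "metsel_param_error")
  }
  tr <- tr[match(design$traits$trait, tr$trait), ]
  traits <- tr$trait
  n_tr <- length(traits)

  prov_all <- sort(unique(unlist(design$provenance_sets)))
  sp_pairs <- dplyr::bind_rows(lapply(design$site_ids, function(s) {
    tibble::tibble(site = s, provenance = design$provenance_sets[[s]])
  }))

  sub_seed <- function(k) as.integer((as.numeric(seed) * 8 + k) %% 2147483647)

  # provenance effects: one draw per provenance label, shared across sites;
  # optionally correlated across traits at the genotype level
  set.seed(sub_seed(1))
  Z <- matrix(rnorm(length(prov_all) * n_tr), length(prov_all), n_tr)
  if (!is.null(params$prov_cor)) {
    Z <- Z %*% chol(params$prov_cor)
  }
  P <- sweep(Z, 2, sqrt(tr$v_p), `*`)
  dimnames(P) <- list(prov_all, traits)

  set.seed(sub_seed(2))
  GE <- matrix(rnorm(nrow(sp_pairs) * n_tr), nrow(sp_pairs), n_tr) %*%
    diag(sqrt(tr$v_ge), n_tr)
  colnames(GE) <- traits

  blocks <- sprintf("B%d", seq_len(design$n_blocks))
  plot_grid <- tidyr::expand_grid(sp_pairs, block = blocks)
  set.seed(sub_seed(3))
  PB <- matrix(rnorm(nrow(plot_grid) * n_tr), nrow(plot_grid), n_tr) %*%
    diag(sqrt(tr$v_pb), n_tr)

  dat <- tidyr::expand_grid(
    plot_grid |> dplyr::mutate(.plot = dplyr::row_number()),
    tree = seq_len(design$n_trees_per_plot)
  )
  dat$.pair <- match(paste(dat$site, dat$provenance),
                     paste(sp_pairs$site, sp_pairs$provenance))

  site_eff <- fixed_effect_lookup(params$site_effects, "site",
                                  design$site_ids, traits)
  block_eff <- fixed_effect_lookup(params$block_effects, "block",
                                   blocks, traits)

  set.seed(sub_seed(4))
  for (j in seq_len(n_tr)) {
    e <- rnorm(nrow(dat), 0, sqrt(tr$v_r[j]))
    dat[[traits[j]]] <- unname(
      tr$mu[j] +
        site_eff[dat$site, j] +
        block_eff[dat$block, j] +
        P[dat$provenance, j] +
        GE[dat$.pair, j] +
        PB[dat$.plot, j] +
        e
    )
  }
  truth <- list(
    provenance = tibble::as_tibble(P, rownames = "provenance") |>
      tidyr::pivot_longer(-"provenance", names_to = "trait",
                          values_to = "effect"),
    interaction = dplyr::bind_cols(sp_pairs, tibble::as_tibble(GE)) |>
      tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                          values_to = "effect")
  )
  out <- dat |>
    dplyr::select("site", "provenance", "block", "tree",
                  dplyr::all_of(traits)) |>
    dplyr::arrange(.data$site, .data$provenance, .data$block, .data$tree)
  attr(out, "truth") <- truth
  attr(out, "design") <- design
  out
}

# named matrix (levels x traits) of fixed offsets, default all zero
fixed_effect_lookup <- function(tbl, key, levels, traits) {
  m <- matrix(0, length(levels), length(traits),
              dimnames = list(levels, traits))
  if (!is.null(tbl)) {
    tbl <- tibble::as_tibble(tbl)
    stopifnot(all(c(key, "trait", "effect") %in% names(tbl)))
    keep <- tbl[[key]] %in% levels & tbl$trait %in% traits
    tbl <- tbl[keep, ]
    m[cbind(tbl[[key]], tbl$trait)] <- tbl$effect
  }
  m
}

#' Thin a simulated trial by random tree mortality
#'
#' Each tree is retained independently with probability `survival_rate`,
#' producing the unbalanced plot counts typical of decades-old field trials.
#' A plot (site x provenance x block) that loses all its trees is redrawn a
#' few times; if it stays empty, the provenance is dropped from that site
#' entirely (with a message), so every provenance that remains at a site has
#' at least one tree in each of its plots.
#'
#' @param data Trial tibble from [simulate_met()] or [read_trial()].
#' @param survival_rate Retention probability in (0, 1].
#' @param seed Integer seed; the retained set is reproducible.
#' @return Trial tibble with a subset of rows; truth attributes preserved.
#' @export
apply_mortality <- function(data, survival_rate, seed) {
  if (survival_rate <= 0 || survival_rate > 1) {
    abort("survival_rate must be in (0, 1]", class = "metsel_param_error")
  }
  if (survival_rate == 1) {
    return(data)
  }
  set.seed(as.integer(seed %% 2147483647))
  keep <- rbinom(nrow(data), 1, survival_rate) == 1
  plot_id <- paste(data$site, data$provenance, data$block, sep = "\r")
  for (i in 1:10) {
    empty <- setdiff(unique(plot_id), unique(plot_id[keep]))
    if (!length(empty)) break
    redo <- plot_id %in% empty
    keep[redo] <- rbinom(sum(redo), 1, survival_rate) == 1
  }
  empty <- setdiff(unique(plot_id), unique(plot_id[keep]))
  if (length(empty)) {
    bad <- unique(data[plot_id %in% empty, c("site", "provenance")])
    inform(sprintf(
      "dropping %d provenance-site combination(s) with an empty plot: %s",
      nrow(bad), paste(bad$provenance, "@", bad$site, collapse = ", ")))
    drop <- paste(data$site, data$provenance) %in% paste(bad$site, bad$provenance)
    keep <- keep & !drop
  }
  out <- data[keep, ]
  attr(out, "truth") <- attr(data, "truth")
  attr(out, "design") <- attr(data, "design")
  out
}
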