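#' Rescale genotype trait means to a 0-100 desirability scale
#'
#' First step of the genotype-ideotype distance construction. For a
#' higher-is-better trait, `r = (x - min) / (max - min) * 100`; for a
#' lower-is-better trait the map is reflected, so 100 always marks the
#' desirable extreme. Rescaling absorbs units, which makes the downstream
#' index invariant to positive affine recoding of any raw trait.
#'
#' @param means Data frame with a `genotype` column (or genotype labels in
#'   the first column) and one numeric column per trait.
#' @param higher_better Named logical vector, one entry per trait; unnamed
#'   `TRUE`/`FALSE` of length 1 is recycled. Default: all higher-is-better.
#' @return Tibble of the same shape, every trait cell in \[0, 100\].
#' @export
rescale_traits <- function(means, higher_better = TRUE) {
  m <- as_genotype_table(means)
  traits <- setdiff(names(m), "genotype")
  hb <- resolve_orientation(higher_better, traits)
  for (tr in traits) {
    x <- m[[tr]]
    if (max(x) == min(x)) {
      abort(sprintf("trait '%s' is constant across genotypes; cannot rescale",
                    tr),
            class = "metsel_degenerate_error")
    }
    m[[tr]] <- rescale_0_100(x, larger_better = hb[[tr]], what = tr)
  }
  m
}

as_genotype_table <- function(means) {
  m <- tibble::as_tibble(means)
  if (!"genotype" %in% names(m)) {
    if (is.numeric(m[[1]])) {
      abort("means must have a 'genotype' label column first",
            class = "metsel_param_error")
    }
    names(m)[1] <- "genotype"
  }
  m <- dplyr::relocate(m, "genotype")
  if (anyDuplicated(m$genotype)) {
    abort("duplicate genotype labels", class = "metsel_param_error")
  }
  if (any(!vapply(m[-1], is.numeric, TRUE))) {
    abort("all trait columns must be numeric", class = "metsel_param_error")
  }
  if (anyNA(m)) {
    abort("genotype x trait means must have no missing cells",
          class = "metsel_param_error")
  }
  m
}

resolve_orientation <- function(higher_better, traits) {
  if (length(higher_better) == 1 && is.null(names(higher_better))) {
    higher_better <- setNames(rep(higher_better, length(traits)), traits)
  }
  if (!all(traits %in% names(higher_better))) {
    abort("higher_better must name every trait",
          class = "metsel_param_error")
  }
  higher_better[traits]
}

#' Factor analysis of rescaled genotype trait means
#'
#' Principal-axis machinery behind the MGIDI and MTSI: eigendecomposition of
#' the trait correlation matrix, retention of factors with eigenvalue >= 1
#' (at least one), loadings scaled by the root eigenvalues, varimax rotation
#' (Kaiser-normalized) with a column sign convention making each factor's
#' dominant loading positive, and factor scores by the regression method
#' `Z R^-1 L`. The all-100 ideotype row is pushed through the identical
#' standardization and scoring transform to give the ideotype's factor
#' scores.
#'
#' A numerically singular correlation matrix is ridge-regularized
#' (1e-8 on the diagonal) with a warning.
#'
#' @param rescaled Output of [rescale_traits()] (>= 3 genotypes, >= 2
#'   traits).
#' @return Object of class `factor_model`: eigenvalues, rotated `loadings`,
#'   `communalities`, `explained` variance proportions, genotype `scores`,
#'   `ideotype_scores`, and the standardization used.
#' @export
factor_analysis <- function(rescaled) {
  m <- as_genotype_table(rescaled)
  X <- as.matrix(m[-1])
  rownames(X) <- m$genotype
  if (nrow(X) < 3) {
    abort("factor analysis needs >= 3 genotypes",
          class = "metsel_design_error")
  }
  if (ncol(X) < 1) {
    abort("factor analysis needs >= 1 trait", class = "metsel_design_error")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    abort(sprintf("trait '%s' is constant; cannot standardize",
                  colnames(X)[scl == 0][1]),
          class = "metsel_degenerate_error")
  }
  R <- cor(X)
  ev <- eigen(R, symmetric = TRUE)
  nf <- max(1L, sum(ev$values >= 1))
  L <- ev$vectors[, seq_len(nf), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(nf)], 0)), nf)
  if (nf > 1) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-5)
    L <- L %*% rot$rotmat
  }
  # sign convention: dominant loading of each factor positive
  flip <- apply(L, 2, function(col) sign(col[which.max(abs(col))]))
  L <- sweep(L, 2, ifelse(flip == 0, 1, flip), `*`)
  dimnames(L) <- list(colnames(X), paste0("FA", seq_len(nf)))

  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(Rinv) || min(ev$values) < 1e-10) {
    warn("correlation matrix numerically singular; ridge-regularizing (1e-8)")
    Rinv <- solve(R + diag(1e-8, ncol(R)))
  }
  W <- Rinv %*% L
  Z <- scale(X, center = ctr, scale = scl)
  scores <- Z %*% W
  z_ideo <- (rep(100, ncol(X)) - ctr) / scl
  ideotype_scores <- drop(z_ideo %*% W)

  structure(
    list(
      rescaled = X,
      cor = R,
      eigenvalues = ev$values,
      n_retained = nf,
      loadings = L,
      communalities = rowSums(L^2),
      explained = colSums(L^2) / ncol(X),
      scores = scores,
      ideotype_scores = ideotype_scores,
      center = ctr, scale = scl
    ),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d traits, %d genotypes, %d factor(s) retained (%.1f%% variance)\n",
              ncol(x$rescaled), nrow(x$rescaled), x$n_retained,
              100 * sum(x$explained)))
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
tidy.factor_model <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "trait") |>
    dplyr::mutate(communality = x$communalities)
}

#' @export
glance.factor_model <- function(x, ...) {
  tibble::tibble(
    n_genotypes = nrow(x$rescaled), n_traits = ncol(x$rescaled),
    n_retained = x$n_retained,
    explained_total = sum(x$explained)
  )
}

#' Genotype-ideotype distance index (MGIDI)
#'
#' Euclidean distance, in retained-factor-score space, between each genotype
#' and the all-100 ideotype: `MGIDI_i = sqrt(sum_j (y_ij - y_j)^2)`. Lower
#' is better; a genotype whose rescaled profile equals the ideotype scores 0.
#'
#' @param model A [factor_analysis()] fit.
#' @return Tibble `genotype`, `mgidi`, `rank` (ascending).
#' @export
compute_mgidi <- function(model) {
  stopifnot(inherits(model, "factor_model"))
  ideotype_distance(model, index_name = "mgidi")
}

ideotype_distance <- function(model, index_name) {
  dev <- sweep(model$scores, 2, model$ideotype_scores, `-`)
  d <- sqrt(rowSums(dev^2))
  out <- tibble::tibble(genotype = rownames(model$scores), !!index_name := d)
  out$rank <- rank(d, ties.method = "min")
  dplyr::arrange(out, .data$rank)
}

#' Select genotypes at a stated intensity
#'
#' The selected-set size is `round(n * intensity / 100)` with banker's
#' (round-half-to-even) rounding and a minimum of 1; the genotypes with the
#' smallest index values are selected. Ties at the selection boundary are
#' all included, with a warning that the realized intensity exceeds the
#' nominal one.
#'
#' @param index Data frame whose first two columns are genotype label and
#'   index value (as from [compute_mgidi()] / [mtsi()]), or a named numeric
#'   vector.
#' @param intensity Selection intensity in percent, in (0, 100\].
#' @return Tibble `genotype`, `index`, `rank`, `selected`, with attributes
#'   `intensity` and `n_selected`.
#' @export
select_genotypes <- function(index, intensity) {
  if (intensity <= 0 || intensity > 100) {
    abort("intensity must be in (0, 100]", class = "metsel_param_error")
  }
  if (is.numeric(index) && !is.null(names(index))) {
    index <- tibble::enframe(index, name = "genotype", value = "index")
  }
  index <- tibble::as_tibble(index)
  names(index)[1:2] <- c("genotype", "index")
  n <- nrow(index)
  n_sel <- max(1L, as.integer(round(n * intensity / 100)))
  ord <- order(index$index)
  cutoff <- index$index[ord[n_sel]]
  selected <- index$index <= cutoff
  if (sum(selected) > n_sel) {
    warn(sprintf(
      "ties at the selection boundary: %d genotypes selected (realized intensity %.1f%% > nominal %.1f%%)",
      sum(selected), 100 * sum(selected) / n, intensity))
  }
  out <- index[c("genotype", "index")]
  out$rank <- rank(index$index, ties.method = "min")
  out$selected <- selected
  out <- dplyr::arrange(out, .data$rank)
  attr(out, "intensity") <- intensity
  attr(out, "n_selected") <- sum(selected)
  out
}

#' Selection differential, percent of the site mean
#'
#' `100 * (selected_mean - site_mean) / site_mean`, reported to one decimal.
#'
#' @param site_mean Overall trial-site trait mean (> 0).
#' @param selected_mean Mean of the selected group.
#' @return Percent differential, rounded to one decimal. Vectorized.
#' @export
selection_differential <- function(site_mean, selected_mean) {
  if (any(site_mean <= 0)) {
    abort("site_mean must be > 0", class = "metsel_param_error")
  }
  round(100 * (selected_mean - site_mean) / site_mean, 1)
}

#' Per-site, per-trait selection differentials of a selected set
#'
#' Site means are arithmetic means over all measured trees at the site;
#' selected means are over the trees of the selected provenances.
#'
#' @param data Trial tibble.
#' @param selected Character vector of selected provenance labels, or a
#'   named list of such vectors keyed by site (site-specific selections).
#' @param traits Trait columns to summarise (default: all).
#' @return Tibble `site`, `trait`, `site_mean`, `selected_mean`,
#'   `differential`.
#' @export
selection_differentials <- function(data, selected, traits = NULL) {
  traits <- traits %||% setdiff(names(data), c("site", "provenance", "block",
                                               "tree"))
  long <- data |>
    dplyr::select("site", "provenance", dplyr::all_of(traits)) |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  in_selected <- function(site, provenance) {
    if (is.list(selected)) provenance %in% selected[[site[1]]]
    else provenance %in% selected
  }
  long |>
    dplyr::group_by(.data$site, .data$trait) |>
    dplyr::summarise(
      site_mean = mean(.data$value),
      selected_mean = mean(.data$value[in_selected(.data$site,
                                                   .data$provenance)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      differential = selection_differential(.data$site_mean,
                                            .data$selected_mean),
      trait = factor(.data$trait, levels = traits)
    ) |>
    dplyr::arrange(.data$trait, .data$site) |>
    dplyr::mutate(trait = as.character(.data$trait))
}

#' Within-trial multi-trait selection by the MGIDI
#'
#' Convenience wrapper chaining [rescale_traits()], [factor_analysis()],
#' [compute_mgidi()] and [select_genotypes()].
#'
#' @inheritParams rescale_traits
#' @inheritParams select_genotypes
#' @return Object of class `mgidi_result`: `factor_model`, `index` (ranking
#'   tibble with `selected` flag), `intensity`.
#' @export
mgidi <- function(means, higher_better = TRUE, intensity = 15) {
  fm <- factor_analysis(rescale_traits(means, higher_better))
  idx <- compute_mgidi(fm)
  sel <- select_genotypes(idx[c("genotype", "mgidi")], intensity)
  structure(
    list(factor_model = fm, index = dplyr::rename(sel, mgidi = "index"),
         intensity = intensity),
    class = "mgidi_result"
  )
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat(sprintf("<mgidi_result> %d genotypes, %d selected at %.0f%% intensity\n",
              nrow(x$index), sum(x$index$selected), x$intensity))
  print(head(x$index, sum(x$index$selected)))
  invisible(x)
}

#' @export
tidy.mgidi_result <- function(x, ...) x$index

#' @export
glance.mgidi_result <- function(x, ...) {
  dplyr::mutate(glance(x$factor_model), intensity = x$intensity,
                n_selected = sum(x$index$selected))
}

#' Selected genotype labels of a selection-style result
#'
#' @param x An `mgidi_result`, `mtsi_result`, or a tibble from
#'   [select_genotypes()].
#' @return Character vector of selected genotype labels.
#' @export
selected_genotypes <- function(x) {
  idx <- if (is.data.frame(x)) x else x$index
  idx$genotype[idx$selected]
}
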