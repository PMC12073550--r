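#' WAASB: weighted average of absolute IPCA scores of the interaction BLUPs
#'
#' Stability statistic computed from the singular value decomposition of the
#' genotype-by-environment interaction BLUP matrix. With `theta = U D V'`,
#' the interaction principal component axis (IPCA) scores are
#' `theta_ik = U_ik d_k` over the first `p = min(g - 1, e - 1)` axes
#' (minimum 1), the axis explained proportions are
#' `EP_k = d_k^2 / sum(d^2)`, and
#' `WAASB_i = sum_k |theta_ik| EP_k / sum_k EP_k`. Lower values mean the
#' genotype's interaction pattern is closer to zero on the dominant axes,
#' i.e. more stable across environments. All retained axes enter the
#' average; no truncation.
#'
#' @param theta Interaction BLUP matrix (genotypes x environments, >= 2 of
#'   each; absent pairs already 0-filled), or a [fit_met_model()] result.
#' @return Object of class `waasb_result`: `waasb` ranking tibble,
#'   IPCA `scores`, explained proportions `ep`, and the input matrix.
#' @export
waasb <- function(theta) {
  if (inherits(theta, "met_fit")) theta <- interaction_blups(theta)
  theta <- as.matrix(theta)
  if (ncol(theta) < 2) {
    abort("stability is undefined with a single environment",
          class = "metsel_design_error")
  }
  if (nrow(theta) < 2) {
    abort("need >= 2 genotypes", class = "metsel_design_error")
  }
  if (anyNA(theta)) {
    abort("interaction matrix must have no missing cells (0-fill absent pairs)",
          class = "metsel_param_error")
  }
  g <- rownames(theta) %||% paste0("G", seq_len(nrow(theta)))
  p <- max(1L, min(nrow(theta) - 1L, ncol(theta) - 1L))
  sv <- svd(theta, nu = p, nv = p)
  d <- sv$d[seq_len(p)]
  tot <- sum(sv$d^2)
  if (tot == 0) {
    # perfectly stable everywhere: all scores 0, axes carry equal weight
    ep <- rep(1 / p, p)
    scores <- matrix(0, nrow(theta), p)
  } else {
    ep <- d^2 / tot
    scores <- sv$u %*% diag(d, p)
  }
  dimnames(scores) <- list(g, paste0("IPCA", seq_len(p)))
  w <- as.vector(abs(scores) %*% ep) / sum(ep)
  structure(
    list(
      waasb = tibble::tibble(genotype = g, waasb = w,
                             rank = rank(w, ties.method = "min")) |>
        dplyr::arrange(.data$rank),
      scores = scores,
      ep = ep,
      theta = theta
    ),
    class = "waasb_result"
  )
}

#' @export
print.waasb_result <- function(x, ...) {
  cat(sprintf("<waasb_result> %d genotypes x %d environments, %d IPCA axis/axes\n",
              nrow(x$theta), ncol(x$theta), length(x$ep)))
  print(head(x$waasb))
  invisible(x)
}

#' @export
tidy.waasb_result <- function(x, ...) x$waasb

#' WAASBY: weighted blend of mean performance and WAASB stability
#'
#' Mean performance is rescaled 0-100 (best performer 100) and WAASB is
#' rescaled 0-100 reversed (most stable, i.e. lowest WAASB, gets 100); the
#' blend is `(rY * w_y + rW * w_s) / (w_y + w_s)`. Equal weights (50/50)
#' give performance and stability the same say.
#'
#' @param performance Numeric vector of genotype mean performance (higher
#'   is better).
#' @param stability Numeric vector of WAASB values, same length/order.
#' @param w_y,w_s Non-negative weights for performance and stability
#'   (`w_y + w_s > 0`).
#' @return Numeric vector of WAASBY values in \[0, 100\], names preserved.
#' @export
waasby <- function(performance, stability, w_y = 50, w_s = 50) {
  if (length(performance) != length(stability)) {
    abort("performance and stability must have the same length",
          class = "metsel_param_error")
  }
  if (w_y < 0 || w_s < 0 || w_y + w_s <= 0) {
    abort("weights must be non-negative with a positive sum",
          class = "metsel_param_error")
  }
  const_p <- max(performance) == min(performance)
  const_s <- max(stability) == min(stability)
  if (const_p && const_s) {
    abort("performance and stability are both constant: WAASBY undefined",
          class = "metsel_degenerate_error")
  }
  r_y <- rescale_0_100(performance, larger_better = TRUE, constant = "max",
                       what = "performance values")
  r_w <- rescale_0_100(stability, larger_better = FALSE, constant = "max",
                       what = "WAASB values")
  out <- (r_y * w_y + r_w * w_s) / (w_y + w_s)
  names(out) <- names(performance) %||% names(stability)
  out
}

#' Per-trait WAASBY table from across-site fits
#'
#' For each trait's `met_fit`, combines the BLUP-based predicted provenance
#' means (performance) with the WAASB of its interaction BLUP matrix into a
#' WAASBY value, and assembles the genotype x trait WAASBY matrix the MTSI
#' operates on.
#'
#' @param fits Named list of [fit_met_model()] results (names = traits).
#' @inheritParams waasby
#' @return Tibble: `genotype` plus one WAASBY column per trait.
#' @export
waasby_table <- function(fits, w_y = 50, w_s = 50) {
  stopifnot(length(fits) >= 1)
  cols <- purrr::imap(fits, function(fit, trait) {
    perf <- predicted_means(fit)
    wb <- waasb(fit)$waasb
    m <- dplyr::inner_join(perf, wb, by = c(provenance = "genotype"))
    tibble::tibble(
      genotype = m$provenance,
      !!trait := waasby(m$pred_mean, m$waasb, w_y, w_s)
    )
  })
  purrr::reduce(cols, dplyr::inner_join, by = "genotype")
}

#' Multi-trait stability index (MTSI)
#'
#' The genotype-ideotype distance construction applied to per-trait WAASBY
#' values: rescale the WAASBY matrix 0-100 (all columns higher-is-better),
#' run the factor analysis, score the all-100 ideotype, and take
#' `MTSI_i = sqrt(sum_j (F_ij - F_j)^2)` over retained factors. Lower MTSI
#' means closer to the ideal blend of performance and stability on every
#' trait. Selection uses the same rounding and tie rules as
#' [select_genotypes()].
#'
#' @param waasby_tbl Tibble from [waasby_table()] (genotype + one WAASBY
#'   column per trait; >= 3 genotypes, >= 2 traits).
#' @param intensity Selection intensity in percent.
#' @return Object of class `mtsi_result`: `factor_model`, `index` ranking
#'   tibble with `selected` flag, `intensity`.
#' @export
mtsi <- function(waasby_tbl, intensity = 20) {
  fm <- factor_analysis(rescale_traits(waasby_tbl, higher_better = TRUE))
  idx <- ideotype_distance(fm, index_name = "mtsi")
  sel <- select_genotypes(idx[c("genotype", "mtsi")], intensity)
  structure(
    list(factor_model = fm, index = dplyr::rename(sel, mtsi = "index"),
         intensity = intensity),
    class = "mtsi_result"
  )
}

#' Re-select from an MTSI result at a different intensity
#'
#' @param mtsi_result An [mtsi()] result.
#' @param intensity Selection intensity in percent.
#' @return The `mtsi_result` with its `index` and `intensity` updated.
#' @export
select_across_sites <- function(mtsi_result, intensity) {
  stopifnot(inherits(mtsi_result, "mtsi_result"))
  sel <- select_genotypes(mtsi_result$index[c("genotype", "mtsi")], intensity)
  mtsi_result$index <- dplyr::rename(sel, mtsi = "index")
  mtsi_result$intensity <- intensity
  mtsi_result
}

#' @export
print.mtsi_result <- function(x, ...) {
  cat(sprintf("<mtsi_result> %d genotypes, %d selected at %.0f%% intensity\n",
              nrow(x$index), sum(x$index$selected), x$intensity))
  print(head(x$index, sum(x$index$selected)))
  invisible(x)
}

#' @export
tidy.mtsi_result <- function(x, ...) x$index

#' @export
glance.mtsi_result <- function(x, ...) {
  dplyr::mutate(glance(x$factor_model), intensity = x$intensity,
                n_selected = sum(x$index$selected))
}
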