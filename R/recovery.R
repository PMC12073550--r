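#' Parameter-recovery simulation study
#'
#' Validates the estimation chain end to end: simulate trials from known
#' variance components at a stated size, refit them with [fit_site_model()]
#' or [fit_met_model()], and compare the average recovered components
#' against the simulation truth. Averaging the estimates over a few
#' replicate simulations measures the estimator's bias at that design size
#' rather than a single draw's Monte Carlo noise.
#'
#' @param kind `"site"` for the within-site model (components `provenance`,
#'   `residual`) or `"met"` for the across-site model (adds
#'   `provenance_x_site`).
#' @param v_p,v_ge,v_r True variance components (squared trait units);
#'   `v_ge` is ignored for `kind = "site"`.
#' @param mu True grand mean.
#' @param n_prov,n_sites,n_blocks,n_trees Design size per replicate
#'   (`n_sites` is 1 for `kind = "site"`).
#' @param n_reps Number of replicate simulations averaged.
#' @param seed Master seed; replicate seeds are derived deterministically.
#' @return Tibble `component`, `truth`, `estimate` (mean over replicates),
#'   `rel_error`.
#' @export
recovery_study <- function(kind = c("site", "met"), v_p, v_ge = 0, v_r,
                           mu = 30, n_prov = 550, n_sites = 3, n_blocks = 3,
                           n_trees = 25, n_reps = 3, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "site") n_sites <- 1
  prov <- sprintf("G%04d", seq_len(n_prov))
  sites <- paste0("S", seq_len(n_sites))
  des <- trial_design(
    site_ids = sites,
    provenance_sets = setNames(rep(list(prov), n_sites), sites),
    n_blocks = n_blocks, n_trees_per_plot = n_trees,
    traits = tibble::tibble(trait = "Y", higher_better = TRUE)
  )
  par <- variance_params(tibble::tibble(
    trait = "Y", mu = mu, v_p = v_p,
    v_ge = if (kind == "met") v_ge else 0, v_pb = 0, v_r = v_r
  ))
  est <- purrr::map(seq_len(n_reps), function(r) {
    rep_seed <- (as.numeric(seed) + r * 104729) %% 2147483647
    dat <- simulate_met(des, par, seed = rep_seed)
    fit <- suppressWarnings(
      if (kind == "site") {
        fit_site_model(dat, "Y", lrt = FALSE)
      } else {
        fit_met_model(dat, "Y", analysis_set = "all", lrt = FALSE)
      }
    )
    setNames(fit$varcomp$variance, fit$varcomp$component)
  })
  truth <- if (kind == "site") {
    c(provenance = v_p, residual = v_r)
  } else {
    c(provenance = v_p, provenance_x_site = v_ge, residual = v_r)
  }
  avg <- colMeans(do.call(rbind, est))[names(truth)]
  tibble::tibble(
    component = names(truth),
    truth = unname(truth),
    estimate = unname(avg),
    rel_error = unname(abs(avg - truth) / truth)
  )
}
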