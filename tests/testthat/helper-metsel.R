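# small multi-site design for fast fits
tiny_design <- function(n_prov = 10, n_sites = 2, n_blocks = 2, n_trees = 4,
                        traits = c("DBH", "TH")) {
  prov <- sprintf("G%02d", seq_len(n_prov))
  sites <- paste0("S", seq_len(n_sites))
  trial_design(
    site_ids = sites,
    provenance_sets = setNames(rep(list(prov), n_sites), sites),
    n_blocks = n_blocks,
    n_trees_per_plot = n_trees,
    traits = tibble::tibble(trait = traits, higher_better = TRUE)
  )
}

tiny_params <- function(traits = c("DBH", "TH"), mu = 30, v_p = 4,
                        v_ge = 2, v_pb = 0, v_r = 10,
                        site_effects = NULL, block_effects = NULL) {
  variance_params(
    tibble::tibble(trait = traits, mu = mu, v_p = v_p, v_ge = v_ge,
                   v_pb = v_pb, v_r = v_r),
    site_effects = site_effects, block_effects = block_effects
  )
}

# independent restatement of the selected-set size rule:
# round-half-to-even of n * intensity / 100, floor of 1
oracle_n_selected <- function(n, intensity) {
  m <- n * intensity / 100
  f <- floor(m)
  frac <- m - f
  k <- if (frac > 0.5) {
    f + 1
  } else if (frac < 0.5) {
    f
  } else if (f %% 2 == 0) {
    f
  } else {
    f + 1
  }
  max(1, k)
}

# genotype x trait mean table with distinct, well-conditioned structure
toy_means <- function(n_g = 5, n_t = 3, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(n_g * n_t, 50, 10), n_g, n_t)
  tibble::as_tibble(setNames(as.data.frame(m), paste0("T", seq_len(n_t)))) |>
    dplyr::mutate(genotype = paste0("G", seq_len(n_g)), .before = 1)
}
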