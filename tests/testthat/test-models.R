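test_that("per-site REML recovers known variance components on scaled-up data", {
  # truth: within-site total-height components V_p = 3.36, V_r = 19.68,
  # simulated at ten times the field trial's provenance count
  prov <- sprintf("G%03d", 1:550)
  des <- trial_design(
    site_ids = "S1", provenance_sets = list(S1 = prov),
    n_blocks = 3, n_trees_per_plot = 25,
    traits = tibble::tibble(trait = "TH", higher_better = TRUE)
  )
  par <- tiny_params(traits = "TH", mu = 30, v_p = 3.36, v_ge = 0,
                     v_pb = 0, v_r = 19.68)
  dat <- simulate_met(des, par, seed = 101)
  fit <- fit_site_model(dat, "TH")
  vc <- setNames(fit$varcomp$variance, fit$varcomp$component)
  expect_lt(abs(vc[["provenance"]] - 3.36) / 3.36, 0.15)
  expect_lt(abs(vc[["residual"]] - 19.68) / 19.68, 0.15)
  expect_true(fit$converged)
  # provenance BLUPs centre on zero
  expect_lt(abs(sum(fit$blups$blup)), 1e-6 * nrow(fit$blups) * sd(dat$TH))
})

test_that("a zero provenance variance is often pinned at the boundary", {
  hits <- 0
  for (i in 1:10) {
    des <- tiny_design(n_prov = 15, n_sites = 1, n_blocks = 2, n_trees = 5,
                       traits = "DBH")
    dat <- simulate_met(des, tiny_params(traits = "DBH", v_p = 0, v_ge = 0,
                                         v_r = 10),
                        seed = 200 + i)
    fit <- fit_site_model(dat, "DBH")
    if (fit$varcomp$variance[1] < 1e-6) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("REML estimates are stable under row duplication and row order", {
  des <- tiny_design(n_prov = 12, n_sites = 1, n_blocks = 3, n_trees = 8,
                     traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH"), seed = 55)
  fit <- fit_site_model(dat, "DBH")

  shuffled <- dat[sample(nrow(dat)), ]
  fit_sh <- fit_site_model(shuffled, "DBH")
  expect_equal(fit_sh$varcomp$variance, fit$varcomp$variance,
               tolerance = 1e-8)
  expect_equal(fit_sh$blups, fit$blups, tolerance = 1e-8)

  # duplicating every observation leaves the provenance variance and the
  # within-provenance total (plot + residual) essentially unchanged; the
  # plot/residual split itself is only weakly identified at small cell sizes
  doubled <- dplyr::bind_rows(
    dat, dplyr::mutate(dat, tree = tree + max(dat$tree)))
  fit_db <- fit_site_model(doubled, "DBH")
  vc <- setNames(fit$varcomp$variance, fit$varcomp$component)
  vc_db <- setNames(fit_db$varcomp$variance, fit_db$varcomp$component)
  expect_equal(vc_db[["provenance"]], vc[["provenance"]], tolerance = 0.02)
  expect_equal(vc_db[["provenance_x_block"]] + vc_db[["residual"]],
               vc[["provenance_x_block"]] + vc[["residual"]],
               tolerance = 0.02)
})

test_that("degenerate site designs are rejected", {
  des <- tiny_design(n_prov = 6, n_sites = 2, traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH"), seed = 9)
  expect_error(fit_site_model(dat, "DBH"), class = "metsel_design_error")
  one_prov <- dat[dat$provenance == "G01" & dat$site == "S1", ]
  expect_error(fit_site_model(one_prov, "DBH"),
               class = "metsel_design_error")
  expect_error(fit_site_model(dat, "HT", site = "S1"),
               class = "metsel_param_error")
  expect_error(fit_met_model(dat[dat$site == "S1", ], "DBH"),
               class = "metsel_design_error")
})

test_that("across-site model recovers components and shrinks the interaction to zero when absent", {
  # no interaction simulated: every interaction BLUP should be negligible
  des <- tiny_design(n_prov = 50, n_sites = 3, n_blocks = 3, n_trees = 20,
                     traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH", v_p = 4, v_ge = 0,
                                       v_r = 10),
                      seed = 77)
  fit <- fit_met_model(dat, "DBH", analysis_set = "all")
  v_r <- fit$varcomp$variance[fit$varcomp$component == "residual"]
  expect_lt(max(abs(fit$theta)), 0.05 * sqrt(v_r))
})

test_that("interaction BLUP matrix covers the analysis set with zeros for unobserved pairs", {
  des <- default_design()
  par <- default_params(des)
  dat <- simulate_met(des, par, seed = 12)
  expect_warning(
    fit <- fit_met_model(dat, "DBH", analysis_set = "all"),
    "single site"
  )
  expect_equal(dim(fit$theta), c(61, 3))
  # provenances absent from a site must carry the BLUP of an unobserved
  # effect: exactly zero
  for (s in des$site_ids) {
    absent <- setdiff(rownames(fit$theta), des$provenance_sets[[s]])
    expect_true(all(fit$theta[absent, s] == 0))
  }
  fit_c <- suppressWarnings(fit_met_model(dat, "DBH"))
  expect_equal(dim(fit_c$theta), c(38, 3))
  expect_setequal(rownames(fit_c$theta), common_provenances(des))
})

test_that("likelihood ratio tests match the chi-square reference", {
  null_case <- lrt_random_effect(-100, -100, df = 1)
  expect_equal(null_case$statistic, 0)
  expect_equal(null_case$p_value, 1)

  # chi-square 0.95 quantile at 1 df is 3.841
  at_05 <- lrt_random_effect(-100 + 3.841 / 2, -100, df = 1)
  expect_equal(at_05$p_value, 0.05, tolerance = 1e-3)

  strong <- lrt_random_effect(-100 + 23.16 / 2, -100, df = 1)
  expect_lt(strong$p_value, 0.001)
  expect_equal(strong$signif, "***")

  expect_error(lrt_random_effect(-1, -2, df = 0),
               class = "metsel_param_error")
  expect_warning(lrt_random_effect(-103, -100), "clamped")
})

test_that("adding a truly active random term never decreases the REML log-likelihood", {
  worse <- 0
  for (i in 1:30) {
    des <- tiny_design(n_prov = 10, n_sites = 1, n_blocks = 2, n_trees = 3,
                       traits = "DBH")
    dat <- simulate_met(des, tiny_params(traits = "DBH", v_p = 3, v_ge = 0,
                                         v_r = 5),
                        seed = 900 + i)
    fit <- fit_site_model(dat, "DBH")
    if (fit$loglik < fit$loglik_reduced - 1e-6) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("BLUPs shrink towards zero relative to raw provenance mean deviations", {
  des <- tiny_design(n_prov = 20, n_sites = 1, n_blocks = 3, n_trees = 5,
                     traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH", v_p = 2, v_ge = 0,
                                       v_r = 20),
                      seed = 66)
  fit <- fit_site_model(dat, "DBH")
  raw_dev <- tapply(dat$DBH, dat$provenance, mean) - mean(dat$DBH)
  raw_dev <- raw_dev[fit$blups$provenance]
  expect_true(all(abs(fit$blups$blup) <= abs(raw_dev) + 1e-8))
})

test_that("variance proportions reproduce component arithmetic and sum to one", {
  pr <- variance_proportions(c(v_p = 7.23, v_r = 60.77))
  expect_equal(round(100 * pr$proportion[1], 2), 10.63)

  pr3 <- variance_proportions(c(v_p = 3.53, v_ge = 3.91, v_r = 5.69))
  expect_equal(round(100 * pr3$proportion), c(27, 30, 43))
  expect_equal(sum(pr3$proportion), 1, tolerance = 1e-12)

  single <- variance_proportions(c(v_p = 0, v_r = 2.2))
  expect_equal(single$proportion, c(0, 1))

  expect_error(variance_proportions(c(v_p = 0, v_r = 0)),
               class = "metsel_param_error")

  des <- tiny_design(n_prov = 8, n_sites = 2, traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH"), seed = 21)
  f <- fit_site_model(dat, "DBH", site = "S1")
  expect_equal(sum(variance_proportions(f)$proportion), 1, tolerance = 1e-12)
  m <- fit_met_model(dat, "DBH")
  expect_equal(sum(variance_proportions(m)$proportion), 1, tolerance = 1e-12)
})

test_that("fixed-effect F tests behave under null and strong effects", {
  # blocks simulated with no effect: the block test should rarely reject
  sig <- 0
  for (i in 1:10) {
    des <- tiny_design(n_prov = 10, n_sites = 1, n_blocks = 3, n_trees = 5,
                       traits = "DBH")
    dat <- simulate_met(des, tiny_params(traits = "DBH", v_p = 2, v_ge = 0,
                                         v_r = 10),
                        seed = 400 + i)
    an <- anova_fixed(fit_site_model(dat, "DBH"))
    if (an$p_value[an$term == "block"] <= 0.05) sig <- sig + 1
  }
  expect_lte(sig, 1)

  # identical blocks: zero between-block mean square
  des1 <- tiny_design(n_prov = 6, n_sites = 1, n_blocks = 2, n_trees = 4,
                      traits = "DBH")
  dat1 <- simulate_met(des1, tiny_params(traits = "DBH"), seed = 31)
  b1 <- dat1[dat1$block == "B1", ]
  dup <- dplyr::mutate(b1, block = "B2")
  twin <- dplyr::bind_rows(b1, dup)
  an1 <- anova_fixed(fit_site_model(twin, "DBH"))
  expect_lt(an1$mean_sq[an1$term == "block"], 1e-18)

  # large injected site offsets: environment term flagged ***
  des2 <- tiny_design(n_prov = 15, n_sites = 3, n_blocks = 2, n_trees = 5,
                      traits = "DBH")
  se <- tibble::tibble(site = c("S1", "S2", "S3"), trait = "DBH",
                       effect = c(-8, 0, 8))
  dat2 <- simulate_met(des2, tiny_params(traits = "DBH", v_ge = 0.5,
                                         site_effects = se),
                       seed = 32)
  an2 <- anova_fixed(fit_met_model(dat2, "DBH"))
  expect_equal(an2$signif[an2$term == "site"], "***")
})

test_that("tidy and glance expose fits as tibbles", {
  des <- tiny_design(n_prov = 8, n_sites = 2, traits = c("DBH", "TH"))
  dat <- simulate_met(des, tiny_params(), seed = 13)
  f <- fit_site_model(dat, "DBH", site = "S1")
  expect_named(tidy(f), c("trait", "site", "component", "variance",
                          "proportion"))
  expect_equal(nrow(glance(f)), 1)
  m <- fit_met_model(dat, "TH")
  expect_true(all(c("v_p", "v_ge", "v_r", "lrt_ge_p") %in% names(glance(m))))
  expect_equal(nrow(tidy(m, effects = "ran_vals")), 8)
  expect_identical(interaction_blups(m), m$theta)
  expect_named(predicted_means(m), c("provenance", "pred_mean"))
})
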