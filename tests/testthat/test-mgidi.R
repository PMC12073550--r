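test_that("trait rescaling maps extremes to 0/100 in the desired direction", {
  m <- tibble::tibble(genotype = c("a", "b", "c"), X = c(10, 20, 30))
  expect_equal(rescale_traits(m, c(X = TRUE))$X, c(0, 50, 100))
  expect_equal(rescale_traits(m, c(X = FALSE))$X, c(100, 50, 0))
  const <- tibble::tibble(genotype = c("a", "b", "c"), X = c(5, 5, 5))
  expect_error(rescale_traits(const), "X",
               class = "metsel_degenerate_error")
})

test_that("perfectly correlated traits collapse to one factor explaining everything", {
  m <- tibble::tibble(genotype = paste0("g", 1:5),
                      A = c(1, 3, 5, 7, 9))
  m$B <- 2 * m$A + 1
  expect_warning(fm <- factor_analysis(rescale_traits(m)), "singular")
  expect_equal(fm$n_retained, 1)
  expect_equal(sum(fm$explained), 1, tolerance = 1e-6)
  expect_equal(sum(fm$eigenvalues), 2, tolerance = 1e-9)
})

test_that("loadings and scores agree with an independent SVD route", {
  m <- toy_means(n_g = 5, n_t = 3)
  # make the three traits strongly collinear so one factor is retained and
  # no rotation is applied
  m$T2 <- m$T1 * 0.9 + m$T2 * 0.1
  m$T3 <- m$T1 * 0.8 + m$T3 * 0.2
  r <- rescale_traits(m)
  fm <- factor_analysis(r)
  expect_equal(fm$n_retained, 1)

  # oracle: eigenstructure of the correlation matrix via the SVD of the
  # standardized data matrix, never touching eigen() on cor()
  X <- as.matrix(r[-1])
  Z <- scale(X)
  sv <- svd(Z / sqrt(nrow(Z) - 1))
  expect_equal(sort(fm$eigenvalues), sort(sv$d^2), tolerance = 1e-8)
  load_oracle <- sv$v[, 1] * sv$d[1]
  agree <- min(max(abs(fm$loadings[, 1] - load_oracle)),
               max(abs(fm$loadings[, 1] + load_oracle)))
  expect_lt(agree, 1e-8)

  # scores by the regression method, recomputed longhand
  R <- crossprod(Z) / (nrow(Z) - 1)
  score_oracle <- Z %*% solve(R) %*% fm$loadings
  expect_equal(unname(fm$scores), unname(score_oracle), tolerance = 1e-10)

  # communalities are preserved by rotation and bounded by one
  expect_true(all(fm$communalities >= 0 & fm$communalities <= 1 + 1e-9))
})

test_that("rotation preserves communalities on a multi-factor problem", {
  set.seed(14)
  m <- toy_means(n_g = 12, n_t = 4, seed = 14)
  r <- rescale_traits(m)
  fm <- factor_analysis(r)
  X <- as.matrix(r[-1])
  ev <- eigen(cor(X), symmetric = TRUE)
  nf <- fm$n_retained
  unrot <- ev$vectors[, 1:nf, drop = FALSE] %*%
    diag(sqrt(ev$values[1:nf]), nf)
  expect_equal(unname(rowSums(fm$loadings^2)), rowSums(unrot^2),
               tolerance = 1e-9)
  expect_equal(sum(fm$eigenvalues), 4, tolerance = 1e-9)
})

test_that("near-uncorrelated traits give eigenvalues near one", {
  set.seed(3)
  n <- 4000
  m <- tibble::tibble(genotype = paste0("g", 1:n),
                      A = rnorm(n), B = rnorm(n), C = rnorm(n))
  fm <- factor_analysis(rescale_traits(m))
  expect_true(all(abs(fm$eigenvalues - 1) < 0.1))
})

test_that("the ideotype and its coincident genotype sit at distance zero", {
  m <- toy_means(n_g = 6, n_t = 3, seed = 8)
  # genotype g1 made best on every trait: its rescaled row is all 100
  m[1, -1] <- as.list(apply(m[-1], 2, max) + 5)
  fm <- factor_analysis(rescale_traits(m))
  idx <- compute_mgidi(fm)
  expect_equal(idx$genotype[1], "G1")
  expect_lt(idx$mgidi[idx$genotype == "G1"], 1e-8)
  expect_true(all(idx$mgidi >= 0))
})

test_that("distances match a longhand recomputation from the factor scores", {
  m <- toy_means(n_g = 4, n_t = 3, seed = 5)
  fm <- factor_analysis(rescale_traits(m))
  idx <- compute_mgidi(fm)
  longhand <- sqrt(rowSums(
    sweep(fm$scores, 2, fm$ideotype_scores, `-`)^2))
  expect_equal(setNames(idx$mgidi, idx$genotype),
               longhand[idx$genotype], tolerance = 1e-10)
})

test_that("the index is invariant to positive affine recoding of a raw trait", {
  m <- toy_means(n_g = 8, n_t = 3, seed = 77)
  base <- compute_mgidi(factor_analysis(rescale_traits(m)))
  m2 <- dplyr::mutate(m, T2 = 3.7 * T2 + 120)
  recoded <- compute_mgidi(factor_analysis(rescale_traits(m2)))
  expect_equal(base$mgidi, recoded$mgidi, tolerance = 1e-9)
})

test_that("a single trait reduces the index ranking to the trait ranking", {
  m <- tibble::tibble(genotype = paste0("g", 1:7),
                      X = c(3, 9, 1, 7, 5, 8, 2))
  idx <- compute_mgidi(factor_analysis(rescale_traits(m)))
  expect_equal(idx$genotype, m$genotype[order(-m$X)])
})

test_that("selected-set sizes follow round-half-even with a floor of one", {
  expect_equal(attr(select_genotypes(setNames(runif(55), 1:55), 15),
                    "n_selected"), 8L)
  expect_equal(attr(select_genotypes(setNames(runif(49), 1:49), 15),
                    "n_selected"), 7L)
  expect_equal(attr(select_genotypes(setNames(runif(48), 1:48), 15),
                    "n_selected"), 7L)
  expect_equal(attr(select_genotypes(setNames(runif(38), 1:38), 20),
                    "n_selected"), 8L)

  for (intensity in c(5, 10, 15, 20)) {
    got <- vapply(1:200, function(n) {
      attr(select_genotypes(setNames(seq_len(n), seq_len(n)), intensity),
           "n_selected")
    }, 1L)
    want <- vapply(1:200, oracle_n_selected, 1, intensity = intensity)
    expect_equal(got, as.integer(want),
                 label = sprintf("sizes at %d%%", intensity))
  }
})

test_that("boundary ties are all selected, with a warning", {
  idx <- tibble::tibble(genotype = paste0("g", 1:10),
                        value = c(1, 2, 3, 3, 3, 6, 7, 8, 9, 10))
  expect_warning(sel <- select_genotypes(idx, 30), "ties")
  expect_equal(sum(sel$selected), 5)
  expect_setequal(selected_genotypes(sel), paste0("g", 1:5))
  expect_error(select_genotypes(idx, 0), class = "metsel_param_error")
  expect_error(select_genotypes(idx, 101), class = "metsel_param_error")
})

test_that("selection differentials reproduce hand arithmetic", {
  expect_equal(selection_differential(35.9, 39.8), 10.9)
  expect_equal(selection_differential(17.7, 18.2), 2.8)
  expect_equal(selection_differential(12.3, 12.3), 0)
  expect_error(selection_differential(0, 1), class = "metsel_param_error")
})

test_that("dataset-level differentials average the right trees", {
  des <- tiny_design(n_prov = 4, n_sites = 2, n_blocks = 2, n_trees = 2,
                     traits = "DBH")
  dat <- simulate_met(des, tiny_params(traits = "DBH"), seed = 19)
  d <- selection_differentials(dat, c("G01", "G02"))
  for (s in c("S1", "S2")) {
    sub <- dat[dat$site == s, ]
    expect_equal(d$site_mean[d$site == s], mean(sub$DBH))
    expect_equal(d$selected_mean[d$site == s],
                 mean(sub$DBH[sub$provenance %in% c("G01", "G02")]))
  }
  # site-specific selections via a named list
  d2 <- selection_differentials(dat, list(S1 = "G01", S2 = "G03"))
  expect_equal(d2$selected_mean[d2$site == "S2"],
               mean(dat$DBH[dat$site == "S2" & dat$provenance == "G03"]))
})

test_that("the mgidi wrapper chains the full construction", {
  m <- toy_means(n_g = 20, n_t = 3, seed = 23)
  res <- mgidi(m, intensity = 15)
  expect_s3_class(res, "mgidi_result")
  expect_equal(sum(res$index$selected), 3) # round-half-even(20 * 0.15) = 3
  expect_equal(nrow(tidy(res)), 20)
  expect_equal(glance(res)$n_selected, 3)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
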