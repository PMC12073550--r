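#' Pipeline configuration
#'
#' A validated bundle of everything [run_pipeline()] needs: the data source
#' (exactly one of `input`, a trial CSV path, or `scenario`, currently
#' `"default"` for the built-in three-site simulation), trait orientations,
#' selection intensities, WAASBY weights, analysis-set mode and the master
#' seed. Serialized to plain-text YAML by [write_config()].
#'
#' @param input Path to a trial CSV (long format, see [read_trial()]).
#' @param scenario Name of a built-in simulation scenario (`"default"`).
#' @param traits Character vector of trait columns to analyse (default: all
#'   trait columns in the data).
#' @param higher_better Orientation flag(s) as in [rescale_traits()].
#' @param mgidi_intensity,mtsi_intensity Selection intensities in percent.
#' @param w_y,w_s WAASBY weights (performance / stability).
#' @param analysis_set `"common"` or `"all"` provenances for the
#'   across-site stage.
#' @param n_trees_per_plot,survival_rate Scenario overrides (simulated data
#'   only).
#' @param seed Master seed for simulation.
#' @param out_dir Optional directory: when set, every output table is also
#'   written there as CSV together with a `run_info.json` stamp (config
#'   hash, seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, scenario = NULL, traits = NULL,
                            higher_better = TRUE,
                            mgidi_intensity = 15, mtsi_intensity = 20,
                            w_y = 50, w_s = 50,
                            analysis_set = c("common", "all"),
                            n_trees_per_plot = NULL, survival_rate = 1,
                            seed = 1, out_dir = NULL) {
  if (is.null(input) == is.null(scenario)) {
    abort("exactly one of `input` and `scenario` must be given",
          class = "metsel_config_error")
  }
  if (!is.null(scenario) && !identical(scenario, "default")) {
    abort(sprintf("unknown scenario '%s'", scenario),
          class = "metsel_config_error")
  }
  for (x in c(mgidi_intensity, mtsi_intensity)) {
    if (x <= 0 || x > 100) {
      abort("intensities must be in (0, 100]", class = "metsel_config_error")
    }
  }
  structure(
    list(input = input, scenario = scenario, traits = traits,
         higher_better = higher_better,
         mgidi_intensity = mgidi_intensity, mtsi_intensity = mtsi_intensity,
         w_y = w_y, w_s = w_s,
         analysis_set = match.arg(analysis_set),
         n_trees_per_plot = n_trees_per_plot, survival_rate = survival_rate,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Per-site, per-trait summary of a trial dataset
#'
#' Arithmetic mean and sample SD of every trait at every site, with tree
#' and provenance counts. Sites with no non-missing value for a trait are
#' omitted with a warning.
#'
#' @param data Trial tibble.
#' @return Tibble `site`, `trait`, `n_trees`, `n_provenances`, `mean`, `sd`.
#' @export
summarize_dataset <- function(data) {
  check_trial(data)
  traits <- setdiff(names(data), c("site", "provenance", "block", "tree"))
  out <- data |>
    tidyr::pivot_longer(dplyr::all_of(traits), names_to = "trait",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$site, .data$trait) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      n_provenances = dplyr::n_distinct(.data$provenance),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    )
  missing <- setdiff(
    paste(rep(unique(data$site), each = length(traits)), traits),
    paste(out$site, out$trait)
  )
  if (length(missing)) {
    warn(paste("no measurements for:", paste(missing, collapse = "; ")))
  }
  out
}

#' Run the full provenance-trial analysis pipeline
#'
#' Reads or simulates a trial, then: (1) summarises it; (2) fits the
#' per-site mixed model for every site x trait, collecting variance
#' components, provenance LRTs and block mean squares; (3) fits the
#' across-site model per trait with the provenance-by-site interaction;
#' (4) runs the MGIDI selection within each site at `mgidi_intensity` and
#' computes selection differentials; (5) computes WAASB/WAASBY per trait,
#' the MTSI across sites at `mtsi_intensity`, and its differentials.
#' Outputs are a pure function of (data, config, seed); with `out_dir` set
#' they are also written as CSV plus a `run_info.json` stamp.
#'
#' @param config A [pipeline_config()] or path to a YAML config file.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a named list of tibbles: `summary`,
#'   `site_components`, `met_components`, `mgidi_ranking`,
#'   `mgidi_differentials`, `mtsi_ranking`, `mtsi_differentials`, plus
#'   `fits` (the underlying model objects) and `data`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, ...) {
    if (!quiet) inform(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage_ctx <- function(stage, trait, expr) {
    withCallingHandlers(
      expr,
      error = function(e) {
        abort(sprintf("stage '%s' (trait %s) failed: %s", stage, trait,
                      conditionMessage(e)),
              class = "metsel_stage_error", parent = e)
      }
    )
  }

  t0 <- Sys.time()
  if (!is.null(config$input)) {
    data <- read_trial(config$input)
    say("data", "read %d rows from %s", nrow(data), config$input)
  } else {
    design <- default_design()
    if (!is.null(config$n_trees_per_plot)) {
      design$n_trees_per_plot <- as.integer(config$n_trees_per_plot)
    }
    data <- simulate_met(design, default_params(design), seed = config$seed)
    if (config$survival_rate < 1) {
      data <- apply_mortality(data, config$survival_rate,
                              seed = config$seed + 1L)
    }
    say("data", "simulated %d trees (seed %d)", nrow(data), config$seed)
  }

  all_traits <- setdiff(names(data), c("site", "provenance", "block", "tree"))
  traits <- config$traits %||% all_traits
  bad <- setdiff(traits, all_traits)
  if (length(bad)) {
    abort(paste("unknown trait(s) in config:", paste(bad, collapse = ", ")),
          class = "metsel_config_error")
  }
  hb <- resolve_orientation(config$higher_better, traits)

  summary_tbl <- summarize_dataset(data[c("site", "provenance", "block",
                                          "tree", traits)])

  sites <- unique(data$site)
  grid <- tidyr::expand_grid(site = sites, trait = traits)
  site_fits <- purrr::pmap(grid, function(site, trait) {
    stage_ctx("site_fit", trait, {
      f <- fit_site_model(data, trait, site = site)
      say("site_fit", "%s @ %s: n=%d converged=%s", trait, site, f$n_obs,
          f$converged)
      f
    })
  })
  names(site_fits) <- paste(grid$site, grid$trait, sep = ".")
  site_components <- purrr::map_dfr(site_fits, function(f) {
    vc <- setNames(f$varcomp$variance, f$varcomp$component)
    ms <- anova_fixed(f)
    s <- summary_tbl[summary_tbl$site == f$site & summary_tbl$trait == f$trait, ]
    tibble::tibble(
      site = f$site, trait = f$trait,
      lrt_p_statistic = f$lrt$statistic, lrt_p_signif = f$lrt$signif,
      v_p = vc[["provenance"]], v_pb = vc[["provenance_x_block"]],
      v_r = vc[["residual"]],
      prop_vp = variance_proportions(f)$proportion[1],
      ms_block = ms$mean_sq[1], ms_block_signif = ms$signif[1],
      mean = s$mean, sd = s$sd, n_obs = f$n_obs
    )
  })

  met_fits <- purrr::map(setNames(traits, traits), function(trait) {
    stage_ctx("met_fit", trait, {
      f <- fit_met_model(data, trait, analysis_set = config$analysis_set)
      say("met_fit", "%s: n=%d converged=%s", trait, f$n_obs, f$converged)
      f
    })
  })
  met_components <- purrr::map_dfr(met_fits, function(f) {
    vc <- setNames(f$varcomp$variance, f$varcomp$component)
    pr <- variance_proportions(f)
    ms <- anova_fixed(f)
    tibble::tibble(
      trait = f$trait,
      lrt_g = f$lrt$statistic[1], lrt_g_signif = f$lrt$signif[1],
      lrt_ge = f$lrt$statistic[2], lrt_ge_signif = f$lrt$signif[2],
      v_p = vc[["provenance"]], v_ge = vc[["provenance_x_site"]],
      v_r = vc[["residual"]],
      prop_vp = pr$proportion[1], prop_vge = pr$proportion[2],
      prop_vr = pr$proportion[3],
      ms_env = ms$mean_sq[1], ms_env_signif = ms$signif[1],
      ms_block_env = ms$mean_sq[2], ms_block_env_signif = ms$signif[2],
      n_obs = f$n_obs
    )
  })

  mgidi_by_site <- purrr::map(setNames(sites, sites), function(s) {
    stage_ctx("mgidi", paste(traits, collapse = "/"), {
      means <- purrr::reduce(
        purrr::map(traits, function(tr) {
          pm <- predicted_means(site_fits[[paste(s, tr, sep = ".")]])
          setNames(pm, c("genotype", tr))
        }),
        dplyr::inner_join, by = "genotype")
      r <- mgidi(means, higher_better = hb, intensity = config$mgidi_intensity)
      say("mgidi", "%s: %d/%d selected", s, sum(r$index$selected),
          nrow(r$index))
      r
    })
  })
  mgidi_ranking <- purrr::imap_dfr(mgidi_by_site, function(r, s) {
    dplyr::mutate(r$index, site = s, .before = 1)
  })
  mgidi_differentials <- selection_differentials(
    data[c("site", "provenance", "block", "tree", traits)],
    lapply(mgidi_by_site, selected_genotypes)
  )

  stage_ctx("mtsi", paste(traits, collapse = "/"), {
    wtab <- waasby_table(met_fits, w_y = config$w_y, w_s = config$w_s)
    mtsi_res <- mtsi(wtab, intensity = config$mtsi_intensity)
    say("mtsi", "%d/%d selected", sum(mtsi_res$index$selected),
        nrow(mtsi_res$index))
  })
  mtsi_differentials <- selection_differentials(
    data[c("site", "provenance", "block", "tree", traits)],
    selected_genotypes(mtsi_res)
  )

  out <- list(
    summary = summary_tbl,
    site_components = site_components,
    met_components = met_components,
    mgidi_ranking = mgidi_ranking,
    mgidi_differentials = mgidi_differentials,
    waasby = wtab,
    mtsi_ranking = mtsi_res$index,
    mtsi_differentials = mtsi_differentials,
    fits = list(site = site_fits, met = met_fits,
                mgidi = mgidi_by_site, mtsi = mtsi_res),
    data = data,
    config = config
  )
  class(out) <- "met_pipeline"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- c("summary", "site_components", "met_components",
                "mgidi_ranking", "mgidi_differentials", "waasby",
                "mtsi_ranking", "mtsi_differentials")
    for (nm in tables) {
      readr::write_csv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")))
    }
    # hash identifies the analysis, not where its outputs land
    cfg_id <- unclass(config)
    cfg_id$out_dir <- NULL
    stamp <- list(config_hash = rlang::hash(cfg_id),
                  seed = config$seed,
                  package = "metsel",
                  version = as.character(utils::packageVersion("metsel")))
    jsonlite::write_json(stamp, file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    say("write", "tables written to %s", config$out_dir)
  }
  say("done", "finished in %.1fs", as.numeric(Sys.time() - t0, units = "secs"))
  invisible(out)
}

#' @export
print.met_pipeline <- function(x, ...) {
  cat("<met_pipeline>\n")
  cat(sprintf("  data: %d trees, %d sites, %d provenances\n",
              nrow(x$data), dplyr::n_distinct(x$data$site),
              dplyr::n_distinct(x$data$provenance)))
  cat(sprintf("  MGIDI (%.0f%%): %s selected per site\n",
              x$config$mgidi_intensity,
              paste(vapply(split(x$mgidi_ranking$selected, x$mgidi_ranking$site),
                           sum, 1L), collapse = "/")))
  cat(sprintf("  MTSI (%.0f%%): %d of %d selected\n",
              x$config$mtsi_intensity, sum(x$mtsi_ranking$selected),
              nrow(x$mtsi_ranking)))
  invisible(x)
}
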