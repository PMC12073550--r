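#' Write / read a trial dataset as delimited text
#'
#' The on-disk format is long-format UTF-8 CSV with a header row
#' `site,provenance,block,tree` followed by one numeric column per trait;
#' missing trait values are empty cells. `read_trial()` validates the file:
#' the four key columns must be present, every `(site, provenance, block,
#' tree)` tuple unique, and every trait cell numeric or empty.
#'
#' @param data Trial tibble.
#' @param path File path.
#' @return `write_trial()` returns `data` invisibly; `read_trial()` returns
#'   the trial tibble.
#' @export
write_trial <- function(data, path) {
  check_trial(data)
  readr::write_csv(data, path, na = "")
  invisible(data)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  hdr <- readr::read_lines(path, n_max = 1)
  if (length(hdr) == 0 || !nzchar(hdr)) {
    abort(sprintf("'%s' is empty: not a trial dataset", path),
          class = "metsel_parse_error")
  }
  keys <- c("site", "provenance", "block", "tree")
  cols <- strsplit(hdr, ",", fixed = TRUE)[[1]]
  if (!identical(cols[1:4], keys) || length(cols) < 5) {
    abort(paste0("malformed header in '", path, "': expected ",
                 "site,provenance,block,tree,<trait>..."),
          class = "metsel_parse_error")
  }
  traits <- cols[-(1:4)]
  spec <- c(list(site = readr::col_character(),
                 provenance = readr::col_character(),
                 block = readr::col_character(),
                 tree = readr::col_integer()),
            setNames(rep(list(readr::col_double()), length(traits)), traits))
  dat <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols, spec),
                    na = "", progress = FALSE)
  )
  pb <- readr::problems(dat)
  if (nrow(pb) > 0) {
    abort(sprintf("parse error in '%s': row %d, column %d (%s)",
                  path, pb$row[1], pb$col[1], pb$expected[1]),
          class = "metsel_parse_error")
  }
  check_trial(dat)
  dat
}

# shared invariants of a trial table
check_trial <- function(data) {
  keys <- c("site", "provenance", "block", "tree")
  if (!all(keys %in% names(data)) || ncol(data) < 5) {
    abort("trial data needs site, provenance, block, tree and >= 1 trait",
          class = "metsel_parse_error")
  }
  key <- paste(data$site, data$provenance, data$block, data$tree)
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    abort(sprintf("duplicate (site, provenance, block, tree) tuple at row %d: %s",
                  i, key[i]),
          class = "metsel_parse_error")
  }
  traits <- setdiff(names(data), keys)
  for (tr in traits) {
    v <- data[[tr]]
    if (!is.numeric(v)) {
      abort(sprintf("trait column '%s' is not numeric", tr),
            class = "metsel_parse_error")
    }
    if (any(is.infinite(v))) {
      abort(sprintf("trait column '%s' contains non-finite values", tr),
            class = "metsel_parse_error")
    }
  }
  invisible(data)
}

#' Read / write a scenario configuration file
#'
#' Scenario files are plain-text YAML key/value documents holding the
#' pipeline configuration (see [pipeline_config()]): either an `input` path
#' to a trial CSV or a `scenario` name, plus intensities, weights,
#' analysis-set mode and the seed. Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A [pipeline_config()] list.
#' @return `read_config()` returns a validated [pipeline_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste("unknown config keys:", paste(extra, collapse = ", ")),
          class = "metsel_config_error")
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- config[!vapply(config, is.null, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(config)
}
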