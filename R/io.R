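#' Write a measure series to CSV
#'
#' One row per simulated day, one column per measure (raw and, when
#' present, normalized).
#'
#' @param series A measure series (see [run_replicate()]) or replicate
#'   mean (see [run_experiment()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_measure_series <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an experiment exactly: the full
#' configuration, the derived per-replicate seeds of both arms, the fixed
#' release number and the package version.
#'
#' @param experiment A `sit_experiment` from [run_experiment()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(experiment, path) {
  cfg <- experiment$config
  arm <- .arm_label(cfg)
  manifest <- list(
    config = unclass(cfg),
    seeds = list(
      treated = vapply(seq_len(cfg$replicates), function(r) {
        derive_seed(cfg$master_seed, arm, r)
      }, integer(1)),
      control = vapply(seq_len(cfg$replicates), function(r) {
        derive_seed(cfg$master_seed, "control", r)
      }, integer(1))
    ),
    release_number = attr(experiment$treated_replicates[[1]],
                          "release_number"),
    package_version = as.character(utils::packageVersion("sitabm"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a campaign configuration from a file
#'
#' Accepts a YAML file (when the yaml package is available) or a flat
#' `key: value` / `key=value` text file whose keys are the
#' [campaign_config()] argument names; unknown keys are rejected.
#'
#' @param path Configuration file.
#' @return A [campaign_config()].
#' @export
read_campaign_config <- function(path) {
  vals <- NULL
  if (grepl("[.]ya?ml$", path) &&
      requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[:=]", fixed = FALSE)
    vals <- lapply(parts, function(p) {
      v <- trimws(paste(p[-1], collapse = ":"))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(vals) <- vapply(parts, function(p) trimws(p[1]), character(1))
  }
  unknown <- setdiff(names(vals), names(formals(campaign_config)))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(campaign_config, vals)
}
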