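#' Load and validate a YAML run configuration
#'
#' Reads a YAML file whose keys configure the experiment ensembles
#' ([experiment_config()]), the PNLM parameters ([pnlm_params()]) and the
#' marking policy ([mark_policy()]).  Missing keys take the package
#' defaults; unknown keys are rejected by name.  An empty or absent file
#' yields the full defaults.
#'
#' Recognized top-level keys: `experiment` (clean_grays, variances, reps,
#' image_size, seed, family), `pnlm` (search_radius, patch_radius,
#' road_radius, road_L, alpha, h), `mark` (k, min_grad), `repair_window`,
#' `max_passes`.
#'
#' @param path Path to a YAML file, or NULL for defaults.
#' @return A list with elements `experiment`, `pnlm`, `mark`,
#'   `repair_window`, `max_passes`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list()
         else if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("experiment", "pnlm", "mark", "repair_window", "max_passes")
  check_keys <- function(x, known, where) {
    bad <- setdiff(names(x), known)
    if (length(bad))
      stop(sprintf("unknown config key%s in %s: %s",
                   if (length(bad) > 1) "s" else "", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  check_keys(raw, known_top, "top level")
  exp_args <- raw$experiment %||% list()
  check_keys(exp_args, c("clean_grays", "variances", "reps", "image_size",
                         "seed", "family"), "experiment")
  pnlm_args <- raw$pnlm %||% list()
  check_keys(pnlm_args, c("search_radius", "patch_radius", "road_radius",
                          "road_L", "alpha", "h"), "pnlm")
  mark_args <- raw$mark %||% list()
  check_keys(mark_args, c("k", "min_grad"), "mark")
  list(experiment = do.call(experiment_config, exp_args),
       pnlm = do.call(pnlm_params, pnlm_args),
       mark = do.call(mark_policy, mark_args),
       repair_window = as.integer(raw$repair_window %||% 9L),
       max_passes = as.integer(raw$max_passes %||% 3L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a JSON run record
#'
#' Emits a reproducibility record for a run: configuration snapshot, seed,
#' package version, per-stage timings and output paths.
#'
#' @param path Output JSON path.
#' @param config Configuration snapshot (any list).
#' @param seed Seed used.
#' @param timings Named numeric vector of per-stage elapsed seconds.
#' @param outputs Character vector of files produced.
#' @return The record, invisibly.
#' @export
run_record <- function(path, config = list(), seed = NA_integer_,
                       timings = numeric(0), outputs = character(0)) {
  rec <- list(
    package = "pnlmg",
    version = as.character(utils::packageVersion("pnlmg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    timings_sec = as.list(timings),
    outputs = outputs)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}
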