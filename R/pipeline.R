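#' Pipeline runners: simulate, derive, evaluate, describe
#'
#' These functions wire the package end to end around file-based inputs and
#' outputs, and back the `curtailr` command-line tool (see [cli_main()]).
#' Each takes a named configuration list; [read_run_config()] loads one from
#' YAML/JSON and flag-style overrides take precedence over file values.
#'
#' `run_simulate()` calibrates the generator to reference moments and writes
#' a training and a test response matrix (seeds embedded in the headers).
#' `run_derive()` derives the curtailment table and, when thresholds are
#' requested, fits stage models on the training matrix and writes one
#' stochastic-curtailment table per threshold (plus constrained variants on
#' request) and the stage-model JSON. `run_evaluate()` replays a test matrix
#' through saved tables and writes the operating-characteristic grid.
#' `run_describe()` prints per-item descriptive statistics for a matrix.
#'
#' @param config A named list. Recognised fields (by runner):
#'   * common: `instrument` (path to a YAML definition; default is the COMM),
#'     `out_dir` (default `"."`), `seed`.
#'   * simulate: `n_train` (default 2000), `n_test` (default 1000),
#'     `dataset` (`"training"` or `"test"` reference moments),
#'     `missing_rate`, `gold_missing_rate`.
#'   * derive: `training` (response matrix path; required when `gammas`
#'     non-empty), `gammas` (numeric vector), `constrained` (flag).
#'   * evaluate: `test` (response matrix path), `tables` (character vector
#'     of rule files), `report` (output stem, default `"report"`).
#'   * describe: `matrix` (response matrix path).
#' @return Invisibly, a character vector of the files written
#'   (`run_describe()` returns the summary tibble).
#' @name pipeline
NULL

resolve_instrument <- function(config) {
  if (is.null(config$instrument)) {
    comm_instrument()
  } else if (is_instrument(config$instrument)) {
    config$instrument
  } else {
    read_instrument(config$instrument)
  }
}

resolve_out <- function(config) {
  dir <- config$out_dir %||% "."
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

load_matrix <- function(path, spec, require_gold = FALSE) {
  if (is.null(path) || !file.exists(path)) {
    abort(sprintf("response matrix not found: %s", path %||% "<missing>"))
  }
  val <- validate_responses(read_responses(path), spec,
                            require_gold = require_gold)
  if (nrow(val$excluded) > 0) {
    inform(sprintf("%s: excluded %d of %d rows (%s).",
                   basename(path), nrow(val$excluded),
                   nrow(val$admitted) + nrow(val$excluded),
                   paste(unique(val$excluded$reason), collapse = " / ")))
  }
  if (nrow(val$admitted) == 0) {
    abort(sprintf("no admissible records remain in %s after exclusions.", path))
  }
  val$admitted
}

#' @rdname pipeline
#' @export
run_simulate <- function(config = list()) {
  spec <- resolve_instrument(config)
  out_dir <- resolve_out(config)
  seed <- as.integer(config$seed %||% 1L)
  dataset <- config$dataset %||% "training"
  n_train <- as.integer(config$n_train %||% 2000L)
  n_test <- as.integer(config$n_test %||% 1000L)
  targets <- comm_reference_moments(dataset)
  if (spec$n_items != nrow(targets)) {
    abort("the built-in reference moments fit the 17-item COMM only; supply explicit generator settings for other instruments.")
  }
  cfg_train <- calibrate_cohort(targets, spec, n = n_train, seed = seed)
  cfg_test <- cfg_train
  cfg_test$n <- n_test
  cfg_test$seed <- seed + 1L
  cfg_train$missing_rate <- config$missing_rate %||% 0
  cfg_test$missing_rate <- config$missing_rate %||% 0
  cfg_train$gold_missing_rate <- config$gold_missing_rate %||% 0
  cfg_test$gold_missing_rate <- config$gold_missing_rate %||% 0
  paths <- c(
    train = file.path(out_dir, "train.csv"),
    test = file.path(out_dir, "test.csv")
  )
  write_responses(generate_cohort(cfg_train), paths["train"])
  write_responses(generate_cohort(cfg_test), paths["test"])
  inform(sprintf("wrote %s and %s (seed %d).",
                 paths["train"], paths["test"], seed))
  invisible(unname(paths))
}

#' @rdname pipeline
#' @export
run_derive <- function(config = list()) {
  spec <- resolve_instrument(config)
  out_dir <- resolve_out(config)
  gammas <- as.numeric(config$gammas %||% numeric())
  constrained <- isTRUE(config$constrained)
  written <- character()

  curt <- curtailment_boundaries(spec)
  p <- file.path(out_dir, "curtailment.csv")
  write_rule(curt, p)
  written <- c(written, p)

  if (length(gammas)) {
    if (is.null(config$training)) {
      abort("stochastic-curtailment thresholds were requested but no `training` matrix was given.")
    }
    training <- load_matrix(config$training, spec)
    models <- fit_stage_models(training, spec)
    if (any(models$separation)) {
      inform(sprintf("separation detected at stages %s; empirical fallback used.",
                     paste(models$stage[models$separation], collapse = ", ")))
    }
    mp <- file.path(out_dir, "stage_models.json")
    write_stage_models(models, mp)
    written <- c(written, mp)
    for (g in gammas) {
      rule <- sc_boundaries(models, g, spec)
      p <- file.path(out_dir, sprintf("sc%02d.csv", round(100 * g)))
      write_rule(rule, p)
      written <- c(written, p)
      if (constrained) {
        pc <- file.path(out_dir,
                        sprintf("sc%02d_constrained.csv", round(100 * g)))
        write_rule(constrain_monotone(rule, spec), pc)
        written <- c(written, pc)
      }
    }
  }
  inform(sprintf("wrote %d file(s) to %s.", length(written), out_dir))
  invisible(written)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(config = list()) {
  spec <- resolve_instrument(config)
  out_dir <- resolve_out(config)
  if (is.null(config$tables) || !length(config$tables)) {
    abort("`tables` must list at least one rule file.")
  }
  rules <- purrr::map(as.character(config$tables),
                      function(p) read_rule(p, spec))
  test <- load_matrix(config$test, spec,
                      require_gold = isTRUE(config$require_gold))
  report <- compare_rules(test, rules, spec)
  stem <- config$report %||% "report"
  csv_path <- file.path(out_dir, paste0(stem, ".csv"))
  json_path <- file.path(out_dir, paste0(stem, ".json"))
  write_report(report, csv_path, json_path)
  print_report(report)
  invisible(c(csv_path, json_path))
}

#' @rdname pipeline
#' @export
run_describe <- function(config = list()) {
  spec <- resolve_instrument(config)
  data <- load_matrix(config$matrix, spec)
  out <- describe_items(data, spec, digits = 1)
  print(as.data.frame(out), row.names = FALSE)
  invisible(out)
}

# aligned text rendering of a comparison grid (stdout)
print_report <- function(report) {
  cols <- c("method", "sens_full", "spec_full", "sens_gold", "spec_gold",
            "asn_mean", "asn_sd", "pct_early")
  x <- as.data.frame(report[cols])
  for (cc in cols[-1]) x[[cc]] <- format(round(x[[cc]], 3), nsmall = 1)
  print(x, row.names = FALSE)
  invisible(report)
}

#' Load a run configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration for the pipeline
#' runners and merges overrides on top; override values win.
#'
#' @param path Path to the configuration file, or `NULL` for an empty base.
#' @param overrides A named list of values taking precedence.
#' @return A named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  base <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(base)) abort("configuration file must hold a mapping.")
  modifyList(base, overrides)
}
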