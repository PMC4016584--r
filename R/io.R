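#' Read and write response matrices
#'
#' Response matrices travel as comma-delimited text with header
#' `respondent_id,item_1,...,item_n[,gold]` and empty fields for missing
#' cells. `write_responses()` prepends `#`-prefixed header comments carrying
#' the generator seed and config hash when the tibble has them (as cohorts
#' from [generate_cohort()] do); `read_responses()` skips comment lines.
#' A write/read/write cycle is byte-identical.
#'
#' @param data A response tibble.
#' @param path File path.
#' @return `read_responses()` returns a tibble; `write_responses()` returns
#'   `path` invisibly.
#' @export
write_responses <- function(data, path) {
  header <- character()
  if (!is.null(attr(data, "seed"))) {
    header <- c(header, sprintf("# seed: %d", attr(data, "seed")))
  }
  if (!is.null(attr(data, "config_hash"))) {
    header <- c(header, sprintf("# config_hash: %s", attr(data, "config_hash")))
  }
  body <- readr::format_csv(as_tibble(data), na = "")
  readr::write_lines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  lines <- readr::read_lines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  out <- readr::read_csv(
    I(paste0(paste(body, collapse = "\n"), "\n")),
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      .default = readr::col_integer()
    ),
    na = ""
  )
  seed_line <- grep("^# seed:", meta, value = TRUE)
  if (length(seed_line)) {
    attr(out, "seed") <- as.integer(sub("^# seed:\\s*", "", seed_line[1]))
  }
  hash_line <- grep("^# config_hash:", meta, value = TRUE)
  if (length(hash_line)) {
    attr(out, "config_hash") <- sub("^# config_hash:\\s*", "", hash_line[1])
  }
  out
}

#' Read and write stopping-rule tables
#'
#' Rule tables travel as comma-delimited text with header
#' `stage,neg_max,pos_min`, an empty field for an absent ("N/A") boundary,
#' and `#`-prefixed header comments recording the method, gamma, constrained
#' flag, cutoff and item count. A write/read/write cycle is byte-identical,
#' including absent cells.
#'
#' @param rule A `"curtail_rule"` table.
#' @param path File path.
#' @return `read_rule()` returns a `"curtail_rule"`; `write_rule()` returns
#'   `path` invisibly.
#' @export
write_rule <- function(rule, path) {
  meta <- rule_meta(rule)
  header <- c(
    sprintf("# method: %s", meta$method),
    sprintf("# gamma: %s", ifelse(is.na(meta$gamma), "NA",
                                  format(meta$gamma, digits = 15))),
    sprintf("# constrained: %s", meta$constrained),
    sprintf("# cutoff: %d", meta$cutoff),
    sprintf("# n_items: %d", meta$n_items)
  )
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  rows <- paste(rule$stage, fmt(rule$neg_max), fmt(rule$pos_min), sep = ",")
  readr::write_lines(c(header, "stage,neg_max,pos_min", rows), path)
  invisible(path)
}

#' @rdname write_rule
#' @param spec The [instrument()] the table belongs to (used to re-validate
#'   boundaries on read).
#' @export
read_rule <- function(path, spec) {
  check_instrument(spec)
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(sprintf("^# %s:", key), meta_lines, value = TRUE)
    if (!length(ln)) abort(sprintf("rule file lacks the `%s` header.", key))
    sub(sprintf("^# %s:\\s*", key), "", ln[1])
  }
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[body != ""]
  if (!identical(body[1], "stage,neg_max,pos_min")) {
    abort("rule file must have header `stage,neg_max,pos_min`.")
  }
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  num <- function(i) {
    vapply(cells, function(x) {
      v <- if (length(x) >= i) x[i] else ""
      if (v == "") NA_integer_ else as.integer(v)
    }, integer(1))
  }
  n_items <- as.integer(get_meta("n_items"))
  cutoff <- as.integer(get_meta("cutoff"))
  if (n_items != spec$n_items || cutoff != spec$cutoff) {
    abort("rule file and instrument disagree on n_items or cutoff.")
  }
  boundary_rule(
    stage = num(1), neg_max = num(2), pos_min = num(3), spec = spec,
    method = get_meta("method"),
    gamma = suppressWarnings(as.numeric(get_meta("gamma"))),
    constrained = as.logical(get_meta("constrained"))
  )
}

#' Read and write stage-model files
#'
#' Persists fitted per-stage models as JSON (intercept, slope, fit method,
#' separation flag, training size, and the empirical lookup for fallback
#' stages), so boundary tables can be re-extracted at new thresholds without
#' refitting.
#'
#' @param models A `"stage_models"` tibble.
#' @param path File path.
#' @return `read_stage_models()` returns a `"stage_models"` tibble;
#'   `write_stage_models()` returns `path` invisibly.
#' @export
write_stage_models <- function(models, path) {
  payload <- list(
    n_items = attr(models, "n_items"),
    cutoff = attr(models, "cutoff"),
    positive_rate = attr(models, "positive_rate"),
    stages = purrr::pmap(models, function(stage, intercept, slope, fit_method,
                                          separation, n_train, empirical) {
      list(
        stage = stage, intercept = intercept, slope = slope,
        fit_method = fit_method, separation = separation, n_train = n_train,
        empirical = if (is.null(empirical)) NULL else {
          list(score = empirical$score, prob = empirical$prob)
        }
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_stage_models
#' @export
read_stage_models <- function(path) {
  payload <- jsonlite::read_json(path)
  rows <- purrr::map(payload$stages, function(s) {
    tibble(
      stage = as.integer(s$stage),
      intercept = if (is.null(s$intercept)) NA_real_ else as.numeric(s$intercept),
      slope = if (is.null(s$slope)) NA_real_ else as.numeric(s$slope),
      fit_method = s$fit_method,
      separation = isTRUE(s$separation),
      n_train = as.integer(s$n_train),
      empirical = list(if (is.null(s$empirical)) NULL else {
        tibble(
          score = as.integer(unlist(s$empirical$score)),
          prob = as.numeric(unlist(s$empirical$prob))
        )
      })
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("stage_models", class(out))
  attr(out, "n_items") <- as.integer(payload$n_items)
  attr(out, "cutoff") <- as.integer(payload$cutoff)
  attr(out, "positive_rate") <- as.numeric(payload$positive_rate)
  out
}

#' Read and write instrument definitions
#'
#' Instrument definitions travel as YAML with keys `n_items`, `item_min`,
#' `item_max` (scalar or per-item list) and `cutoff`.
#'
#' @param spec An [instrument()].
#' @param path File path.
#' @return `read_instrument()` returns an [instrument()];
#'   `write_instrument()` returns `path` invisibly.
#' @export
write_instrument <- function(spec, path) {
  check_instrument(spec)
  payload <- list(
    n_items = spec$n_items,
    item_min = collapse_uniform(spec$item_min),
    item_max = collapse_uniform(spec$item_max),
    cutoff = spec$cutoff
  )
  if (!is.null(spec$item_labels)) payload$item_labels <- spec$item_labels
  yaml::write_yaml(payload, path)
  invisible(path)
}

collapse_uniform <- function(x) if (length(unique(x)) == 1L) x[1] else x

#' @rdname write_instrument
#' @export
read_instrument <- function(path) {
  payload <- yaml::read_yaml(path)
  for (key in c("n_items", "item_min", "item_max", "cutoff")) {
    if (is.null(payload[[key]])) {
      abort(sprintf("instrument file lacks the `%s` key.", key))
    }
  }
  instrument(
    n_items = payload$n_items,
    item_min = unlist(payload$item_min),
    item_max = unlist(payload$item_max),
    cutoff = payload$cutoff,
    item_labels = if (!is.null(payload$item_labels)) {
      unlist(payload$item_labels)
    }
  )
}

#' Write an operating-characteristic report
#'
#' Writes a [compare_rules()] (or [evaluate_rule()]) report as delimited
#' text (concordance cells flattened to `full_tp`-style columns) and/or
#' JSON mirroring the grid layout.
#'
#' @param report A report tibble.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The flattened tibble, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  flat <- flatten_report(report)
  if (!is.null(csv_path)) readr::write_csv(flat, csv_path, na = "")
  if (!is.null(json_path)) {
    jsonlite::write_json(flat, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(flat)
}

flatten_report <- function(report) {
  base <- select(report, -"counts")
  cells <- purrr::map_dfr(report$counts, function(cc) {
    wide <- tidyr::pivot_wider(
      tidyr::pivot_longer(cc, c("tp", "fn", "fp", "tn"),
                          names_to = "cell", values_to = "count"),
      names_from = c("comparison", "cell"), values_from = "count",
      names_sep = "_"
    )
    wide
  })
  dplyr::bind_cols(base, cells)
}
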