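#' Plot a stopping-rule table
#'
#' Draws the per-stage stopping boundaries as step lines over the attainable
#' cumulative-score band: scores at or below the negative line stop with a
#' negative decision, scores at or above the positive line stop positive,
#' and the region between continues to the next item.
#'
#' @param object A `"curtail_rule"` table.
#' @param spec The matching [instrument()] (draws the attainable band).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.curtail_rule <- function(object, spec = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$stage))
  if (!is.null(spec)) {
    check_instrument(spec)
    band <- tibble(stage = df$stage, lo = cum_min(spec), hi = cum_max(spec))
    p <- p + ggplot2::geom_ribbon(
      data = band,
      ggplot2::aes(x = .data$stage, ymin = .data$lo, ymax = .data$hi),
      inherit.aes = FALSE, fill = "grey92"
    )
  }
  p +
    ggplot2::geom_step(ggplot2::aes(y = .data$neg_max,
                                    colour = "stop negative (score <=)"),
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$pos_min,
                                    colour = "stop positive (score >=)"),
                       na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$neg_max,
                                     colour = "stop negative (score <=)"),
                        na.rm = TRUE, size = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pos_min,
                                     colour = "stop positive (score >=)"),
                        na.rm = TRUE, size = 1) +
    ggplot2::scale_colour_manual(
      values = c("stop negative (score <=)" = "#2166ac",
                 "stop positive (score >=)" = "#b2182b"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "items completed (stage)", y = "cumulative score",
      title = sprintf("Stopping boundaries: %s", rule_label(object))
    ) +
    ggplot2::theme_minimal()
}

#' Plot fitted stage probabilities
#'
#' Curves of the estimated probability of a positive full-length result as a
#' function of the cumulative score, one per interim stage (step functions
#' for empirical-fallback stages).
#'
#' @param models A `"stage_models"` tibble.
#' @param spec The matching [instrument()].
#' @param stages Which stages to draw (default: all interim stages).
#' @return A ggplot object.
#' @export
plot_stage_probabilities <- function(models, spec, stages = NULL) {
  check_instrument(spec)
  stages <- stages %||% models$stage
  cmin <- cum_min(spec)
  cmax <- cum_max(spec)
  df <- purrr::map_dfr(stages, function(k) {
    s <- seq.int(cmin[k], cmax[k])
    tibble(stage = factor(k), score = s,
           prob = estimate_probability(models, k, s))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$prob,
                                   colour = .data$stage)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cumulative score", y = "P(full-length positive)",
                  colour = "stage") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an operating-characteristic comparison
#'
#' Mean test length (with an SD whisker) and the percentage of early stops,
#' per method, from a [compare_rules()] report.
#'
#' @param report A report tibble from [compare_rules()].
#' @return A ggplot object.
#' @export
plot_comparison <- function(report) {
  df <- mutate(report, method = factor(.data$method,
                                       levels = rev(report$method)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$asn_mean, y = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = pmax(.data$asn_mean - .data$asn_sd, 0),
      xmax = .data$asn_mean + .data$asn_sd
    )) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%% early", .data$pct_early)
    ), vjust = -1, size = 3) +
    ggplot2::labs(x = "mean items administered (+/- SD)", y = NULL) +
    ggplot2::theme_minimal()
}
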