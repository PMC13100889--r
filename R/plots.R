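#' Plot TSS distributions by resolution level
#'
#' Boxplots of independent-test TSS across species for each modelled
#' resolution, the standard view for judging whether skill shifts with
#' spatial grain.
#'
#' @param evaluation The `evaluation` tibble of a [run_pipeline()] result
#'   (columns `species_id`, `level`, `test_tss`).
#' @return A ggplot object.
#' @export
plot_tss_by_level <- function(evaluation) {
  ggplot2::ggplot(evaluation,
                  ggplot2::aes(x = factor(.data$level), y = .data$test_tss)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "Resolution level", y = "Independent-test TSS") +
    ggplot2::theme_minimal()
}

#' Plot permutation variable importance by level
#'
#' @param importance The `importance` tibble of a run (columns `level`,
#'   `variable`, `importance`).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ord <- importance |>
    group_by(.data$variable) |>
    summarise(m = median(.data$importance), .groups = "drop") |>
    arrange(.data$m)
  importance |>
    mutate(variable = factor(.data$variable, levels = ord$variable)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$variable, y = .data$importance,
                                 fill = factor(.data$level))) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.size = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Permutation importance (1 - r)",
                  fill = "Level") +
    ggplot2::theme_minimal()
}

#' Plot predicted and observed range sizes by level
#'
#' Paired boxplots of predicted and observed range size (km^2, log scale)
#' per resolution level, plus the relative-difference panel.
#'
#' @param ranges The `ranges` tibble of a run.
#' @return A ggplot object.
#' @export
plot_range_sizes <- function(ranges) {
  long <- ranges |>
    select("species_id", "level", predicted = "predicted_km2",
           observed = "observed_km2") |>
    tidyr::pivot_longer(c("predicted", "observed"), names_to = "kind",
                        values_to = "km2")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$level), y = .data$km2,
                                     fill = .data$kind)) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Resolution level", y = expression(Range~size~(km^2)),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_range_sizes
#' @export
plot_range_reldiff <- function(ranges) {
  ggplot2::ggplot(ranges,
                  ggplot2::aes(x = factor(.data$level), y = .data$rel_diff)) +
    ggplot2::geom_boxplot(fill = "darkorange", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Resolution level",
                  y = "(predicted - observed) / observed") +
    ggplot2::theme_minimal()
}

#' Member skill profile of an ensemble
#'
#' @param object An `ensemble_sdm`.
#' @param ... Unused.
#' @return A ggplot object showing each member's cross-validated TSS and its
#'   ensemble weight.
#' @export
autoplot.ensemble_sdm <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("cv_tss", "weight"), names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$member,
                                                     .data$value),
                                  y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s at level %d", object$species_id,
                                  object$level)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
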