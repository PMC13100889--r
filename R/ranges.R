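#' Observed range of a species at a resolution level
#'
#' The observed range is the set of basins at `level` containing at least one
#' cleaned occurrence record of the species, and its size is the summed area
#' of those basins. Because finer occupied basins nest inside coarser
#' occupied basins, observed range size never increases when moving to a
#' finer level.
#'
#' @param occ An `occurrence_set` from [clean_occurrences()].
#' @param h The [basin_hierarchy()].
#' @param species Species id.
#' @param level Modelled level.
#' @return List with `basins` (character) and `km2` (summed area).
#' @export
observed_range <- function(occ, h, species, level) {
  basins <- presences_at_level(occ, h, species, level)
  units <- basins_at_level(h, level)
  km2 <- sum(units$area[units$basin_id %in% basins])
  list(basins = basins, km2 = km2)
}

#' Relative difference between predicted and observed range size
#'
#' `(predicted - observed) / observed`: 0 when they agree, positive when the
#' model predicts a larger range than the records support, bounded below by
#' -1. No clamping is applied.
#'
#' @param predicted_km2,observed_km2 Range sizes in km^2; `observed_km2`
#'   must be positive.
#' @return A single number.
#' @export
#' @examples
#' relative_difference(887.5, 710) # 0.25
relative_difference <- function(predicted_km2, observed_km2) {
  if (observed_km2 <= 0) {
    stop_basinsdm("basinsdm_bad_argument", "observed range must be positive")
  }
  (predicted_km2 - observed_km2) / observed_km2
}

#' Predicted range and its comparison with the observed range
#'
#' Predicts probability of occurrence for every basin at the model's level
#' whose macro-basin (level 4) holds at least one focal occurrence -- the
#' range constraint -- binarises at the model's max-TSS threshold
#' (`poo >= threshold` marks presence), and sums the areas of the predicted
#' basins. The observed counterpart comes from [observed_range()] on all
#' cleaned records.
#'
#' @param m An `ensemble_sdm` (refit on all training data, with its training
#'   threshold).
#' @param predictors A [predictor_table()] at the model's level.
#' @param h The [basin_hierarchy()].
#' @param occ The `occurrence_set` used to fit the model.
#' @return A one-row tibble `(species_id, level, predicted_km2, observed_km2,
#'   rel_diff, n_predicted, n_observed)` with list-columns
#'   `predicted_basins` and `observed_basins`.
#' @export
predict_range <- function(m, predictors, h, occ) {
  level <- m$level
  obs <- observed_range(occ, h, m$species_id, level)
  anc4 <- ancestor_map(h, level, 4L)
  occupied4 <- unique(unname(anc4[obs$basins]))
  units <- basins_at_level(h, level)
  domain <- units$basin_id[unname(anc4[units$basin_id]) %in% occupied4]
  poo <- predict_ensemble(m, predictors, domain)
  predicted <- poo$basin_id[poo$poo >= m$threshold]
  pred_km2 <- sum(units$area[units$basin_id %in% predicted])
  tibble(
    species_id = m$species_id, level = level,
    predicted_km2 = pred_km2, observed_km2 = obs$km2,
    rel_diff = relative_difference(pred_km2, obs$km2),
    n_predicted = length(predicted), n_observed = length(obs$basins),
    predicted_basins = list(predicted), observed_basins = list(obs$basins))
}

#' Summarise range sizes across species
#'
#' Medians and 95% ranges (linear-interpolation quantiles) of predicted and
#' observed range size and of their relative difference, per level.
#'
#' @param range_table Output rows of [predict_range()] bound together.
#' @return Tibble with one row per level.
#' @export
summarise_ranges <- function(range_table) {
  q <- function(x, p) unname(quantile(x, p, type = 7))
  as_tibble(range_table) |>
    group_by(.data$level) |>
    summarise(
      n_species = dplyr::n(),
      predicted_median = median(.data$predicted_km2),
      predicted_lo = q(.data$predicted_km2, 0.025),
      predicted_hi = q(.data$predicted_km2, 0.975),
      observed_median = median(.data$observed_km2),
      observed_lo = q(.data$observed_km2, 0.025),
      observed_hi = q(.data$observed_km2, 0.975),
      rel_diff_median = median(.data$rel_diff),
      rel_diff_lo = q(.data$rel_diff, 0.025),
      rel_diff_hi = q(.data$rel_diff, 0.975),
      .groups = "drop")
}
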