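#' Aggregate a predictor table to a coarser resolution level
#'
#' Coarsens per-basin predictors up the basin hierarchy: `mean`- and
#' `fraction`-kind variables take the area-weighted mean of their child
#' values (child basins proxy equal-resolution grid cells of unequal extent),
#' and `density`-kind variables take total count over total area, which is
#' again the area-weighted mean of child densities. Aggregating to the
#' table's own level is the identity.
#'
#' @param fine A [predictor_table()] at a level nested within `target_level`.
#' @param h The [basin_hierarchy()] relating the levels.
#' @param target_level Coarser modelled level to aggregate to.
#' @return A [predictor_table()] at `target_level` with the same schema.
#' @export
#' @examples
#' h <- sim_hierarchy(2, c(3, 2), seed = 1)
#' fine <- sim_predictors(h, seed = 2)
#' agg <- aggregate_to_level(fine, h, 8)
aggregate_to_level <- function(fine, h, target_level) {
  target_level <- as.integer(target_level)
  if (!target_level %in% h$levels) {
    stop_basinsdm("basinsdm_unknown_level",
                  sprintf("target level %d is not modelled", target_level))
  }
  if (target_level > fine$level) {
    stop_basinsdm("basinsdm_bad_argument",
                  sprintf("target level %d is finer than the table's level %d",
                          target_level, fine$level))
  }
  if (target_level == fine$level) return(fine)
  anc <- ancestor_map(h, fine$level, target_level)
  areas <- basins_at_level(h, fine$level) |> select("basin_id", "area")
  vars <- predictor_vars(fine)
  agg <- fine$values |>
    left_join(areas |> rename(.area = "area"), by = "basin_id") |>
    mutate(.group = unname(anc[.data$basin_id])) |>
    group_by(.data$.group) |>
    summarise(across(all_of(vars),
                     ~ sum(.x * .data$.area) / sum(.data$.area)),
              .groups = "drop") |>
    rename(basin_id = ".group")
  # every basin at the target level must have a complete row
  target_ids <- basins_at_level(h, target_level)$basin_id
  if (!setequal(agg$basin_id, target_ids)) {
    stop_basinsdm("basinsdm_missing_values",
                  "aggregated table does not cover every target-level basin")
  }
  predictor_table(agg, fine$schema, target_level,
                  provenance = c(fine$provenance,
                                 list(aggregated_from = fine$level,
                                      scheme = "area-weighted mean")))
}

#' Add upstream/downstream neighbour predictors
#'
#' Builds the pressure-propagation covariates: for `direction = "upstream"`
#' the new column `<variable>_up` is the unweighted mean of the variable over
#' the one-step upstream neighbours (0 for headwaters, where absent upstream
#' pressure is a meaningful zero); for `direction = "downstream"`,
#' `<variable>_down` is the value in the adjacent downstream unit (0 at
#' outlets).
#'
#' @param t A [predictor_table()].
#' @param h The [basin_hierarchy()].
#' @param specs Data frame with columns `variable` and `direction`
#'   (`"upstream"` or `"downstream"`).
#' @return A [predictor_table()] with the neighbour columns appended; the new
#'   columns inherit the source variable's schema kind, except fractions
#'   become `mean` (a neighbour mean of fractions is no longer a fraction of
#'   the focal unit).
#' @export
add_neighbor_predictors <- function(t, h, specs) {
  specs <- as_tibble(specs)
  units <- basins_at_level(h, t$level) |> select("basin_id", "next_down_id")
  vals <- t$values |> left_join(units, by = "basin_id")
  if (anyNA(vals$basin_id)) {
    stop_basinsdm("basinsdm_bad_table", "table basins missing from hierarchy")
  }
  new_schema <- list(t$schema)
  for (i in seq_len(nrow(specs))) {
    v <- specs$variable[i]
    dir <- specs$direction[i]
    if (!v %in% predictor_vars(t)) {
      stop_basinsdm("basinsdm_missing_predictor",
                    sprintf("variable '%s' not in the table", v))
    }
    if (dir == "upstream") {
      up <- vals |>
        filter(!is.na(.data$next_down_id)) |>
        group_by(basin_id = .data$next_down_id) |>
        summarise(.up = mean(.data[[v]]), .groups = "drop")
      newcol <- paste0(v, "_up")
      vals <- vals |>
        left_join(up, by = "basin_id") |>
        mutate(!!newcol := tidyr::replace_na(.data$.up, 0)) |>
        select(-".up")
    } else if (dir == "downstream") {
      down <- vals |> select(next_down_id = "basin_id", .down = all_of(v))
      newcol <- paste0(v, "_down")
      vals <- vals |>
        left_join(down, by = "next_down_id") |>
        mutate(!!newcol := tidyr::replace_na(.data$.down, 0)) |>
        select(-".down")
    } else {
      stop_basinsdm("basinsdm_bad_argument",
                    sprintf("unknown direction '%s'", dir))
    }
    kind <- t$schema$kind[t$schema$variable == v]
    new_schema[[i + 1L]] <- tibble(
      variable = newcol,
      kind = if (kind == "fraction") "mean" else kind,
      unit = t$schema$unit[t$schema$variable == v])
  }
  predictor_table(vals |> select(-"next_down_id"), bind_rows(new_schema),
                  t$level, provenance = t$provenance)
}

#' Screen predictors for collinearity
#'
#' Implements the standard pairwise Pearson screen: variables are considered
#' in a priority order and whenever a pair reaches `|r| >= threshold` the
#' lower-priority member is dropped, so the retained set has all pairwise
#' `|r|` below the threshold. Zero-variance variables are excluded up front
#' with their own reason code because their correlation is undefined.
#'
#' @param t A [predictor_table()] (or a plain data frame of numeric columns
#'   plus `basin_id`).
#' @param threshold Absolute Pearson correlation at or above which a pair is
#'   collinear. Default 0.7, the conventional screening cut.
#' @param priority Character vector ordering variables from most to least
#'   preferred; unlisted variables follow in column order.
#' @return A list with `retained` (character vector) and `report`, a tibble
#'   `(variable, partner, r, action)` with one row per variable
#'   (`kept`, `dropped`, or `zero_variance`).
#' @export
collinearity_filter <- function(t, threshold = 0.7, priority = character()) {
  vals <- if (inherits(t, "predictor_table")) t$values else as_tibble(t)
  vars <- setdiff(names(vals), "basin_id")
  if (nrow(vals) < 2L) {
    stop_basinsdm("basinsdm_bad_argument",
                  "need at least 2 basins to estimate correlations")
  }
  ord <- c(intersect(priority, vars), setdiff(vars, priority))
  x <- as.matrix(vals[ord])
  sds <- apply(x, 2, sd)
  zero_var <- ord[sds == 0]
  live <- setdiff(ord, zero_var)
  report <- list()
  for (v in zero_var) {
    report[[v]] <- tibble(variable = v, partner = NA_character_, r = NA_real_,
                          action = "zero_variance")
  }
  retained <- character()
  dropped <- character()
  for (v in live) {
    if (v %in% dropped) next
    retained <- c(retained, v)
    report[[v]] <- tibble(variable = v, partner = NA_character_, r = NA_real_,
                          action = "kept")
    rest <- setdiff(live, c(retained, dropped))
    for (w in rest) {
      r <- cor(x[, v], x[, w])
      if (abs(r) >= threshold) {
        dropped <- c(dropped, w)
        report[[w]] <- tibble(variable = w, partner = v, r = r,
                              action = "dropped")
      }
    }
  }
  list(retained = retained,
       report = bind_rows(report[c(zero_var, live)]))
}

#' Between- vs within-basin variance decomposition
#'
#' One-way decomposition of a fine-level predictor grouped by the containing
#' unit at a coarser level: `ss_between = sum_g n_g (xbar_g - xbar)^2`,
#' `ss_within = sum_g sum_i (x_gi - xbar_g)^2`. Used to ask whether a
#' variable's spatial variation lives mostly between coarse basins (in which
#' case averaging within them loses little signal) or within them.
#'
#' @param fine A [predictor_table()] at a fine level.
#' @param h The [basin_hierarchy()].
#' @param group_level Coarser level whose units define the groups.
#' @param variable Variable name to decompose.
#' @return A one-row tibble `(variable, group_level, ss_between, ss_within,
#'   prop_between, prop_within, degenerate)`. When all values are identical
#'   both sums of squares are 0; proportions are reported as 0 with
#'   `degenerate = TRUE`.
#' @export
variance_decomposition <- function(fine, h, group_level, variable) {
  if (!variable %in% predictor_vars(fine)) {
    stop_basinsdm("basinsdm_missing_predictor",
                  sprintf("variable '%s' not in the table", variable))
  }
  anc <- ancestor_map(h, fine$level, group_level)
  x <- fine$values[[variable]]
  g <- unname(anc[fine$values$basin_id])
  xbar <- mean(x)
  by_g <- tibble(x = x, g = g) |>
    group_by(.data$g) |>
    summarise(n = dplyr::n(), m = mean(.data$x),
              ssw = sum((.data$x - mean(.data$x))^2), .groups = "drop")
  ss_between <- sum(by_g$n * (by_g$m - xbar)^2)
  ss_within <- sum(by_g$ssw)
  total <- ss_between + ss_within
  degenerate <- total == 0
  tibble(variable = variable, group_level = as.integer(group_level),
         ss_between = ss_between, ss_within = ss_within,
         prop_between = if (degenerate) 0 else ss_between / total,
         prop_within = if (degenerate) 0 else ss_within / total,
         degenerate = degenerate)
}

#' Read and write predictor tables
#'
#' Values travel as a CSV (`basin_id` plus one column per variable); the
#' schema travels as a YAML sidecar mapping each variable to its kind and
#' unit, with the table's level.
#'
#' @param t A [predictor_table()].
#' @param path CSV path for the values.
#' @param schema_path YAML path for the schema; defaults to `path` with a
#'   `.yml` extension.
#' @return `write_predictor_table()` returns `path` invisibly;
#'   `read_predictor_table()` returns a [predictor_table()].
#' @export
write_predictor_table <- function(t, path,
                                  schema_path = sub("\\.csv$", ".yml", path)) {
  readr::write_csv(t$values, path)
  yaml::write_yaml(list(
    level = t$level,
    variables = purrr::pmap(t$schema, function(variable, kind, unit)
      list(name = variable, kind = kind, unit = unit))
  ), schema_path)
  invisible(path)
}

#' @rdname write_predictor_table
#' @export
read_predictor_table <- function(path,
                                 schema_path = sub("\\.csv$", ".yml", path)) {
  meta <- yaml::read_yaml(schema_path)
  schema <- purrr::map(meta$variables, ~ tibble(
    variable = .x$name, kind = .x$kind, unit = .x$unit)) |> list_rbind()
  vals <- readr::read_csv(path, col_types = readr::cols(
    basin_id = readr::col_character(), .default = readr::col_double()))
  predictor_table(vals, schema, meta$level,
                  provenance = list(source = path))
}

#' Average per-year predictor tables into a long-term mean
#'
#' Reads several per-year value CSVs (same basins and variables) and returns
#' their element-wise mean as one table, for predictors supplied as yearly
#' stacks over an observation window.
#'
#' @param paths CSV paths, one per year.
#' @param schema_path YAML schema shared by the yearly tables.
#' @return A [predictor_table()] of multi-year means.
#' @export
read_multiyear_mean <- function(paths, schema_path) {
  tabs <- lapply(paths, read_predictor_table, schema_path = schema_path)
  base <- tabs[[1]]
  vars <- predictor_vars(base)
  for (t in tabs[-1]) {
    if (!identical(t$values$basin_id, base$values$basin_id)) {
      stop_basinsdm("basinsdm_bad_table",
                    "yearly tables cover different basins")
    }
  }
  vals <- base$values
  for (v in vars) {
    vals[[v]] <- rowMeans(vapply(tabs, function(t) t$values[[v]],
                                 numeric(nrow(vals))))
  }
  predictor_table(vals, base$schema, base$level,
                  provenance = list(scheme = "multi-year mean",
                                    n_years = length(paths)))
}
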