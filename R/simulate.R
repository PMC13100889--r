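#' Simulate a nested basin hierarchy
#'
#' Generates a synthetic drainage landscape with the nested structure of
#' HydroBASINS-style units: `n_level4` macro-basins (level 4), each subdivided
#' by the given branching factors into successive fine levels labelled 8, 9,
#' 10, ... Unit areas are drawn log-normally and children are rescaled so they
#' partition their parent's area exactly; within every macro-basin the
#' same-level units are wired into a random drainage tree toward a single
#' outlet. Centroids are planar: macro-basins sit on a jittered grid and
#' children scatter around their parent, so nearby ids are spatial
#' neighbours.
#'
#' @param n_level4 Number of macro-basins (>= 1).
#' @param branching Integer vector, one subdivision factor per fine level.
#' @param seed Integer seed; the same seed reproduces the hierarchy exactly.
#' @param level4_median_km2 Median macro-basin area. The default mirrors the
#'   typical size of a European level-4 hydrobasin (about 50,000 km^2).
#' @param area_sdlog Log-scale spread of unit areas.
#' @return A [basin_hierarchy()] with levels `4, 8, 9, ...`.
#' @export
#' @examples
#' h <- sim_hierarchy(n_level4 = 2, branching = c(4, 2), seed = 7)
#' h
sim_hierarchy <- function(n_level4, branching, seed,
                          level4_median_km2 = 50364, area_sdlog = 0.4) {
  check_number(n_level4, "n_level4", min = 1)
  if (length(branching) < 1L || any(branching < 1)) {
    stop_basinsdm("basinsdm_bad_argument",
                  "`branching` must contain factors >= 1, one per fine level")
  }
  with_seed(seed, {
    n4 <- as.integer(n_level4)
    ncol_grid <- ceiling(sqrt(n4))
    gx <- ((seq_len(n4) - 1L) %% ncol_grid) * 10
    gy <- ((seq_len(n4) - 1L) %/% ncol_grid) * 10
    macro <- tibble(
      basin_id = sprintf("L4_%03d", seq_len(n4)),
      level = 4L,
      parent_id = NA_character_,
      next_down_id = NA_character_,
      area = stats::rlnorm(n4, log(level4_median_km2), area_sdlog),
      cx = gx + runif(n4, -1, 1),
      cy = gy + runif(n4, -1, 1)
    )
    levels_fine <- 8L + seq_along(branching) - 1L
    out <- list(macro)
    parent <- macro
    for (j in seq_along(branching)) {
      b <- as.integer(branching[j])
      lv <- levels_fine[j]
      kids <- purrr::pmap(parent, function(basin_id, area, cx, cy, ...) {
        w <- stats::rlnorm(b, 0, area_sdlog)
        # child dispersion shrinks with depth and scales with footprint
        r <- sqrt(area) / sqrt(level4_median_km2) * 4 / (1 + j)
        pid <- basin_id
        child_ids <- sprintf("%s.%d", pid, seq_len(b))
        tibble(
          basin_id = child_ids,
          level = lv,
          parent_id = pid,
          next_down_id = NA_character_,
          area = area * w / sum(w),
          cx = cx + rnorm(b, 0, r),
          cy = cy + rnorm(b, 0, r)
        )
      }) |> list_rbind()
      # random drainage tree per macro-basin: shuffle the units, the first is
      # the outlet, every later unit drains into a uniformly chosen earlier one
      kids$macro4 <- sub("\\..*$", "", kids$basin_id)
      kids <- kids |>
        group_by(.data$macro4) |>
        dplyr::group_modify(function(g, key) {
          ord <- sample.int(nrow(g))
          g <- g[ord, ]
          if (nrow(g) > 1L) {
            sink <- vapply(2:nrow(g), function(i) sample.int(i - 1L, 1L),
                           integer(1))
            g$next_down_id[-1L] <- g$basin_id[sink]
          }
          g
        }) |>
        ungroup() |>
        select(-"macro4")
      out[[j + 1L]] <- kids
      parent <- kids
    }
    basin_hierarchy(bind_rows(out))
  })
}

#' Predictor tables
#'
#' A `predictor_table` bundles per-basin predictor values at one resolution
#' level with a schema declaring how each variable aggregates when coarsened:
#' `mean` variables (temperature, streamflow, roughness) take area-weighted
#' means, `fraction` variables (cropland, built-up area) are area-weighted
#' fractions in `[0, 1]`, and `density` variables (dams per km^2) aggregate
#' as total count over total area, which equals the area-weighted mean of the
#' child densities.
#'
#' @param values Data frame with a `basin_id` column plus one numeric column
#'   per variable; one row per basin at `level`.
#' @param schema Data frame with columns `variable`, `kind`
#'   (`mean`/`fraction`/`density`) and `unit`.
#' @param level Integer resolution level of the rows.
#' @param provenance Optional list recording how the table was produced.
#' @return An object of class `predictor_table`.
#' @export
predictor_table <- function(values, schema, level, provenance = list()) {
  values <- as_tibble(values)
  schema <- as_tibble(schema)
  if (!"basin_id" %in% names(values)) {
    stop_basinsdm("basinsdm_bad_table", "predictor values need a basin_id column")
  }
  vars <- setdiff(names(values), "basin_id")
  if (!setequal(vars, schema$variable)) {
    stop_basinsdm("basinsdm_bad_table",
                  "schema variables do not match the value columns")
  }
  if (!all(schema$kind %in% c("mean", "fraction", "density"))) {
    stop_basinsdm("basinsdm_bad_table",
                  "schema kind must be one of mean, fraction, density")
  }
  if (anyNA(values[vars])) {
    stop_basinsdm("basinsdm_missing_values",
                  "predictor table has missing values")
  }
  frac <- schema$variable[schema$kind == "fraction"]
  for (v in frac) {
    if (any(values[[v]] < 0 | values[[v]] > 1)) {
      stop_basinsdm("basinsdm_bad_fraction",
                    sprintf("fraction variable '%s' outside [0, 1]", v))
    }
  }
  dens <- schema$variable[schema$kind == "density"]
  for (v in dens) {
    if (any(values[[v]] < 0)) {
      stop_basinsdm("basinsdm_bad_density",
                    sprintf("density variable '%s' is negative", v))
    }
  }
  structure(list(level = as.integer(level),
                 values = values[c("basin_id", sort(vars))],
                 schema = schema |> arrange(.data$variable),
                 provenance = provenance),
            class = "predictor_table")
}

#' @export
print.predictor_table <- function(x, ...) {
  cat("<predictor_table> level ", x$level, ": ", nrow(x$values), " basins x ",
      nrow(x$schema), " variables\n", sep = "")
  print(x$schema, n = Inf)
  invisible(x)
}

#' @export
tidy.predictor_table <- function(x, ...) x$values

predictor_vars <- function(pt) setdiff(names(pt$values), "basin_id")

#' Simulate spatially autocorrelated predictors
#'
#' Draws predictor fields over the finest-level basin centroids from a
#' multivariate Gaussian with an exponential distance-decay covariance
#' (`exp(-d / range_decay)`), realised exactly by one Cholesky factorisation
#' shared across variables. Continuous (`mean`-kind) variables are affine
#' transforms of a latent field, optionally exponentiated for positive
#' quantities; `fraction` variables are logistic transforms; dam counts are
#' Poisson draws with intensity proportional to an exponentiated latent field
#' times basin area, stored as a density (dams per km^2).
#'
#' @param h A [basin_hierarchy()].
#' @param vars List of variable specifications; see [default_predictor_vars()].
#' @param range_decay Length scale of the exponential covariance, in the
#'   hierarchy's planar map units (> 0).
#' @param seed Integer seed.
#' @return A [predictor_table()] at the finest modelled level.
#' @export
sim_predictors <- function(h, vars = default_predictor_vars(),
                           range_decay = 4, seed = 1) {
  check_number(range_decay, "range_decay", min = 1e-12)
  fine <- basins_at_level(h, max(h$levels))
  n <- nrow(fine)
  with_seed(seed, {
    d <- as.matrix(stats::dist(cbind(fine$cx, fine$cy)))
    K <- exp(-d / range_decay)
    L <- t(chol(K + diag(1e-8, n)))
    z <- L %*% matrix(rnorm(n * length(vars)), n, length(vars))
    cols <- list(basin_id = fine$basin_id)
    schema <- list()
    for (i in seq_along(vars)) {
      v <- vars[[i]]
      zi <- z[, i]
      val <- switch(v$kind,
        mean = if (isTRUE(v$log)) exp(v$mu + v$sigma * zi)
               else v$mu + v$sigma * zi,
        fraction = plogis(v$mu + v$sigma * zi),
        density = {
          counts <- rpois(n, exp(v$mu + v$sigma * zi) * fine$area * v$rate)
          counts / fine$area
        },
        stop_basinsdm("basinsdm_bad_argument",
                      sprintf("unknown variable kind '%s'", v$kind)))
      cols[[v$name]] <- val
      schema[[i]] <- tibble(variable = v$name, kind = v$kind, unit = v$unit)
    }
    predictor_table(as_tibble(cols), bind_rows(schema), max(h$levels),
                    provenance = list(scheme = "simulated",
                                      range_decay = range_decay, seed = seed))
  })
}

#' Default simulated predictor set
#'
#' Mirrors the predictor families used for European freshwater fish:
#' annual mean temperature (`bio1`, degrees C) and temperature annual range
#' (`bio7`, degrees C), minimum streamflow (`flow_min`, m^3/s), terrain
#' roughness (`roughness`, m), cropland and built-up fractions, and dam
#' density (dams per km^2).
#'
#' @return A list of variable specifications for [sim_predictors()].
#' @export
default_predictor_vars <- function() {
  list(
    list(name = "bio1", kind = "mean", unit = "degC", mu = 10, sigma = 4,
         log = FALSE),
    list(name = "bio7", kind = "mean", unit = "degC", mu = 25, sigma = 5,
         log = FALSE),
    list(name = "flow_min", kind = "mean", unit = "m3/s", mu = 1.5,
         sigma = 0.8, log = TRUE),
    list(name = "roughness", kind = "mean", unit = "m", mu = 3.2, sigma = 0.7,
         log = TRUE),
    list(name = "cropland", kind = "fraction", unit = "fraction", mu = -1,
         sigma = 1.5),
    list(name = "builtup", kind = "fraction", unit = "fraction", mu = -3,
         sigma = 1.2),
    list(name = "dam_density", kind = "density", unit = "dams/km2",
         mu = -0.5, sigma = 1, rate = 0.004)
  )
}

#' Gaussian niche specification for a virtual species
#'
#' Occurrence probability is a product of independent Gaussian responses,
#' `max_prob * prod_v exp(-(x_v - optimum_v)^2 / (2 * breadth_v^2))`, the
#' standard virtual-species bell response.
#'
#' @param species_id Species identifier.
#' @param optima Named numeric vector of niche optima (predictor units).
#' @param breadths Named numeric vector of positive Gaussian breadths.
#' @param max_prob Peak occurrence probability in `(0, 1]`.
#' @param prevalence_target Optional target mean occurrence probability across
#'   basins; when set, probabilities are rescaled toward it.
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, optima, breadths, max_prob = 1,
                       prevalence_target = NULL) {
  if (!setequal(names(optima), names(breadths))) {
    stop_basinsdm("basinsdm_bad_argument",
                  "optima and breadths must name the same variables")
  }
  if (any(breadths <= 0)) {
    stop_basinsdm("basinsdm_bad_argument", "breadths must be positive")
  }
  check_number(max_prob, "max_prob", min = 1e-12, max = 1)
  structure(list(species_id = species_id, optima = optima,
                 breadths = breadths[names(optima)], max_prob = max_prob,
                 prevalence_target = prevalence_target),
            class = "niche_spec")
}

#' Simulate true species occupancy from a niche
#'
#' @param h A [basin_hierarchy()].
#' @param predictors A [predictor_table()] at the finest level.
#' @param niche A [niche_spec()].
#' @param seed Integer seed.
#' @return Tibble `(species_id, basin_id, prob, occupied)` at the finest
#'   level; `occupied` is a Bernoulli draw from `prob`.
#' @export
sim_species <- function(h, predictors, niche, seed) {
  vars <- names(niche$optima)
  missing_vars <- setdiff(vars, predictor_vars(predictors))
  if (length(missing_vars)) {
    stop_basinsdm("basinsdm_missing_predictor",
                  paste0("niche variables not in predictor table: ",
                         paste(missing_vars, collapse = ", ")))
  }
  vals <- predictors$values
  p <- rep(niche$max_prob, nrow(vals))
  for (v in vars) {
    p <- p * exp(-(vals[[v]] - niche$optima[[v]])^2 /
                   (2 * niche$breadths[[v]]^2))
  }
  if (!is.null(niche$prevalence_target)) {
    target <- niche$prevalence_target
    f <- function(k) mean(pmin(1, k * p)) - target
    if (f(1 / max(p)) < 0) {
      warn(sprintf("prevalence target %.2f unattainable for %s; using max",
                   target, niche$species_id))
      p <- pmin(1, p / max(p))
    } else {
      k <- stats::uniroot(f, c(1e-9, 1 / max(p)))$root
      p <- pmin(1, k * p)
    }
  }
  with_seed(seed, tibble(
    species_id = niche$species_id,
    basin_id = vals$basin_id,
    prob = p,
    occupied = rbinom(nrow(vals), 1L, p) == 1L
  ))
}

#' Simulate a spatially biased sampling-effort field
#'
#' One effort surface is shared by every species, emulating the survey bias
#' of aggregated occurrence archives: where effort is high all species are
#' well recorded, where it is low all are under-recorded, which is exactly the
#' structure the target-group pseudoabsence approach exploits.
#'
#' @param h A [basin_hierarchy()].
#' @param range_decay Length scale of the effort field's autocorrelation.
#' @param sdlog Log-scale spatial variation of effort.
#' @param seed Integer seed.
#' @return Tibble `(basin_id, effort)` at the finest level, effort >= 0 with
#'   median 1.
#' @export
sim_effort <- function(h, range_decay = 6, sdlog = 0.8, seed = 1) {
  fine <- basins_at_level(h, max(h$levels))
  n <- nrow(fine)
  with_seed(seed, {
    d <- as.matrix(stats::dist(cbind(fine$cx, fine$cy)))
    L <- t(chol(exp(-d / range_decay) + diag(1e-8, n)))
    z <- as.vector(L %*% rnorm(n))
    tibble(basin_id = fine$basin_id, effort = exp(sdlog * z))
  })
}

#' Simulate biased occurrence records from true occupancy
#'
#' A species is recorded in an occupied basin with probability
#' `1 - exp(-detect_slope * effort)`; the shared effort field induces the
#' target-group structure across species. Detection only thins presences:
#' no false presences are generated. Each record carries a year drawn
#' uniformly from the observation window.
#'
#' @param truth Tibble of true occupancy as returned by [sim_species()]
#'   (rows for several species may be bound together).
#' @param effort Tibble `(basin_id, effort)` from [sim_effort()].
#' @param detect_slope Nonnegative detection rate per unit effort.
#' @param seed Integer seed.
#' @param window Integer year range for record dates.
#' @return Tibble of records `(species_id, basin_id, year)`.
#' @export
sim_occurrences <- function(truth, effort, detect_slope, seed,
                            window = c(1992L, 2015L)) {
  check_number(detect_slope, "detect_slope", min = 0)
  occ <- truth |>
    filter(.data$occupied) |>
    left_join(effort, by = "basin_id")
  if (anyNA(occ$effort)) {
    stop_basinsdm("basinsdm_bad_table",
                  "effort field does not cover every occupied basin")
  }
  with_seed(seed, {
    p_det <- 1 - exp(-detect_slope * occ$effort)
    hit <- runif(nrow(occ)) < p_det
    occ |>
      filter(hit) |>
      mutate(year = sample(seq(window[1], window[2]), dplyr::n(),
                           replace = TRUE)) |>
      select("species_id", "basin_id", "year")
  })
}
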