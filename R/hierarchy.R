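#' Nested basin hierarchies
#'
#' A `basin_hierarchy` holds hydrological basin units at several nested
#' resolution levels, in the style of the HydroBASINS product: a coarse
#' macro-basin level (conventionally level 4) subdivided into progressively
#' finer units (conventionally levels 8-12). Each unit knows its containing
#' parent at the next-coarser modelled level and, within its own level, the
#' adjacent unit immediately downstream, so the same-level drainage graph is a
#' forest of trees rooted at outlets.
#'
#' @param units A data frame with columns `basin_id` (character), `level`
#'   (integer), `parent_id` (character, `NA` at the coarsest level),
#'   `next_down_id` (character, `NA` for outlets), `area` (km^2, positive),
#'   and optionally centroid coordinates `cx`, `cy` (planar map units).
#' @return An object of class `basin_hierarchy`: a list with a `units` tibble
#'   and the sorted vector of modelled `levels`.
#' @details Validation enforces the structural invariants: positive areas,
#'   parent and downstream references resolving to declared units (downstream
#'   within the same level, parent at the next-coarser modelled level), child
#'   areas summing to their parent's area (relative tolerance 1e-6), an
#'   acyclic same-level downstream graph, and a complete parent chain from
#'   every fine unit up to a single macro-basin.
#' @export
#' @examples
#' units <- tibble::tibble(
#'   basin_id = c("M1", "a", "b"), level = c(4L, 8L, 8L),
#'   parent_id = c(NA, "M1", "M1"), next_down_id = c(NA, "b", NA),
#'   area = c(100, 60, 40))
#' h <- basin_hierarchy(units)
#' basin_levels(h)
basin_hierarchy <- function(units) {
  units <- as_tibble(units)
  req <- c("basin_id", "level", "parent_id", "next_down_id", "area")
  missing_cols <- setdiff(req, names(units))
  if (length(missing_cols)) {
    stop_basinsdm("basinsdm_bad_table",
                  paste0("basin table lacks columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  units <- units |>
    mutate(
      basin_id = as.character(.data$basin_id),
      level = as.integer(.data$level),
      parent_id = dplyr::na_if(as.character(.data$parent_id), ""),
      next_down_id = dplyr::na_if(as.character(.data$next_down_id), ""),
      area = as.double(.data$area)
    )
  if (!all(c("cx", "cy") %in% names(units))) {
    units$cx <- NA_real_
    units$cy <- NA_real_
  }
  units <- units |> select(all_of(c(req, "cx", "cy")))
  h <- structure(
    list(units = units, levels = sort(unique(units$level))),
    class = "basin_hierarchy"
  )
  validate_hierarchy(h)
  h
}

validate_hierarchy <- function(h) {
  u <- h$units
  if (anyDuplicated(paste(u$level, u$basin_id))) {
    dup <- u$basin_id[duplicated(paste(u$level, u$basin_id))][1]
    stop_basinsdm("basinsdm_bad_table",
                  sprintf("duplicate unit '%s' within one level", dup))
  }
  if (any(!is.finite(u$area) | u$area <= 0)) {
    bad <- u$basin_id[which(!is.finite(u$area) | u$area <= 0)[1]]
    stop_basinsdm("basinsdm_bad_area",
                  sprintf("unit '%s' has non-positive area", bad))
  }
  lv <- h$levels
  for (i in seq_along(lv)) {
    this <- u |> filter(.data$level == lv[i])
    ids <- this$basin_id
    # downstream links stay within the level
    nd <- this$next_down_id
    dangle <- nd[!is.na(nd) & !(nd %in% ids)]
    if (length(dangle)) {
      stop_basinsdm("basinsdm_dangling_reference",
                    sprintf("next_down_id '%s' at level %d is not a declared unit",
                            dangle[1], lv[i]))
    }
    check_downstream_acyclic(this, lv[i])
    # parent links go to the next-coarser modelled level
    if (i == 1L) {
      if (any(!is.na(this$parent_id))) {
        stop_basinsdm("basinsdm_bad_parent",
                      "units at the coarsest level must not declare a parent")
      }
    } else {
      parents <- u |> filter(.data$level == lv[i - 1L]) |> pull("basin_id")
      if (any(is.na(this$parent_id))) {
        orphan <- this$basin_id[which(is.na(this$parent_id))[1]]
        stop_basinsdm("basinsdm_bad_parent",
                      sprintf("unit '%s' at level %d has no parent", orphan, lv[i]))
      }
      miss <- this$parent_id[!(this$parent_id %in% parents)]
      if (length(miss)) {
        stop_basinsdm("basinsdm_dangling_reference",
                      sprintf("parent_id '%s' at level %d is not a level-%d unit",
                              miss[1], lv[i], lv[i - 1L]))
      }
      # area conservation: children partition their parent
      sums <- this |>
        group_by(.data$parent_id) |>
        summarise(child_area = sum(.data$area), .groups = "drop")
      par <- u |>
        filter(.data$level == lv[i - 1L]) |>
        select(parent_id = "basin_id", parent_area = "area")
      chk <- inner_join(sums, par, by = "parent_id") |>
        mutate(rel = abs(.data$child_area - .data$parent_area) /
                 .data$parent_area)
      if (any(chk$rel > 1e-6)) {
        bad <- chk |> arrange(dplyr::desc(.data$rel)) |> slice(1)
        stop_basinsdm(
          "basinsdm_area_mismatch",
          sprintf("children of '%s' sum to %.6g but parent area is %.6g",
                  bad$parent_id, bad$child_area, bad$parent_area))
      }
    }
  }
  invisible(h)
}

check_downstream_acyclic <- function(units_level, level) {
  nd <- setNames(units_level$next_down_id, units_level$basin_id)
  state <- setNames(integer(length(nd)), names(nd)) # 0 new, 1 active, 2 done
  for (start in names(nd)) {
    if (state[[start]] != 0L) next
    path <- character()
    node <- start
    while (!is.na(node) && state[[node]] == 0L) {
      state[[node]] <- 1L
      path <- c(path, node)
      node <- nd[[node]]
    }
    if (!is.na(node) && state[[node]] == 1L) {
      cyc <- c(path[which(path == node):length(path)], node)
      stop_basinsdm("basinsdm_cyclic_downstream",
                    sprintf("cyclic downstream graph at level %d: %s",
                            level, paste(cyc, collapse = " -> ")))
    }
    state[path] <- 2L
  }
  invisible(NULL)
}

#' @export
print.basin_hierarchy <- function(x, ...) {
  counts <- x$units |> dplyr::count(.data$level)
  cat("<basin_hierarchy> ", nrow(x$units), " units over levels ",
      paste(x$levels, collapse = ", "), "\n", sep = "")
  for (i in seq_len(nrow(counts))) {
    cat("  level ", counts$level[i], ": ", counts$n[i], " units\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @rdname basin_hierarchy
#' @param h,x A `basin_hierarchy`.
basin_levels <- function(h) h$levels

#' @export
#' @rdname basin_hierarchy
#' @param ... Passed on to methods.
tidy.basin_hierarchy <- function(x, ...) x$units

#' Units of a hierarchy at one level
#'
#' @param h A [basin_hierarchy()].
#' @param level Modelled level to extract.
#' @return Tibble of units at `level`.
#' @export
basins_at_level <- function(h, level) {
  if (!level %in% h$levels) {
    stop_basinsdm("basinsdm_unknown_level",
                  sprintf("level %s is not modelled (levels: %s)",
                          level, paste(h$levels, collapse = ", ")))
  }
  h$units |> filter(.data$level == !!as.integer(level))
}

#' Read and write basin attribute tables
#'
#' The on-disk interchange format is a plain CSV with header
#' `basin_id,level,parent_id,next_down_id,area,cx,cy`; empty strings mark an
#' absent parent (coarsest level) or absent downstream unit (outlets). One
#' file carries all modelled levels.
#'
#' @param path CSV file path.
#' @return `read_basin_hierarchy()` returns a validated [basin_hierarchy()];
#'   `write_basin_hierarchy()` returns `path` invisibly.
#' @export
read_basin_hierarchy <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    basin_id = readr::col_character(),
    level = readr::col_integer(),
    parent_id = readr::col_character(),
    next_down_id = readr::col_character(),
    area = readr::col_double(),
    .default = readr::col_double()
  ), na = character())
  basin_hierarchy(tab)
}

#' @rdname read_basin_hierarchy
#' @param h A [basin_hierarchy()].
#' @export
write_basin_hierarchy <- function(h, path) {
  out <- h$units |>
    mutate(parent_id = tidyr::replace_na(.data$parent_id, ""),
           next_down_id = tidyr::replace_na(.data$next_down_id, ""))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' One-step upstream neighbours of a basin unit
#'
#' Returns the same-level units draining directly into the given unit, i.e.
#' those whose `next_down_id` equals `basin_id`. Only immediate neighbours are
#' returned, not the full upstream cascade.
#'
#' @param h A [basin_hierarchy()].
#' @param level Level of the focal unit.
#' @param basin_id Identifier of the focal unit.
#' @return Character vector of upstream neighbour ids (possibly empty).
#' @export
#' @examples
#' h <- sim_hierarchy(n_level4 = 1, branching = 4, seed = 1)
#' u <- basins_at_level(h, 8)
#' upstream_neighbors(h, 8, u$basin_id[1])
upstream_neighbors <- function(h, level, basin_id) {
  this <- basins_at_level(h, level)
  if (!basin_id %in% this$basin_id) {
    stop_basinsdm("basinsdm_unknown_unit",
                  sprintf("unit '%s' does not exist at level %d",
                          basin_id, as.integer(level)))
  }
  this$basin_id[!is.na(this$next_down_id) & this$next_down_id == basin_id]
}

#' Ancestor of a unit at a coarser modelled level
#'
#' Walks parent links from a unit up the modelled levels until reaching
#' `target_level`. Querying a unit at its own level returns its own id.
#'
#' @param h A [basin_hierarchy()].
#' @param basin_id Identifier of the focal unit.
#' @param level Level of the focal unit.
#' @param target_level Coarser modelled level (or the unit's own level).
#' @return The unique ancestor id at `target_level`.
#' @export
ancestor_at <- function(h, basin_id, level, target_level) {
  level <- as.integer(level)
  target_level <- as.integer(target_level)
  if (!target_level %in% h$levels) {
    stop_basinsdm("basinsdm_unknown_level",
                  sprintf("target level %d is not modelled", target_level))
  }
  if (target_level > level) {
    stop_basinsdm("basinsdm_bad_argument",
                  sprintf("target level %d is finer than unit level %d",
                          target_level, level))
  }
  map <- ancestor_map(h, level, target_level)
  if (!basin_id %in% names(map)) {
    stop_basinsdm("basinsdm_unknown_unit",
                  sprintf("unit '%s' does not exist at level %d",
                          basin_id, level))
  }
  anc <- map[[basin_id]]
  if (is.na(anc)) {
    stop_basinsdm("basinsdm_broken_parent_chain",
                  sprintf("parent chain from '%s' does not reach level %d",
                          basin_id, target_level))
  }
  anc
}

# named vector basin_id -> ancestor id at target_level, for all units at level
ancestor_map <- function(h, level, target_level) {
  lv <- h$levels
  i <- match(as.integer(level), lv)
  j <- match(as.integer(target_level), lv)
  this <- basins_at_level(h, level)
  anc <- setNames(this$basin_id, this$basin_id)
  k <- i
  while (k > j) {
    step <- basins_at_level(h, lv[k])
    up <- setNames(step$parent_id, step$basin_id)
    anc <- setNames(unname(up[anc]), names(anc))
    k <- k - 1L
  }
  anc
}
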