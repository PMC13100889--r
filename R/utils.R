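#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr filter mutate select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join distinct bind_rows bind_cols
#'   pull rename n across all_of any_of row_number slice
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl imap pmap walk
#'   list_rbind set_names
#' @importFrom stats rnorm runif rpois rbinom cor sd var median quantile
#'   predict aov glm binomial plogis qlogis complete.cases setNames
#'   as.formula
#' @importFrom utils head tail
NULL

# Structured condition helper: all package errors carry a subclass so callers
# (and the pipeline's failure isolation) can branch on the kind of failure.
stop_basinsdm <- function(class, message, ...) {
  abort(message, class = c(class, "basinsdm_error"), ...)
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the package flows from explicit integer seeds. Pipeline
#' stages derive their own seeds deterministically from one master seed plus
#' string tags (stage name, species id, level), so re-running any stage in
#' isolation reproduces the full run bit for bit.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric tags identifying the stage.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "fit", "sp01", 8)
derive_seed <- function(master, ...) {
  tags <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(tags)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# run code under a local RNG state so package functions never disturb the
# caller's .Random.seed
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_basinsdm("basinsdm_bad_argument",
                  sprintf("`%s` must be a single finite number in [%s, %s]",
                          name, format(min), format(max)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
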