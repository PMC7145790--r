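#' Population-weighted areal mean of point exposure values
#'
#' Aggregates location-level exposure measurements (e.g. postcode-level
#' estimates with headcount weights) to areal units as
#' `sum(w * x) / sum(w)` per area. Areas present in the data but with zero
#' total weight get `NA` with a warning; downstream screens treat them as
#' missing (complete-case per variable).
#'
#' @param points A data frame with columns `area_id`, `value`, `weight`
#'   (weights >= 0).
#' @return A tibble `area_id`, `value`, one row per area in first-appearance
#'   order.
#' @examples
#' pts <- tibble::tibble(area_id = c("A", "A"), value = c(2, 4), weight = c(1, 3))
#' population_weighted_mean(pts)  # 3.5
#' @export
population_weighted_mean <- function(points) {
  check_points(points)
  out <- points |>
    dplyr::group_by(area_id = factor(.data$area_id,
                                     levels = unique(points$area_id))) |>
    dplyr::summarise(
      value = if (sum(.data$weight) > 0) {
        sum(.data$weight * .data$value) / sum(.data$weight)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(area_id = as.character(.data$area_id))
  warn_missing_weight(out)
  out
}

#' Percentage of an area's population meeting a condition
#'
#' Population-weighted percentage of records satisfying an indicator (e.g.
#' the share of residents within reach of accessible natural greenspace):
#' `100 * sum(w * indicator) / sum(w)` per area, in \[0, 100\].
#'
#' @param points A data frame with columns `area_id`, `weight`, and a logical
#'   column named by `indicator`.
#' @param indicator Name of the logical column, default `"meets"`.
#' @return A tibble `area_id`, `percent`.
#' @export
percent_population_meeting <- function(points, indicator = "meets") {
  check_points(points, value_col = indicator)
  ind <- as.logical(points[[indicator]])
  out <- points |>
    dplyr::mutate(.ind = ind) |>
    dplyr::group_by(area_id = factor(.data$area_id,
                                     levels = unique(points$area_id))) |>
    dplyr::summarise(
      percent = if (sum(.data$weight) > 0) {
        100 * sum(.data$weight * .data$.ind) / sum(.data$weight)
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(area_id = as.character(.data$area_id))
  warn_missing_weight(out, col = "percent")
  out
}

check_points <- function(points, value_col = "value") {
  need <- c("area_id", value_col, "weight")
  if (!all(need %in% names(points))) {
    stop("Point table needs columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  if (any(points$weight < 0)) stop("Weights must be >= 0.", call. = FALSE)
  invisible(points)
}

warn_missing_weight <- function(out, col = "value") {
  miss <- is.na(out[[col]])
  if (any(miss)) {
    warning("Zero total weight in area(s) ",
            paste(out$area_id[miss], collapse = ", "),
            "; reported as missing.", call. = FALSE)
  }
  invisible(out)
}

#' Decile-code area values over the national distribution
#'
#' Assigns each area the decile (1-10) of its value within the distribution
#' of all non-missing area values. Ties take the lowest applicable decile
#' (minimum-rank tie rule), so the coding is deterministic and independent of
#' input order; with all values equal every area lands in decile 1.
#'
#' @param values Numeric vector of per-area values (>= 10 non-missing).
#' @return Integer vector of deciles in `1:10` (`NA` where input is missing).
#' @examples
#' decile_code(1:10)
#' @export
decile_code <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 10L) stop("Need at least 10 non-missing areas.", call. = FALSE)
  r <- rank(values[ok], ties.method = "min")
  out <- rep(NA_integer_, length(values))
  out[ok] <- as.integer(ceiling(r * 10 / n))
  out
}
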