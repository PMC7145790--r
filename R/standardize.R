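#' Indirectly standardised expected counts
#'
#' Computes age-sex-adjusted expected counts with the pooled study region
#' itself as the reference: stratum reference rates are
#' `r_s = (total cases in stratum s) / (total population in stratum s)` and
#' each area's expected count is `E_i = sum_s pop_{i,s} * r_s`. With this
#' internal reference the expected counts are calibrated exactly:
#' `sum(E_i) = sum(O_i)`.
#'
#' @param counts A data frame with columns `area_id`, `stratum`, `population`
#'   and `cases` (long format, one row per area-stratum).
#' @return A tibble with columns `area_id` and `E`, in first-appearance area
#'   order, with the per-stratum reference rates attached as attribute
#'   `reference_rates` (tibble: `stratum`, `rate`).
#' @examples
#' counts <- tibble::tibble(
#'   area_id = rep(c("A", "B"), each = 2),
#'   stratum = rep(c("young", "old"), 2),
#'   population = c(100, 200, 300, 400),
#'   cases = c(1, 4, 2, 9)
#' )
#' expected_counts(counts)
#' @export
expected_counts <- function(counts) {
  need <- c("area_id", "stratum", "population", "cases")
  if (!all(need %in% names(counts))) {
    stop("`counts` needs columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  if (any(counts$population < 0) || any(counts$cases < 0)) {
    stop("Populations and cases must be non-negative.", call. = FALSE)
  }
  ref <- counts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(cases = sum(.data$cases),
                     population = sum(.data$population), .groups = "drop")
  bad <- ref$population == 0 & ref$cases > 0
  if (any(bad)) {
    stop("Stratum ", ref$stratum[bad][1L],
         " has cases but zero reference population.", call. = FALSE)
  }
  ref$rate <- ifelse(ref$population > 0, ref$cases / ref$population, 0)
  out <- counts |>
    dplyr::left_join(ref[, c("stratum", "rate")], by = "stratum") |>
    dplyr::group_by(area_id = factor(.data$area_id,
                                     levels = unique(counts$area_id))) |>
    dplyr::summarise(E = sum(.data$population * .data$rate), .groups = "drop") |>
    dplyr::mutate(area_id = as.character(.data$area_id))
  attr(out, "reference_rates") <- tibble::tibble(stratum = ref$stratum,
                                                 rate = ref$rate)
  out
}

#' Incidence rate with an exact Poisson confidence interval
#'
#' Crude incidence per 100,000 person-years with the exact
#' (gamma-quantile) Poisson confidence interval: with `x` cases the lower
#' bound is the `alpha/2` quantile of Gamma(`x`) and the upper bound the
#' `1 - alpha/2` quantile of Gamma(`x + 1`), each divided by person-years.
#' The exact method remains valid at the small counts seen in individual
#' areas and converges to the normal approximation at large counts.
#'
#' @param cases Case count (>= 0).
#' @param person_years Person-years at risk (> 0).
#' @param level Confidence level, default 0.95.
#' @return A one-row tibble: `rate`, `ci_low`, `ci_high` (per 100,000
#'   person-years), `cases`, `person_years`.
#' @examples
#' incidence_rate(100, 1e6)
#' @export
incidence_rate <- function(cases, person_years, level = 0.95) {
  if (!is.numeric(person_years) || person_years <= 0) {
    stop("`person_years` must be positive.", call. = FALSE)
  }
  if (cases < 0) stop("`cases` must be >= 0.", call. = FALSE)
  a <- (1 - level) / 2
  lo <- if (cases == 0) 0 else stats::qgamma(a, shape = cases) / person_years
  hi <- stats::qgamma(1 - a, shape = cases + 1) / person_years
  tibble::tibble(
    rate = cases / person_years * 1e5,
    ci_low = lo * 1e5,
    ci_high = hi * 1e5,
    cases = cases,
    person_years = person_years
  )
}
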