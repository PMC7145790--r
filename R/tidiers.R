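#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Tidy an EnWAS screen
#'
#' @param x An [enwas_screen()] result.
#' @param ... Unused.
#' @return The screen as a plain tibble (one row per variable).
#' @export
tidy.enwas_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of an EnWAS screen
#'
#' @param x An [enwas_screen()] result.
#' @param ... Unused.
#' @return A tibble with `n_variables`, `n_significant`, `alpha`,
#'   `threshold` (the Bonferroni per-test level).
#' @export
glance.enwas_screen <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha"),
    threshold = attr(x, "threshold")
  )
}

#' Tidy a BYM2 fit
#'
#' @param x A [fit_bym2()] result.
#' @param what `"parameters"` (default) for model-level posterior summaries
#'   with diagnostics, or `"areas"` for the per-area relative-risk surface.
#' @param ... Unused.
#' @return A tibble. For `"parameters"`: `term`, posterior `mean`, `ci_low`,
#'   `ci_high` (95% credible interval), `rhat`, `ess`; coefficient rows also
#'   carry `rr`, `rr_low`, `rr_high`.
#' @export
tidy.bym2_fit <- function(x, what = c("parameters", "areas"), ...) {
  what <- match.arg(what)
  if (what == "areas") return(x$areas)
  out <- x$parameters
  is_coef <- !out$term %in% c("sigma", "phi")
  out$rr <- ifelse(is_coef, exp(out$mean), NA_real_)
  out$rr_low <- ifelse(is_coef, exp(out$ci_low), NA_real_)
  out$rr_high <- ifelse(is_coef, exp(out$ci_high), NA_real_)
  out
}

#' One-row summary of a BYM2 fit
#'
#' @param x A [fit_bym2()] result.
#' @param ... Unused.
#' @return A tibble with the number of areas, chain configuration, the
#'   posterior mean structured share (`phi`), worst-case diagnostics and the
#'   convergence flag.
#' @export
glance.bym2_fit <- function(x, ...) {
  tibble::tibble(
    n_areas = nrow(x$areas),
    n_covariates = length(x$covariates),
    chains = x$chains,
    iter = x$iter,
    phi_mean = if (x$prior_only || !is.null(x$priors$fix_phi)) NA_real_
               else mean(x$draws$phi),
    sigma_mean = if (x$prior_only || !is.null(x$priors$fix_sigma)) NA_real_
                 else mean(x$draws$sigma),
    max_rhat = suppressWarnings(max(x$parameters$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$parameters$ess, na.rm = TRUE)),
    converged = x$converged
  )
}

#' Per-area posterior summaries joined to the area table
#'
#' @param x A [fit_bym2()] result.
#' @param data Optional area table to join onto (by `area_id`).
#' @param ... Unused.
#' @return `data` (or the fit's area table) with `rr_mean`, `rr_low`,
#'   `rr_high`, `prob_above_1`, `prob_below_1` columns.
#' @export
augment.bym2_fit <- function(x, data = NULL, ...) {
  if (is.null(data)) return(x$areas)
  dplyr::left_join(data, x$areas, by = "area_id")
}
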