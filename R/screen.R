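#' Univariable Poisson regression with an expected-count offset
#'
#' Maximum-likelihood fit of `O_i ~ Poisson(E_i * exp(a + b * x_i))` by
#' iteratively reweighted least squares, the workhorse of the EnWAS screen.
#' The offset `log(E_i)` makes `exp(b)` the relative risk per covariate unit
#' relative to the age-sex-adjusted expectation. Standard errors come from
#' the inverse Fisher information at the optimum and p-values are two-sided
#' Wald tests against the standard normal.
#'
#' Areas with a missing covariate are dropped (complete-case per variable);
#' `x = NULL` fits the offset-only model, whose intercept has the closed form
#' `log(sum(O) / sum(E))`.
#'
#' @param O Observed counts (non-negative integers).
#' @param E Expected counts (> 0), same length.
#' @param x Optional covariate vector; needs >= 2 distinct values after
#'   dropping missing areas.
#' @param tol Relative convergence tolerance on coefficients, default 1e-10.
#' @param max_iter Iteration cap; non-convergence raises an error carrying
#'   the last iterate.
#' @return A one-row tibble: `term`, `estimate`, `se`, `p`, plus attributes
#'   `intercept`, `loglik`, `n`, `iterations`. Without a covariate the single
#'   row describes the intercept.
#' @examples
#' fit_poisson_offset(O = c(2, 4), E = c(1, 1))       # intercept log(3)
#' @export
fit_poisson_offset <- function(O, E, x = NULL, tol = 1e-10, max_iter = 100L) {
  if (any(E <= 0)) stop("All expected counts must be positive.", call. = FALSE)
  if (length(O) != length(E)) stop("`O` and `E` lengths differ.", call. = FALSE)
  keep <- !is.na(O) & !is.na(E)
  if (!is.null(x)) keep <- keep & !is.na(x)
  O <- O[keep]; E <- E[keep]
  if (!is.null(x)) x <- x[keep]
  if (all(O == 0)) {
    stop("Degenerate data: all observed counts are zero.", call. = FALSE)
  }
  has_x <- !is.null(x)
  if (has_x && length(unique(x)) < 2L) {
    stop("Covariate needs at least 2 distinct values.", call. = FALSE)
  }
  X <- if (has_x) cbind(1, x) else cbind(rep(1, length(O)))
  off <- log(E)
  beta <- c(log(sum(O) / sum(E)), if (has_x) 0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- off + as.vector(X %*% beta)
    mu <- exp(eta)
    z <- (eta - off) + (O - mu) / mu     # working response
    fit <- stats::lm.wfit(X, z, w = mu)
    new_beta <- fit$coefficients
    if (anyNA(new_beta) || !all(is.finite(new_beta))) {
      stop("IRLS diverged (non-finite coefficients) at iteration ", it, ".",
           call. = FALSE)
    }
    step <- max(abs(new_beta - beta) / pmax(abs(new_beta), 1))
    beta <- new_beta
    if (step < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop("IRLS failed to converge in ", max_iter,
         " iterations (last coefficients: ",
         paste(signif(beta, 6), collapse = ", "), ").", call. = FALSE)
  }
  mu <- exp(off + as.vector(X %*% beta))
  info <- crossprod(X, X * mu)
  se <- sqrt(diag(solve(info)))
  est <- if (has_x) beta[2L] else beta[1L]
  sei <- if (has_x) se[2L] else se[1L]
  out <- tibble::tibble(
    term = if (has_x) "x" else "(Intercept)",
    estimate = unname(est),
    se = unname(sei),
    p = 2 * stats::pnorm(-abs(est / sei))
  )
  attr(out, "intercept") <- unname(beta[1L])
  attr(out, "loglik") <- sum(stats::dpois(O, mu, log = TRUE))
  attr(out, "n") <- length(O)
  attr(out, "iterations") <- it
  out
}

#' Bonferroni per-test threshold
#'
#' @param m Number of tests (>= 1).
#' @param alpha Family-wise error level in (0, 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(53, 0.05)
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (!is.numeric(m) || m < 1) stop("`m` must be >= 1.", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  alpha / m
}

#' Environment-wide association screen
#'
#' Stage-1 frequentist screen: one univariable Poisson regression with
#' expected-count offset per exposure variable, family-wise error controlled
#' by Bonferroni division of `alpha` by the number of variables tested.
#' Areas missing a given variable are dropped for that variable only.
#'
#' @param areas Area table: a data frame with columns `area_id`, `O`, `E` and
#'   the exposure columns.
#' @param variables Character vector of exposure column names; defaults to
#'   every numeric column other than `area_id`, `O`, `E`.
#' @param alpha Family-wise error level, default 0.05.
#' @param standardise If `TRUE`, z-score each covariate before fitting
#'   (estimates then are per-SD); default `FALSE`, native units.
#' @return An `enwas_screen` tibble, one row per variable: `variable`,
#'   `estimate` (log RR per unit), `se`, `rr`, `rr_low`, `rr_high` (95% CI),
#'   `p`, `n` (areas used), `significant` (Bonferroni flag) and
#'   `signed_log10p`. Attributes: `alpha`, `threshold`, `m`.
#' @examples
#' region <- simulate_region(n_areas = 30, n_vars = 3, seed = 1)
#' enwas_screen(region$areas)
#' @export
enwas_screen <- function(areas, variables = NULL, alpha = 0.05,
                         standardise = FALSE) {
  stopifnot(all(c("area_id", "O", "E") %in% names(areas)))
  if (is.null(variables)) {
    variables <- setdiff(names(areas)[vapply(areas, is.numeric, TRUE)],
                         c("O", "E", "risk", "O_period1", "O_period2"))
  }
  m <- length(variables)
  thr <- bonferroni_threshold(m, alpha)
  rows <- purrr::map(variables, function(v) {
    x <- areas[[v]]
    if (standardise) x <- as.vector(scale(x))
    fit <- fit_poisson_offset(areas$O, areas$E, x)
    tibble::tibble(variable = v, estimate = fit$estimate, se = fit$se,
                   p = fit$p, n = attr(fit, "n"))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      rr = exp(.data$estimate),
      rr_low = exp(.data$estimate - stats::qnorm(0.975) * .data$se),
      rr_high = exp(.data$estimate + stats::qnorm(0.975) * .data$se),
      significant = .data$p < thr,
      signed_log10p = manhattan_values(.data$p, .data$estimate)
    ) |>
    dplyr::relocate("variable", "estimate", "se", "rr", "rr_low", "rr_high",
                    "p", "n", "significant", "signed_log10p")
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  attr(out, "m") <- m
  class(out) <- c("enwas_screen", class(out))
  out
}

#' Signed Manhattan-plot values
#'
#' The quantity plotted on an EnWAS Manhattan plot:
#' `-log10(p) * sign(estimate)`, encoding significance and direction (but not
#' magnitude) of each association. Numerically zero p-values are clamped at
#' `floor` with a warning — the clamp affects plotting only, inference uses
#' raw p-values.
#'
#' @param p P-values in (0, 1].
#' @param estimate Effect estimates giving the signs (`sign(0)` is 0).
#' @param floor Smallest representable p-value, default 1e-300.
#' @return Numeric vector of signed `-log10` p-values.
#' @export
manhattan_values <- function(p, estimate, floor = 1e-300) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("P-values must lie in (0, 1].", call. = FALSE)
  }
  if (any(p == 0, na.rm = TRUE)) {
    warning("Zero p-value(s) clamped at ", floor, " for plotting.",
            call. = FALSE)
    p <- pmax(p, floor)
  }
  -log10(p) * sign(estimate)
}

#' Quantile-quantile points for screen p-values
#'
#' Pairs observed `-log10` p-values (sorted) with their expected values under
#' the global null, using uniform order-statistic midpoints `(k - 0.5) / m`.
#'
#' @param p P-values in (0, 1].
#' @return A tibble with `expected` and `observed` columns (both `-log10`
#'   scale), sorted so the largest observed value comes first.
#' @export
qq_points <- function(p) {
  if (length(p) == 0L) stop("Empty p-value set.", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("P-values must lie in (0, 1].", call. = FALSE)
  }
  m <- length(p)
  tibble::tibble(
    expected = -log10((seq_len(m) - 0.5) / m),
    observed = -log10(sort(p))
  )
}
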