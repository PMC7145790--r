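#' Spearman rank correlation matrix of area exposures
#'
#' Pairwise Spearman correlations (midrank ties, pairwise-complete
#' observations) across the exposure columns of an area table: the quantity
#' visualised as a correlation heat map when choosing which of a set of
#' intercorrelated exposures can enter the same regression.
#'
#' @param areas Data frame with `area_id` and exposure columns.
#' @param variables Exposure column names; defaults to all numeric columns
#'   except `area_id`, `O`, `E` and bookkeeping columns.
#' @return A symmetric correlation matrix with unit diagonal; constant
#'   variables yield `NA` rows/columns with a warning.
#' @export
spearman_matrix <- function(areas, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(areas)[vapply(areas, is.numeric, TRUE)],
                         c("O", "E", "risk", "O_period1", "O_period2"))
  }
  X <- as.matrix(areas[, variables, drop = FALSE])
  if (nrow(X) < 3) stop("Need at least 3 areas.", call. = FALSE)
  const <- apply(X, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("Constant variable(s): ", paste(variables[const], collapse = ", "),
            "; correlations recorded as missing.", call. = FALSE)
  }
  R <- suppressWarnings(
    stats::cor(X, method = "spearman", use = "pairwise.complete.obs")
  )
  R[const, ] <- NA_real_
  R[, const] <- NA_real_
  diag(R) <- ifelse(const, NA_real_, 1)
  R
}

#' Dual-screen covariate selection for the ecological regression
#'
#' Implements the two-gate inclusion rule of the staged analysis: a variable
#' is a candidate only if it passed the frequentist screen (Bonferroni
#' adjusted p below `alpha`) *and* the Bayesian disease mapping (95% credible
#' interval excluding 1). Candidates are then grouped into clusters of
#' mutually correlated variables — connected components of the graph joining
#' pairs with `|rho| >= rho_max` — and one representative per cluster is
#' retained (by default the smallest screen p-value, overridable), since
#' strongly correlated exposures cannot enter the same model.
#'
#' @param screen An [enwas_screen()] result (needs `variable`, `p`,
#'   `significant`).
#' @param mapping A data frame with one row per variable: `variable`,
#'   `rr_low`, `rr_high` — the per-variable disease-mapping credible
#'   intervals (e.g. assembled from single-covariate [fit_bym2()] fits).
#' @param corr Spearman correlation matrix over the same variables
#'   ([spearman_matrix()]).
#' @param rho_max Absolute-correlation threshold defining "too correlated to
#'   co-enter", default 0.7.
#' @param prefer Optional character vector of variables to force as cluster
#'   representatives (expert override), e.g. a pollutant chosen as the marker
#'   of its correlated group.
#' @param alpha Family-wise level used for the screen gate (matches the
#'   screen's own alpha by default).
#' @return A `selection_report` tibble, one row per variable: `variable`,
#'   `passed_enwas`, `passed_mapping`, `cluster_id` (`NA` for
#'   non-candidates), `selected`, `reason`.
#' @export
select_covariates <- function(screen, mapping, corr, rho_max = 0.7,
                              prefer = NULL, alpha = NULL) {
  vars <- sort(screen$variable)
  if (!setequal(vars, mapping$variable) || !setequal(vars, rownames(corr))) {
    stop("`screen`, `mapping` and `corr` must cover the same variables.",
         call. = FALSE)
  }
  alpha <- alpha %||% attr(screen, "alpha") %||% 0.05
  m <- length(vars)
  scr <- screen[match(vars, screen$variable), ]
  map <- mapping[match(vars, mapping$variable), ]
  passed_enwas <- scr$p < bonferroni_threshold(m, alpha)
  passed_mapping <- map$rr_low > 1 | map$rr_high < 1
  candidate <- passed_enwas & passed_mapping

  # clusters: connected components of the thresholded |rho| graph over
  # candidates (deterministic: variables processed in sorted order)
  cluster_id <- rep(NA_integer_, m)
  if (any(candidate)) {
    idx <- which(candidate)
    Rc <- abs(corr[vars[idx], vars[idx], drop = FALSE])
    nb <- lapply(seq_along(idx), function(i) {
      which(!is.na(Rc[i, ]) & Rc[i, ] >= rho_max & seq_along(idx) != i)
    })
    cluster_id[idx] <- label_components(nb)
  }

  selected <- rep(FALSE, m)
  reason <- dplyr::case_when(
    !passed_enwas & !passed_mapping ~ "failed both screens",
    !passed_enwas ~ "not significant in EnWAS",
    !passed_mapping ~ "credible interval spans 1",
    TRUE ~ ""
  )
  for (cl in unique(stats::na.omit(cluster_id))) {
    members <- which(!is.na(cluster_id) & cluster_id == cl)
    pref <- members[vars[members] %in% prefer]
    rep_i <- if (length(pref)) pref[1L] else members[which.min(scr$p[members])]
    selected[rep_i] <- TRUE
    reason[rep_i] <- if (length(members) == 1L) {
      "passed both screens"
    } else if (length(pref)) {
      "preferred representative of correlated cluster"
    } else {
      "smallest screen p in correlated cluster"
    }
    dropped <- setdiff(members, rep_i)
    reason[dropped] <- paste0("correlated (|rho| >= ", rho_max, ") with ",
                              vars[rep_i])
  }
  out <- tibble::tibble(variable = vars, passed_enwas = passed_enwas,
                        passed_mapping = passed_mapping,
                        cluster_id = cluster_id, selected = selected,
                        reason = reason)
  class(out) <- c("selection_report", class(out))
  out
}

#' Multivariable spatial ecological regression
#'
#' Stage 3 of the pipeline: the BYM2 model of [fit_bym2()] with the selected
#' exposure set entered jointly, reporting per-covariate relative risks with
#' 95% credible intervals alongside the smoothed residual risk surface.
#'
#' @inheritParams fit_bym2
#' @param covariates Character vector of selected covariate columns (may be
#'   empty, reducing to pure disease mapping).
#' @return A `bym2_fit` (see [fit_bym2()]).
#' @export
ecological_regression <- function(areas, graph, covariates,
                                  priors = prior_config(), chains = 4,
                                  iter = 5000, warmup = floor(iter / 2),
                                  seed = 1L) {
  fit_bym2(areas, graph, covariates = covariates, priors = priors,
           chains = chains, iter = iter, warmup = warmup, seed = seed)
}

#' Temporal-split consistency of areal counts
#'
#' Pearson correlation between per-area counts from two sub-periods of the
#' study: high correlation indicates the spatial pattern is stable over time
#' rather than an artefact of a single period.
#'
#' @param counts_a,counts_b Per-area counts for the two periods (same areas,
#'   same order, >= 3 areas).
#' @return Pearson correlation (scalar); `NA` with a warning when either
#'   vector has zero variance.
#' @export
temporal_split_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 3) {
    stop("Need two equal-length vectors over >= 3 areas.", call. = FALSE)
  }
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    warning("Zero variance in a period; correlation undefined.", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(counts_a, counts_b)
}
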