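test_that("Spearman correlation honours monotone invariance and sign", {
  withr::with_seed(1, {
    areas <- tibble::tibble(area_id = paste0("a", 1:50), x01 = rnorm(50))
  })
  areas$x02 <- areas$x01^3
  areas$x03 <- -areas$x01
  R <- spearman_matrix(areas, variables = c("x01", "x02", "x03"))
  expect_equal(R["x01", "x02"], 1)
  expect_equal(R["x01", "x03"], -1)
  expect_equal(diag(R), c(x01 = 1, x02 = 1, x03 = 1))
})

test_that("tied data match the midrank-then-Pearson oracle", {
  withr::with_seed(2, {
    x <- sample(1:5, 80, replace = TRUE)   # heavy ties
    y <- sample(1:4, 80, replace = TRUE) + 0.1 * x
  })
  areas <- tibble::tibble(area_id = paste0("a", 1:80), x01 = x, x02 = y)
  R <- spearman_matrix(areas, variables = c("x01", "x02"))
  oracle <- cor(rank(x), rank(y))  # midranks, then Pearson
  expect_equal(R["x01", "x02"], oracle, tolerance = 1e-12)
})

test_that("constant variables are flagged missing with a warning", {
  areas <- tibble::tibble(area_id = paste0("a", 1:10), x01 = rnorm(10),
                          x02 = 7)
  expect_warning(R <- spearman_matrix(areas, variables = c("x01", "x02")),
                 "Constant")
  expect_true(is.na(R["x01", "x02"]))
})

make_selection_inputs <- function(p, sig, rr_low, rr_high, corr = NULL) {
  vars <- sprintf("v%02d", seq_along(p))
  screen <- tibble::tibble(variable = vars, p = p,
                           significant = sig)
  attr(screen, "alpha") <- 0.05
  mapping <- tibble::tibble(variable = vars, rr_low = rr_low,
                            rr_high = rr_high)
  if (is.null(corr)) corr <- diag(length(p))
  dimnames(corr) <- list(vars, vars)
  list(screen = screen, mapping = mapping, corr = corr)
}

test_that("no candidate passing both gates yields an empty selection", {
  inp <- make_selection_inputs(
    p = c(0.5, 0.9), sig = c(FALSE, FALSE),
    rr_low = c(0.9, 0.8), rr_high = c(1.1, 1.2)
  )
  sel <- select_covariates(inp$screen, inp$mapping, inp$corr)
  expect_false(any(sel$selected))
  expect_true(all(is.na(sel$cluster_id)))
})

test_that("strongly correlated candidates collapse to one representative", {
  corr <- diag(2); corr[1, 2] <- corr[2, 1] <- 0.95
  inp <- make_selection_inputs(
    p = c(1e-6, 1e-4), sig = c(TRUE, TRUE),
    rr_low = c(1.02, 1.01), rr_high = c(1.10, 1.09), corr = corr
  )
  sel <- select_covariates(inp$screen, inp$mapping, inp$corr, rho_max = 0.7)
  expect_equal(sum(sel$selected), 1L)
  expect_true(sel$selected[sel$variable == "v01"])  # smallest p wins
  # expert override flips the representative
  sel2 <- select_covariates(inp$screen, inp$mapping, inp$corr, rho_max = 0.7,
                            prefer = "v02")
  expect_true(sel2$selected[sel2$variable == "v02"])
})

test_that("a variable significant in the screen but with a credible interval
           spanning one is excluded", {
  # the fine-particulate situation: screen p < 0.001 but mapping CrI
  # 0.942-1.005 straddles 1
  inp <- make_selection_inputs(
    p = c(1e-5, 1e-6), sig = c(TRUE, TRUE),
    rr_low = c(1.015, 0.942), rr_high = c(1.074, 1.005)
  )
  sel <- select_covariates(inp$screen, inp$mapping, inp$corr)
  expect_true(sel$selected[1])
  expect_false(sel$selected[2])
  expect_match(sel$reason[2], "spans 1")
})

test_that("selection is deterministic under variable reordering and selected
           variables are never strongly correlated", {
  withr::with_seed(3, {
    m <- 12
    p <- 10^-runif(m, 0, 8)
    rlow <- runif(m, 0.9, 1.05)
    L <- matrix(rnorm(m * m), m) / sqrt(m)
    corr <- cov2cor(crossprod(L) + diag(m) * 0.5)
  })
  inp <- make_selection_inputs(p, p < 0.05 / m, rlow, rlow + 0.1, corr)
  sel <- select_covariates(inp$screen, inp$mapping, inp$corr, rho_max = 0.4)
  shuffle <- sample(nrow(inp$screen))
  sel_shuf <- select_covariates(inp$screen[shuffle, ],
                                inp$mapping[rev(shuffle), ], inp$corr,
                                rho_max = 0.4)
  expect_equal(sel, sel_shuf)
  chosen <- sel$variable[sel$selected]
  if (length(chosen) > 1) {
    off <- abs(inp$corr[chosen, chosen])
    expect_true(all(off[upper.tri(off)] < 0.4))
  }
  expect_true(all(sel$passed_enwas[sel$selected] &
                  sel$passed_mapping[sel$selected]))
})

test_that("temporal-split correlation has its closed-form anchors", {
  x <- c(4, 9, 2, 7, 5)
  expect_equal(temporal_split_correlation(x, x), 1)
  expect_equal(temporal_split_correlation(x, 2 * x), 1)
  withr::with_seed(4, { a <- rpois(40, 30); b <- rpois(40, 30) + a })
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(temporal_split_correlation(a, b), oracle, tolerance = 1e-12)
  expect_warning(r <- temporal_split_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "Zero variance")
  expect_true(is.na(r))
  expect_error(temporal_split_correlation(1:2, 1:2), ">= 3")
})

test_that("the ecological regression is the multivariable spatial model", {
  region <- simulate_region(n_areas = 25, n_vars = 2, seed = 5)
  f1 <- ecological_regression(region$areas, region$graph,
                              covariates = c("x01", "x02"),
                              chains = 2, iter = 300, seed = 6)
  f2 <- fit_bym2(region$areas, region$graph, covariates = c("x01", "x02"),
                 chains = 2, iter = 300, seed = 6)
  expect_identical(f1$draws, f2$draws)
})

test_that("the multivariable model finds true effects among noise covariates", {
  hits <- matrix(FALSE, 20, 2)
  for (r in 1:20) {
    region <- simulate_region(
      n_areas = 354, n_vars = 6, layout = "lattice",
      beta = c(x01 = 0.5, x02 = -0.5), sigma = 0.2, phi = 0.5,
      target_corr = diag(6), seed = 400 + r
    )
    fit <- ecological_regression(region$areas, region$graph,
                                 covariates = sprintf("x%02d", 1:6),
                                 chains = 2, iter = 1000, seed = 500 + r)
    td <- tidy(fit)
    for (k in 1:2) {
      row <- td[td$term == c("x01", "x02")[k], ]
      hits[r, k] <- row$rr_low > 1 || row$rr_high < 1
    }
  }
  expect_gte(sum(hits[, 1]), 16)  # >= 80% of replicates
  expect_gte(sum(hits[, 2]), 16)
})
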