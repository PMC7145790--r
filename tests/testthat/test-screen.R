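test_that("perfectly calibrated counts give zero intercept and slope", {
  withr::with_seed(3, x <- rnorm(12))
  E <- c(2, 5, 9, 4, 7, 3, 8, 6, 2, 4, 10, 5)
  fit <- fit_poisson_offset(O = E, E = E, x = x)
  expect_equal(fit$estimate, 0, tolerance = 1e-9)
  expect_equal(attr(fit, "intercept"), 0, tolerance = 1e-9)
})

test_that("the offset-only intercept has its closed form log(sum O / sum E)", {
  fit <- fit_poisson_offset(O = c(2, 4), E = c(1, 1))
  expect_equal(fit$estimate, log(3), tolerance = 1e-10)
  expect_equal(fit$term, "(Intercept)")
})

test_that("IRLS agrees with glm() on random small datasets", {
  for (s in 1:100) {
    d <- toy_screen_data(n = 20, b = runif(1, -0.5, 0.5), seed = s)
    fit <- fit_poisson_offset(d$O, d$E, d$x)
    ref <- suppressWarnings(
      glm(d$O ~ d$x + offset(log(d$E)), family = poisson())
    )
    expect_equal(fit$estimate, unname(coef(ref)[2]), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(diag(vcov(ref)))[2]), tolerance = 1e-6)
  }
})

test_that("shifting the covariate moves only the intercept", {
  d <- toy_screen_data(n = 30, b = 0.2, seed = 9)
  f0 <- fit_poisson_offset(d$O, d$E, d$x)
  f1 <- fit_poisson_offset(d$O, d$E, d$x + 100)
  expect_equal(f1$estimate, f0$estimate, tolerance = 1e-8)
  expect_equal(f1$se, f0$se, tolerance = 1e-8)
  expect_equal(f1$p, f0$p, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(attr(f1, "intercept"),
                                attr(f0, "intercept"))))
})

test_that("missing covariate areas are dropped per variable", {
  d <- toy_screen_data(n = 25, b = 0.3, seed = 2)
  x_na <- d$x; x_na[1:5] <- NA
  fit <- fit_poisson_offset(d$O, d$E, x_na)
  ref <- fit_poisson_offset(d$O[-(1:5)], d$E[-(1:5)], d$x[-(1:5)])
  expect_equal(fit$estimate, ref$estimate)
  expect_equal(attr(fit, "n"), 20)
})

test_that("degenerate screen inputs raise informative errors", {
  expect_error(fit_poisson_offset(c(0, 0), c(1, 1)), "all observed counts are zero")
  expect_error(fit_poisson_offset(c(1, 2), c(1, 0.0)), "positive")
  expect_error(fit_poisson_offset(c(1, 2), c(1, 1), x = c(3, 3)),
               "distinct")
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(10, 0.05), 0.005)
  expect_equal(bonferroni_threshold(53, 0.05), 0.05 / 53)
  expect_error(bonferroni_threshold(0, 0.05), ">= 1")
  expect_error(bonferroni_threshold(10, 1.5), "in \\(0, 1\\)")
})

test_that("Manhattan values encode significance times direction", {
  expect_equal(manhattan_values(0.01, -2), -2)
  expect_equal(manhattan_values(1, 0.7), 0)
  expect_equal(manhattan_values(1e-4, 3), 4)
  expect_equal(manhattan_values(0.5, 0), 0)  # sign(0) = 0
  expect_warning(v <- manhattan_values(0, 1), "clamped")
  expect_equal(v, 300)
  expect_error(manhattan_values(1.2, 1), "\\(0, 1\\]")
})

test_that("QQ points use the uniform order-statistic midpoint rule", {
  pts <- qq_points(0.5)
  expect_equal(pts$expected, log10(2))
  expect_equal(pts$observed, log10(2))
  # a uniform grid of p-values sits near the diagonal
  grid <- qq_points((1:100) / 100)
  expect_lt(max(abs(grid$expected - grid$observed)), 0.31)  # only smallest p deviates
  expect_error(qq_points(numeric(0)), "Empty")
  expect_error(qq_points(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("uniform p-values stay inside the 99th-percentile Kolmogorov band", {
  withr::with_seed(123, p <- runif(1000))
  pts <- qq_points(p)
  # on the p scale: |F_hat - F| bounded by the 99% KS quantile
  d <- max(abs(sort(p) - (seq_len(1000) - 0.5) / 1000))
  expect_lt(d, 1.628 / sqrt(1000))
})

test_that("the screen flags variables against the Bonferroni threshold", {
  region <- simulate_region(n_areas = 40, n_vars = 5, seed = 6)
  s <- enwas_screen(region$areas)
  expect_s3_class(s, "enwas_screen")
  expect_equal(nrow(s), 5)
  expect_equal(attr(s, "threshold"), 0.01)
  expect_equal(s$significant, s$p < 0.01)
  expect_equal(s$signed_log10p, -log10(s$p) * sign(s$estimate))
  expect_true(all(s$rr_low <= s$rr & s$rr <= s$rr_high))
  g <- glance(s)
  expect_equal(g$n_significant, sum(s$significant))
})

test_that("screen estimates are unchanged by variable order and can be
           standardised", {
  region <- simulate_region(n_areas = 40, n_vars = 4, seed = 8)
  s1 <- enwas_screen(region$areas, variables = c("x01", "x03"))
  s2 <- enwas_screen(region$areas, variables = c("x03", "x01"))
  expect_equal(dplyr::arrange(tidy(s1), variable),
               dplyr::arrange(tidy(s2), variable))
  sz <- enwas_screen(region$areas, variables = "x01", standardise = TRUE)
  raw <- enwas_screen(region$areas, variables = "x01")
  expect_equal(sz$estimate, raw$estimate * sd(region$areas$x01))
  expect_equal(sz$p, raw$p, tolerance = 1e-6)
})
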