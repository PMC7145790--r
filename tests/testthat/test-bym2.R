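test_that("with flat data the posterior intercept approaches the offset MLE", {
  n <- 64
  g <- simulate_area_graph(n, "lattice", seed = 1)
  areas <- tibble::tibble(area_id = g$area_ids, O = rep(600, n),
                          E = rep(500, n))
  fit <- fit_bym2(areas, g, priors = prior_config(fix_sigma = 1e-4),
                  chains = 2, iter = 1000, seed = 2)
  a_row <- fit$parameters[fit$parameters$term == "(Intercept)", ]
  expect_lt(abs(a_row$mean - log(600 / 500)), 0.02)
})

test_that("calibrated large counts with a tight variance prior shrink all
           relative risks to one", {
  n <- 49
  g <- simulate_area_graph(n, "lattice", seed = 1)
  withr::with_seed(5, E <- runif(n, 500, 900))
  areas <- tibble::tibble(area_id = g$area_ids, O = round(E), E = E)
  fit <- fit_bym2(areas, g, priors = prior_config(sigma_upper = 0.02),
                  chains = 2, iter = 1000, seed = 3)
  expect_true(all(fit$areas$rr_mean > 0.95 & fit$areas$rr_mean < 1.05))
})

test_that("prior-only sampling reproduces the sigma and phi priors", {
  n <- 16
  g <- simulate_area_graph(n, "lattice", seed = 1)
  areas <- tibble::tibble(area_id = g$area_ids, O = rep(5, n), E = rep(5, n))
  fit <- fit_bym2(areas, g, chains = 2, iter = 5000, warmup = 2500,
                  seed = 4, prior_only = TRUE)
  phi <- as.numeric(fit$draws$phi)
  sig <- as.numeric(fit$draws$sigma)
  expect_length(phi, 5000)
  rate <- -log(0.01)  # Pr(sigma > 1) = 0.01
  expect_gt(ks.test(phi, "punif")$p.value, 0.01)
  expect_gt(ks.test(sig, "pexp", rate = rate)$p.value, 0.01)
})

test_that("retained structured-effect draws sum to zero in each component", {
  region <- simulate_region(n_areas = 30, n_vars = 0, seed = 6)
  fit <- fit_bym2(region$areas, region$graph, chains = 2, iter = 400, seed = 5)
  sums <- abs(rowSums(fit$draws$u))
  expect_lt(max(sums), 1e-8)
})

test_that("with sigma pinned near zero the Bayesian fit matches the
           frequentist screen", {
  region <- simulate_region(n_areas = 60, n_vars = 1, sigma = 0, seed = 7)
  freq <- fit_poisson_offset(region$areas$O, region$areas$E, region$areas$x01)
  fit <- fit_bym2(region$areas, region$graph, covariates = "x01",
                  priors = prior_config(fix_sigma = 1e-6, fix_phi = 0.5),
                  chains = 2, iter = 2000, seed = 8)
  b_row <- fit$parameters[fit$parameters$term == "x01", ]
  b_sd <- sd(unlist(fit$draws$beta[[1]]))
  expect_lt(abs(b_row$mean - freq$estimate), 2 * b_sd)
  a_row <- fit$parameters[fit$parameters$term == "(Intercept)", ]
  a_sd <- sd(as.numeric(fit$draws$a))
  expect_lt(abs(a_row$mean - attr(freq, "intercept")), 2 * a_sd)
})

test_that("exceedance classification follows the posterior fractions exactly", {
  draws <- cbind(
    hot = c(rep(1.2, 800), rep(0.9, 200)),    # 80% above 1
    cold = c(rep(0.8, 850), rep(1.1, 150)),   # 85% below 1
    flat = rep(c(0.95, 1.05), 500)            # symmetric about 1
  )
  cls <- exceedance(draws, prob_threshold = 0.8)
  expect_equal(as.character(cls$class), c("elevated", "lowered", "uncertain"))
  expect_equal(cls$prob_above[1], 0.8)
  expect_equal(cls$prob_below[2], 0.85)
  expect_equal(cls$prob_above[3], 0.5)
  all_up <- matrix(1.5, 200, 1, dimnames = list(NULL, "a"))
  expect_equal(as.character(exceedance(all_up)$class), "elevated")
  expect_error(exceedance(matrix(1.1, 50, 2)), "at least 100")
})

test_that("raising the probability threshold never adds classifications", {
  withr::with_seed(10, draws <- matrix(exp(rnorm(1000 * 25, 0, 0.2)), 1000, 25))
  prev_decided <- rep(TRUE, 25)
  for (thr in c(0.6, 0.7, 0.8, 0.9, 0.99)) {
    cls <- exceedance(draws, prob_threshold = thr)
    decided <- cls$class != "uncertain"
    expect_true(all(!decided | prev_decided))  # decided set shrinks
    prev_decided <- decided
  }
})

test_that("structured share summarises phi draws", {
  s <- structured_share(rep(0.78, 500))
  expect_equal(s$mean, 0.78)
  expect_equal(s$ci_low, 0.78)
  expect_equal(s$ci_high, 0.78)
  withr::with_seed(2, u <- runif(20000))
  s2 <- structured_share(u)
  expect_lt(abs(s2$mean - 0.5), 0.01)
  expect_lt(abs(s2$ci_low - 0.025), 0.01)
  expect_lt(abs(s2$ci_high - 0.975), 0.01)
  expect_error(structured_share(numeric(0)), "No phi draws")
  expect_error(structured_share(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("model input validation catches broken designs", {
  region <- simulate_region(n_areas = 20, n_vars = 2, seed = 9)
  areas <- region$areas
  areas$dup <- areas$x01
  expect_error(
    fit_bym2(areas, region$graph, covariates = c("x01", "dup"),
             chains = 2, iter = 200),
    "Rank-deficient"
  )
  expect_error(fit_bym2(areas, region$graph, chains = 1, iter = 200),
               "2 chains")
  expect_error(fit_bym2(areas[-1, ], region$graph, chains = 2, iter = 200),
               "missing areas")
  bad <- areas; bad$E[1] <- 0
  expect_error(fit_bym2(bad, region$graph, chains = 2, iter = 200),
               "positive")
})

test_that("fits expose tidy, glance, augment and honest convergence flags", {
  region <- simulate_region(n_areas = 25, n_vars = 1, seed = 11)
  fit <- fit_bym2(region$areas, region$graph, covariates = "x01",
                  chains = 2, iter = 400, seed = 12)
  td <- tidy(fit)
  expect_true(all(c("(Intercept)", "x01", "sigma", "phi") %in% td$term))
  expect_true(all(td$ci_low <= td$mean & td$mean <= td$ci_high))
  ar <- tidy(fit, "areas")
  expect_equal(nrow(ar), 25)
  expect_true(all(abs(ar$prob_above_1 + ar$prob_below_1 - 1) < 1e-12))
  expect_true(all(ar$rr_low <= ar$rr_mean & ar$rr_mean <= ar$rr_high))
  gl <- glance(fit)
  expect_type(gl$converged, "logical")
  expect_equal(gl$n_areas, 25)
  au <- augment(fit, region$areas)
  expect_true(all(c("rr_mean", "x01", "O") %in% names(au)))
})

test_that("identical seeds give identical fits", {
  region <- simulate_region(n_areas = 20, n_vars = 1, seed = 13)
  f1 <- fit_bym2(region$areas, region$graph, covariates = "x01",
                 chains = 2, iter = 300, seed = 14)
  f2 <- fit_bym2(region$areas, region$graph, covariates = "x01",
                 chains = 2, iter = 300, seed = 14)
  expect_identical(f1$draws, f2$draws)
})
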