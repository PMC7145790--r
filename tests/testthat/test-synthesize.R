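test_that("population totals match the log-normal sampling distribution", {
  g <- simulate_area_graph(10, "lattice", seed = 1)
  pop <- simulate_population(g, strata = default_strata(),
                             mean_pop = 140000, seed = 7)
  expect_true(all(pop$population >= 1))
  expect_equal(nrow(pop), 10 * 4)
  # total ~ sum of 10 log-normals with mean 140,000, sdlog 0.5
  v1 <- 140000^2 * (exp(0.25) - 1)
  se <- sqrt(10 * v1)
  expect_lt(abs(sum(pop$population) - 1.4e6), 3 * se)
})

test_that("population generation is deterministic and validates inputs", {
  g <- simulate_area_graph(5, "lattice", seed = 1)
  p1 <- simulate_population(g, seed = 3)
  p2 <- simulate_population(g, seed = 3)
  expect_identical(p1, p2)
  expect_error(simulate_population(g, strata = character(0)), "non-empty")
  expect_error(simulate_population(g, mean_pop = -5), "positive")
})

test_that("one area, one stratum reduces to a single rounded draw", {
  g <- area_graph(list(2L, 1L))
  pop <- simulate_population(g, strata = "all", mean_pop = 1000, seed = 9)
  expect_equal(nrow(pop), 2)
  direct <- withr::with_seed(9L, {
    totals <- rlnorm(2, meanlog = log(1000) - 0.5^2 / 2, sdlog = 0.5)
    shares <- matrix(rgamma(2, shape = 40), nrow = 2)
    pmax(1, round(totals * (shares / shares)))
  })
  expect_equal(pop$population, as.vector(direct))
})

test_that("exposure fields honour an identity target correlation", {
  g <- simulate_area_graph(2000, "lattice", seed = 1)
  x <- simulate_exposures(g, n_vars = 5, spatial_range = 0, seed = 2)
  R <- cor(as.matrix(x[, -1]), method = "spearman")
  expect_lt(max(abs(R[upper.tri(R)])), 0.1)
})

test_that("exposure fields reach a requested cross-correlation", {
  g <- simulate_area_graph(2000, "lattice", seed = 1)
  tc <- diag(3); tc[1, 2] <- tc[2, 1] <- 0.9
  x <- simulate_exposures(g, n_vars = 3, spatial_range = 0,
                          target_corr = tc, seed = 4)
  expect_lt(abs(cor(x$x01, x$x02) - 0.9), 0.05)
})

test_that("exposure edge cases behave", {
  g <- simulate_area_graph(25, "lattice", seed = 1)
  empty <- simulate_exposures(g, n_vars = 0, seed = 1)
  expect_equal(names(empty), "area_id")
  bad <- matrix(c(1, 2, 2, 1), 2)  # not positive-definite
  expect_error(simulate_exposures(g, 2, target_corr = bad),
               "positive-definite")
})

test_that("spatial_range > 0 induces positive spatial autocorrelation", {
  g <- simulate_area_graph(400, "lattice", seed = 1)
  x <- simulate_exposures(g, n_vars = 1, spatial_range = 0.95, seed = 3)
  nb_mean <- vapply(seq_along(g$neighbours),
                    function(i) mean(x$x01[g$neighbours[[i]]]), 0)
  expect_gt(cor(x$x01, nb_mean), 0.3)
})

test_that("the degenerate generative model reduces to Poisson(E)", {
  g <- simulate_area_graph(100, "lattice", seed = 1)
  E <- rep(20, 100)
  ratios <- vapply(1:30, function(s) {
    tr <- synthetic_truth(g, sigma = 0, phi = 0, seed = s)
    mean(simulate_counts(E, NULL, tr, g)$O / E)
  }, 0)
  # 3000 Poisson(20) draws: SE of the mean ratio ~ sqrt(1/20/3000)
  expect_lt(abs(mean(ratios) - 1), 3 * sqrt(1 / 20 / 3000))
})

test_that("a log-2 intercept doubles the expected ratio", {
  g <- simulate_area_graph(100, "lattice", seed = 1)
  E <- rep(20, 100)
  ratios <- vapply(1:30, function(s) {
    tr <- synthetic_truth(g, intercept = log(2), sigma = 0, phi = 0, seed = s)
    mean(simulate_counts(E, NULL, tr, g)$O / E)
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 3 * sqrt(2 / 20 / 3000))
})

test_that("count simulation is deterministic and validates expected counts", {
  g <- simulate_area_graph(20, "lattice", seed = 1)
  tr <- synthetic_truth(g, sigma = 0.3, phi = 0.6, seed = 5)
  E <- rep(10, 20)
  expect_identical(simulate_counts(E, NULL, tr, g),
                   simulate_counts(E, NULL, tr, g))
  expect_error(simulate_counts(c(0, E[-1]), NULL, tr, g), "positive")
})

test_that("synthetic truth enforces its parameter ranges and constraints", {
  g <- simulate_area_graph(30, "random_planar", seed = 2)
  expect_error(synthetic_truth(g, phi = 1.2), "phi")
  expect_error(synthetic_truth(g, sigma = -1), "sigma")
  tr <- synthetic_truth(g, sigma = 0.5, phi = 0.4, seed = 3)
  expect_lt(abs(sum(tr$u)), 1e-10)  # sum-to-zero within the single component
})

test_that("simulate_region assembles a coherent study dataset", {
  region <- simulate_region(n_areas = 30, n_vars = 6, seed = 4)
  a <- region$areas
  expect_setequal(a$area_id, region$graph$area_ids)
  expect_true(all(a$E > 0))
  expect_equal(a$O_period1 + a$O_period2, a$O)
  # per-area stratified cases sum to the observed total
  by_area <- tapply(region$population$cases, region$population$area_id, sum)
  expect_equal(as.vector(by_area[a$area_id]), as.double(a$O))
})
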