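# small deterministic fixtures shared across test files

path_graph <- function(n) {
  nb <- lapply(seq_len(n), function(i) {
    c(if (i > 1) i - 1L, if (i < n) i + 1L)
  })
  area_graph(nb)
}

cycle_graph <- function(n) {
  nb <- lapply(seq_len(n), function(i) {
    sort(c(if (i > 1) i - 1L else n, if (i < n) i + 1L else 1L))
  })
  area_graph(nb)
}

# two-area, two-stratum stratified count table
toy_strat_counts <- function() {
  tibble::tibble(
    area_id = rep(c("A", "B"), each = 2),
    stratum = rep(c("s1", "s2"), 2),
    population = c(100, 200, 300, 400),
    cases = c(1, 4, 2, 9)
  )
}

# small area table with counts drawn around E under a known slope
toy_screen_data <- function(n = 20, b = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    E <- runif(n, 5, 50)
    O <- rpois(n, E * exp(b * x))
  })
  list(O = O, E = E, x = x)
}

# dense graph Laplacian of an area_graph
graph_laplacian <- function(g) {
  n <- length(g$area_ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, g$neighbours[[i]]] <- 1
  diag(lengths(g$neighbours)) - A
}

# constrained generalised-inverse marginal variances of an ICAR field,
# via the (Q + J/n)^{-1} - J/n identity: a route independent of the
# eigendecomposition used by scaled_icar()
icar_marginal_var_oracle <- function(Q) {
  n <- nrow(Q)
  J <- matrix(1 / n, n, n)
  diag(solve(Q + J) - J)
}
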